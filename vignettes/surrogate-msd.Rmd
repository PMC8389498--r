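---
title: "Surrogate-assisted multi-state design: models, parameters and design choices"
author: "msdnn authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-assisted multi-state design: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The optimization problem

Multi-state design (MSD) seeks the residue occupancy of the *n* design-shell
positions of a protein that scores well simultaneously across an ensemble of
*m* backbone conformations ("states"). The exact score of a candidate is the
mean over states of per-state total scores,
`RS_3DM = (1/m) Σ_i ts_i`, in score units with the Rosetta convention that
lower is better. Exact scoring is assumed expensive (minutes per sequence
for a physics-based scorer), which motivates the surrogate loop: spend the
exact-scoring budget only on candidates a cheap learned model already
considers promising.

The package's central loop (`run_protocol(..., protocol = "nn")`):

1. keep a pool `OPT_r` of the `s` best exactly scored sequences, ranked by
   `RS_3DM` (ties keep insertion order);
2. retrain one network per state on the growing archive `OPT*_r` of all
   exactly scored sequences;
3. screen `Z` random mutants of the pool's top fraction with the surrogate;
4. exactly score the `floor(s/2)` best-predicted candidates not already in
   the archive and replace the pool's bottom half with them.

The top half of the pool always survives, so the best pool score is
monotonically non-increasing, and every iteration of every protocol spends
at most `floor(s/2)` exact-scoring calls — the property that makes
iteration-for-iteration comparisons between protocols fair.

## The surrogate ensemble

Each state has its own fully connected feed-forward network: input `w·n`
features (`w = 20` one-hot, `w = 5` physicochemical), hidden layers of
`10 + w·n/2` and `5 + w·n/4` tanh units (floored when fractional), and one
linear output. **No layer carries a bias term**; initial weights are drawn
from a Normal(0, 0.05²). Targets are converted to z-scores (population mean
and SD of the current archive, refit per state at every iteration) before
training; predictions are de-standardized back to score units and averaged
over the m states, mirroring the exact aggregate.

Training is minibatch stochastic gradient descent with momentum on squared
error. Defaults, exposed in `training_config()`:

| parameter | default | notes |
|---|---|---|
| epochs | 100 | per retraining |
| learning rate | 0.01 | unstated in the method's original description; a conventional SGD value |
| momentum | 0.9 | conventional companion to 0.01 |
| batch size | 32 | shuffled each epoch, seeded |
| warm start | TRUE | "incremental" retraining |

"Incremental" retraining is interpreted as *warm-starting from the previous
iteration's weights and running the full epoch budget over the entire
updated archive*: the archive is the training set each time, not only the
newly added tuples. A `warm_start = FALSE` switch re-initializes weights
each iteration for comparison. Momentum buffers are reset at each
retraining; only weights persist.

The per-minibatch update is implemented in compiled code (RcppArmadillo),
with the shuffle stream seeded from R's RNG so whole runs are reproducible
under `set.seed()`.

## The synthetic landscape

No physics-based scorer ships with the package, so
`synthetic_landscape()` provides a seeded stand-in with the two features
that matter for exercising the method:

* an **additive field** `h(pos, aa) ~ N(0, σ_h²)` — the separable part any
  regressor can learn quickly;
* **pairwise epistatic couplings** `J(pos_i, pos_j, aa_i, aa_j) ~ N(0, σ_J²)`
  on a random fraction `ρ` of position pairs — the non-additive structure
  that creates alternative minima and makes mutation order matter;
* **per-state perturbations** `δ ~ N(0, σ_state²)` added independently to
  both terms for each of the m states, so states disagree mildly on
  rankings, as near-identical MD-derived conformations do.

Defaults `σ_h = 1, σ_J = 1, ρ = 0.3, σ_state = 0.1` make the epistatic
term comparable in magnitude to the additive one while keeping the states
strongly correlated. With `ρ = 0` the landscape is exactly additive and
`brute_force_optimum()` (exhaustive enumeration, lexicographic
tie-breaking) is the per-position argmin of the state-averaged field.

What the simulator does **not** emulate: score noise from stochastic
rotamer packing (evaluation is deterministic), heavy-tailed score
distributions, higher-order (≥3-way) epistasis, and any correlation
structure between residue identities beyond the sampled pair tables.
Passing tests on this landscape therefore demonstrate the machinery of the
protocol — budget accounting, selection, learning dynamics, metric
computation — not performance on any particular real design problem.

## Numerical and procedural choices

* **Alphabet order** for one-hot columns and frequency tables is
  alphabetical by one-letter code (A, C, D, …, Y); any fixed order is
  equivalent for the method. Physicochemical scales (volume, polarity,
  isoelectric point, hydropathy, mean accessibility) are shipped as a
  documented TSV and standardized over the 20 residues at load time.
* **Identity substitutions are excluded** in all mutation operators: a
  requested k-mutation offspring truly differs at k positions.
* **Odd pool sizes** are allowed (the production default `s = 239` is odd):
  `floor(s/2)` members are replaced per iteration and `s - floor(s/2)`
  survive as elite.
* **Re-discovered candidates are never re-scored.** The surrogate's
  selection skips sequences already in the archive and backfills from the
  prediction ranking, so the NN protocol makes exactly `floor(s/2)` novel
  exact-scoring calls per iteration. GA/mmGA offspring that re-create an
  archived sequence reuse its stored score (a cache hit), which can only
  reduce the baseline's spent budget.
* **Scan seeding** draws each mutant's seed uniformly from the pool's best
  decile (`seed_fraction = 0.1`).
* **Parent selection** in the GA baselines is rank-proportional
  (weight `s + 1 − rank`); crossover is available behind a flag but off by
  default, matching the single-mutation drift the baseline is meant to
  model.
* **Plateau stopping** ends a run when the pool mean improves by less than
  `ε = 0.01` score units over `w = 10` iterations; the criterion is a user
  choice and can be disabled.
* **NAA quadrature**: the area above the pool-mean curve uses the trapezoid
  rule over the iteration index (unit spacing), normalized by
  `(R − 1)·(curve[1] − global_min)` with `global_min` the lowest value
  reached by any protocol under comparison, which confines the statistic to
  [0, 1]. "Reaching" a reference score uses `≤` (scores are minimized), and
  the reference-generation search returns the earliest tie.
* **Frequency-distance groups**: the first-half/second-half split of a
  trajectory's compositional distances generalizes to `⌊R/2⌋` for runs of
  any length. Degenerate inputs error early: constant targets cannot be
  z-scored, empty pools have no frequency table, and a distance between
  non-normalized tables is refused rather than silently rescaled.

## Study conditions of the acceptance suite

The seeded end-to-end checks in `tests/testthat/test-acceptance.R` use one
landscape family — `n = 6`, `m = 10`, `σ_h = σ_J = 1`, `ρ = 0.3`,
`σ_state = 0.1` — at desk-scale sizes chosen once: pool `s = 40` with scan
`Z = 20,000` over 10 iterations and 10 seeds for the fidelity trend;
`Z = 5,000` over 15 iterations and 20 seeds for the convergence-ordering
comparison; 60 GA/mmGA iterations and 20 seeds for the multi-mutation
degradation check; and an additive `n = 3`, `m = 1` family (pool 20, scan
2,000, 15 iterations, 10 seeds) where the exhaustive global optimum is
known. The single analytic quantity — the supremum `√2 ≈ 1.4` of the
position-wise frequency distance — is recomputed by
`scripts/acceptance.R`.

## Known limitations

* The generation-wise correlation between predicted and exact scores is
  computed, as in the protocol's diagnostics, on the `floor(s/2)` selected
  candidates of each iteration. This restricts both the sample size and the
  score range: when the landscape's epistatic tables are under-sampled by
  the archive (thousands of independent coupling cells versus a few hundred
  exactly scored sequences at small `s`), the surrogate's residual error
  remains comparable to the selected candidates' score spread and the
  candidate-restricted correlation saturates well below the surrogate's
  global fidelity. Larger pools, denser sampling, or smoother landscapes
  raise it; the acceptance suite reports the measured trend honestly rather
  than tuning the landscape to flatter the statistic.
* The surrogate is a regression on shell residues only; it cannot
  extrapolate to positions or alphabets outside the design shell, and no
  structure-aware features are used.
* The adapter oracle inherits whatever nondeterminism the external scorer
  has; bit-reproducibility is guaranteed only for the synthetic oracle.
* Runtime of the scan step grows linearly in `Z·m`; the default
  `Z = 2,000,000` assumes the exact scorer, not the surrogate, dominates
  wall-clock time.
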