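## Trajectory metrics and composition analyses: pool-mean score curves,
## normalized area above the curve (NAA), iterations-to-reference,
## reference-generation search, residue-frequency tables with Euclidean
## distances and shuffled null models, mutation-count histograms, and
## generation-wise prediction/score correlation.

#' Pool-mean score
#'
#' The fitness of a pool at iteration r is the arithmetic mean of its
#' members' exact multi-state scores.
#'
#' @param pool An `opt_pool` (see [initialize_pool()]).
#' @return Mean score (score units).
#' @export
mean_pool_score <- function(pool) {
  if (anyNA(pool$rs_3dm)) stop("pool contains unscored members")
  mean(pool$rs_3dm)
}

#' Pool-mean score series of a trajectory
#'
#' @param trajectory A `design_trajectory` (see [run_protocol()]).
#' @return Numeric vector of RS(OPT_r), one entry per executed iteration.
#' @export
score_curve <- function(trajectory) trajectory$rs_opt

#' Normalized area above a score curve
#'
#' Convergence-speed statistic in \[0, 1\]: the trapezoidal area (unit
#' iteration spacing) between the curve's starting value and the curve,
#' normalized by the rectangle `(R - 1) * (curve[1] - global_min)`, where
#' `global_min` is the lowest score reached by any protocol under
#' comparison. A flat curve gives 0; an instant drop to the global minimum
#' approaches 1.
#'
#' @param curve Numeric score series (length >= 2).
#' @param global_min Reference minimum; must not exceed `min(curve)` and
#'   must lie strictly below `curve[1]`.
#' @return NAA value in \[0, 1\].
#' @export
naa <- function(curve, global_min) {
  R <- length(curve)
  if (R < 2L) stop("need at least 2 points")
  if (global_min > min(curve) + 1e-12)
    stop("global_min must not exceed the curve minimum")
  denom <- curve[1L] - global_min
  if (denom <= 0)
    stop("degenerate normalizer: curve starts at the global minimum")
  d <- curve[1L] - curve
  area <- sum((d[-R] + d[-1L]) / 2)
  area / ((R - 1L) * denom)
}

#' First iteration reaching a score threshold
#'
#' Smallest r with `curve[r] <= threshold` (scores are minimized), or NA if
#' never reached. This is the machinery behind iterations-to-reference
#' statistics such as the first iteration matching a rival protocol's final
#' score or a native-like score.
#'
#' @param curve Numeric score series.
#' @param threshold Score threshold.
#' @return Integer iteration index, or `NA_integer_`.
#' @export
first_iteration_reaching <- function(curve, threshold) {
  if (!length(curve)) stop("empty curve")
  hit <- which(curve <= threshold)
  if (length(hit)) hit[1L] else NA_integer_
}

#' Find the reference generation of a baseline run
#'
#' The earliest generation whose score is most similar to `target_score`
#' (ties resolved to the earliest index). Used to pick the baseline pool
#' whose composition is compared against a full surrogate trajectory.
#'
#' @param curve Numeric score series of the baseline run.
#' @param target_score Score to match.
#' @return Integer generation index.
#' @export
find_reference_generation <- function(curve, target_score) {
  if (!length(curve)) stop("empty curve")
  which.min(abs(curve - target_score))  # which.min returns the first minimum
}

#' Residue frequency table of a sequence pool
#'
#' Per design-shell position, the relative frequencies of the 20 residues
#' over the pool members. Rows are positions, columns follow
#' [aa_alphabet()]; each row sums to 1.
#'
#' @param pool An `opt_pool`, or a character vector of shell sequences.
#' @param shell A [design_shell()] (required when `pool` is a character
#'   vector; otherwise taken from the sequences' length).
#' @return n x 20 matrix of frequencies.
#' @export
frequency_tables <- function(pool, shell = NULL) {
  seqs <- if (inherits(pool, "opt_pool")) pool$sequences else pool
  if (!length(seqs)) stop("empty pool")
  if (is.null(shell))
    shell <- design_shell(seq_len(nchar(seqs[1L])),
                          strsplit(seqs[1L], "")[[1L]])
  idx <- seqs_to_idx(seqs, shell)
  ft <- matrix(0, shell$n, length(shell$alphabet),
               dimnames = list(shell$positions, shell$alphabet))
  for (pos in seq_len(shell$n))
    ft[pos, ] <- tabulate(idx[, pos], nbins = length(shell$alphabet))
  ft / length(seqs)
}

check_freq_vector <- function(f, what) {
  if (length(f) != 20L) stop(what, " must have 20 entries")
  if (any(f < -1e-12)) stop(what, " has negative frequencies")
  if (abs(sum(f) - 1) > 1e-6) stop(what, " is not normalized (sum != 1)")
}

#' Euclidean distance between two position frequency tables
#'
#' Position-specific distance between two normalized 20-category residue
#' frequency vectors. Its range is \[0, sqrt(2) ~ 1.4\]; the maximum is
#' attained by two point masses on different residues.
#'
#' @param ft_a,ft_b Numeric frequency vectors of length 20, each summing
#'   to 1.
#' @return Euclidean distance.
#' @export
table_distance <- function(ft_a, ft_b) {
  check_freq_vector(ft_a, "ft_a")
  check_freq_vector(ft_b, "ft_b")
  sqrt(sum((ft_a - ft_b)^2))
}

#' Mean frequency distance over a design shell
#'
#' Average of the per-position [table_distance()] values over the n shell
#' positions.
#'
#' @param fts_a,fts_b n x 20 frequency matrices (see [frequency_tables()]).
#' @return Mean distance in \[0, sqrt(2)\].
#' @export
mean_shell_distance <- function(fts_a, fts_b) {
  if (nrow(fts_a) != nrow(fts_b)) stop("frequency tables differ in n")
  mean(vapply(seq_len(nrow(fts_a)), function(pos)
    table_distance(fts_a[pos, ], fts_b[pos, ]), numeric(1L)))
}

#' Shuffled null model of a frequency table
#'
#' Permutes the 20 frequencies within each position's table (the multiset
#' of values is preserved, so rows still sum to 1). Distances of shuffled
#' tables to a reference form the null distribution against which observed
#' compositional distances are judged.
#'
#' @param fts n x 20 frequency matrix.
#' @return Shuffled matrix of the same shape.
#' @export
shuffled_null <- function(fts) {
  out <- fts
  for (pos in seq_len(nrow(fts)))
    out[pos, ] <- fts[pos, sample.int(ncol(fts))]
  out
}

#' Mutation-count histogram of a trajectory's candidates
#'
#' For each candidate introduced at iteration r, counts its minimum Hamming
#' distance to the pool OPT_r it was generated from, and tabulates these
#' counts over 1..n. Single-mutation GA trajectories place all mass at 1;
#' the surrogate protocol introduces up to n simultaneous mutations.
#'
#' @param trajectory A `design_trajectory`.
#' @param max_iterations Restrict to the first so-many iterations
#'   (default: all).
#' @return Named integer vector of counts for mutation numbers 1..n.
#' @export
mutation_histogram <- function(trajectory, max_iterations = Inf) {
  n <- trajectory$shell$n
  counts <- integer(n)
  R <- min(length(trajectory$records), max_iterations)
  for (r in seq_len(R)) {
    rec <- trajectory$records[[r]]
    if (is.null(rec$cand)) next
    prev_pool <- trajectory$records[[r - 1L]]$pool$sequences
    for (sq in rec$cand$sequences) {
      d <- min_mutations_to_pool(sq, prev_pool)
      if (d >= 1L && d <= n) counts[d] <- counts[d] + 1L
    }
  }
  names(counts) <- seq_len(n)
  counts
}

#' Generation-wise Pearson correlation
#'
#' Pearson correlation between surrogate-predicted and exact scores of a
#' generation's candidates.
#'
#' @param predicted,actual Equal-length numeric vectors (length >= 3,
#'   non-constant).
#' @return Pearson correlation coefficient.
#' @export
generation_pcc <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (sd(predicted) == 0 || sd(actual) == 0)
    stop("constant input; correlation undefined")
  cor(predicted, actual)
}

#' Per-iteration PCC series of a trajectory
#'
#' @param trajectory A `design_trajectory` from the NN protocol.
#' @return Numeric vector: the generation PCC recorded at each iteration
#'   (NA for iteration 1, which has no candidates).
#' @export
pcc_series <- function(trajectory) {
  vapply(trajectory$records, function(rec) rec$pcc, numeric(1L))
}

#' Compositional distance summary of a trajectory
#'
#' Compares each iteration's pool composition with a fixed reference
#' frequency table: per-iteration mean shell distances, split into
#' first-half (NN1) and second-half (NN2) groups, plus matched shuffled
#' null groups (R1, R2).
#'
#' @param trajectory A `design_trajectory`.
#' @param reference_ft Reference n x 20 frequency matrix (e.g. from the
#'   baseline pool chosen by [find_reference_generation()]).
#' @return A data frame with columns `iteration`, `dist`, `null_dist`,
#'   `group` ("NN1"/"NN2").
#' @export
composition_distance_summary <- function(trajectory, reference_ft) {
  R <- length(trajectory$records)
  half <- R %/% 2L
  out <- data.frame(iteration = seq_len(R), dist = NA_real_,
                    null_dist = NA_real_,
                    group = ifelse(seq_len(R) <= half, "NN1", "NN2"),
                    stringsAsFactors = FALSE)
  for (r in seq_len(R)) {
    ft <- frequency_tables(trajectory$records[[r]]$pool,
                           trajectory$shell)
    out$dist[r] <- mean_shell_distance(ft, reference_ft)
    out$null_dist[r] <- mean_shell_distance(shuffled_null(ft), reference_ft)
  }
  out
}
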