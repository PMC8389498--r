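## The three search protocols (NN-surrogate loop, single-mutation GA,
## multi-mutation mmGA) and the pool/archive bookkeeping they share. All
## protocols keep a pool of s exactly scored sequences, replace its bottom
## floor(s/2) each iteration with freshly scored candidates, and keep the
## top half as elite, so exact-scoring budgets are comparable iteration for
## iteration.

#' Protocol configuration
#'
#' @param protocol `"nn"` (surrogate loop), `"ga"` (single-mutation genetic
#'   algorithm) or `"mmga"` (GA variant introducing 1..n mutations).
#' @param s Pool size (default 239, the production default). Each iteration
#'   replaces `floor(s/2)` members.
#' @param Z Scan size: number of random mutants screened by the surrogate
#'   per iteration (default 2,000,000; configurable downward).
#' @param max_iterations Iteration budget.
#' @param seed_fraction Fraction of the (ranked) pool used to seed the scan;
#'   default 0.1 (the top decile).
#' @param stop_on_plateau Stop early when the pool-mean score improves by
#'   less than `plateau_eps` over `plateau_window` iterations.
#' @param plateau_window,plateau_eps Plateau stopping parameters (10
#'   iterations, 0.01 score units).
#' @param mmga_max_mutations Upper bound on mutations per mmGA offspring;
#'   defaults to the shell size n. With 1 the mmGA reduces to the GA.
#' @param crossover GA/mmGA only: apply uniform crossover between two
#'   parents before mutation (off by default; the baseline protocols drift
#'   by mutation).
#' @return A `protocol_config`.
#' @export
protocol_config <- function(protocol = c("nn", "ga", "mmga"), s = 239L,
                            Z = 2000000L, max_iterations = 100L,
                            seed_fraction = 0.1, stop_on_plateau = TRUE,
                            plateau_window = 10L, plateau_eps = 0.01,
                            mmga_max_mutations = NULL, crossover = FALSE) {
  protocol <- match.arg(protocol)
  s <- as.integer(s)
  if (s < 2L) stop("pool size s must be >= 2")
  Z <- as.integer(Z)
  if (Z < s %/% 2L) stop("scan size Z must be at least floor(s/2)")
  if (seed_fraction <= 0 || seed_fraction > 1)
    stop("seed_fraction must be in (0, 1]")
  if (as.integer(max_iterations) < 1L) stop("max_iterations must be >= 1")
  structure(list(protocol = protocol, s = s, Z = Z,
                 max_iterations = as.integer(max_iterations),
                 seed_fraction = seed_fraction,
                 stop_on_plateau = isTRUE(stop_on_plateau),
                 plateau_window = as.integer(plateau_window),
                 plateau_eps = plateau_eps,
                 mmga_max_mutations = mmga_max_mutations,
                 crossover = isTRUE(crossover)),
            class = "protocol_config")
}

## ---- pool & archive ----------------------------------------------------

new_pool <- function(sequences, ts, iteration, rs_nn = NULL) {
  rs <- rowMeans(ts)
  ord <- order(rs)  # stable: ties keep insertion order
  structure(list(iteration = as.integer(iteration),
                 sequences = sequences[ord],
                 ts = ts[ord, , drop = FALSE],
                 rs_3dm = rs[ord],
                 rs_nn = if (is.null(rs_nn)) rep(NA_real_, length(rs))[ord]
                         else rs_nn[ord]),
            class = "opt_pool")
}

#' @export
print.opt_pool <- function(x, ...) {
  cat("opt_pool: iteration", x$iteration, "-", length(x$sequences),
      "sequences, best", format(x$rs_3dm[1L]), ", mean",
      format(mean(x$rs_3dm)), "\n")
  invisible(x)
}

new_archive <- function(pool) {
  structure(list(sequences = pool$sequences, ts = pool$ts,
                 rs_3dm = pool$rs_3dm),
            class = "design_archive")
}

archive_extend <- function(archive, sequences, ts) {
  novel <- !(sequences %in% archive$sequences)
  if (any(novel)) {
    archive$sequences <- c(archive$sequences, sequences[novel])
    archive$ts <- rbind(archive$ts, ts[novel, , drop = FALSE])
    archive$rs_3dm <- c(archive$rs_3dm, rowMeans(ts[novel, , drop = FALSE]))
  }
  archive
}

#' @export
print.design_archive <- function(x, ...) {
  cat("design_archive:", length(x$sequences), "scored sequences\n")
  invisible(x)
}

#' Initialize the iteration-1 pool
#'
#' The first pool consists of the seed sequence plus `s - 1` distinct
#' single-point mutants of it, all exactly scored.
#'
#' @param seed_seq Seed shell sequence.
#' @param s Pool size.
#' @param oracle A scoring oracle (see [score_sequences()]).
#' @param shell A [design_shell()].
#' @return An `opt_pool` at iteration 1.
#' @export
initialize_pool <- function(seed_seq, s, oracle, shell) {
  s <- as.integer(s)
  if (s < 2L) stop("s must be >= 2")
  capacity <- 19L * shell$n
  if (s - 1L > capacity)
    stop("cannot build ", s - 1L, " distinct single-point mutants: only ",
         capacity, " exist for n = ", shell$n)
  mutants <- character(0L)
  while (length(mutants) < s - 1L) {
    cand <- point_mutant(seed_seq, shell)
    if (!(cand %in% mutants)) mutants <- c(mutants, cand)
  }
  seqs <- c(seed_seq, mutants)
  sc <- score_sequences(oracle, seqs)
  new_pool(seqs, sc$ts, iteration = 1L)
}

## rank-proportional parent sampling: weight s+1-rank on the ranked pool
sample_parents <- function(pool, count) {
  s <- length(pool$sequences)
  w <- rev(seq_len(s))
  sample.int(s, count, replace = TRUE, prob = w / sum(w))
}

## score candidates, reusing archived scores so no sequence is ever
## oracle-scored twice; returns ts for all, count of true oracle calls,
## and the extended archive
score_with_cache <- function(candidates, oracle, archive) {
  m <- ncol(archive$ts)
  ts <- matrix(NA_real_, length(candidates), m)
  hit <- match(candidates, archive$sequences)
  if (any(!is.na(hit)))
    ts[!is.na(hit), ] <- archive$ts[hit[!is.na(hit)], , drop = FALSE]
  need <- which(is.na(hit))
  calls <- 0L
  if (length(need)) {
    uniq <- unique(candidates[need])
    sc <- score_sequences(oracle, uniq)
    calls <- length(uniq)
    ts[need, ] <- sc$ts[match(candidates[need], uniq), , drop = FALSE]
    archive <- archive_extend(archive, uniq, sc$ts)
  }
  list(ts = ts, oracle_calls = calls, archive = archive)
}

#' One iteration of the NN-surrogate protocol
#'
#' Refits the surrogate on the archive, screens `Z` random mutants seeded
#' from the pool's best fraction, exactly scores the `floor(s/2)`
#' best-predicted candidates not already archived (backfilling down the
#' ranking past re-discoveries), and replaces the pool's bottom half with
#' them. Diagnostics carry the generation-wise Pearson correlation between
#' predicted and exact scores of the new candidates.
#'
#' @param pool Current `opt_pool`.
#' @param archive Current `design_archive` (superset of the pool).
#' @param surrogate A [surrogate_ensemble][build_surrogate()].
#' @param oracle A scoring oracle.
#' @param cfg A [protocol_config()].
#' @param training A [training_config()].
#' @return List with elements `pool`, `archive`, `surrogate`, and
#'   `diagnostics` (`pcc`, `oracle_calls`, `cand`).
#' @export
nn_iteration <- function(pool, archive, surrogate, oracle, cfg,
                         training = training_config()) {
  s <- length(pool$sequences)
  n_new <- s %/% 2L
  surrogate <- fit_surrogate(surrogate, archive, training)

  n_seed <- max(1L, ceiling(s * cfg$seed_fraction))
  seed_idx <- seqs_to_idx(pool$sequences[seq_len(n_seed)], surrogate$shell)
  scan_idx <- scan_mutants_idx(seed_idx, cfg$Z, surrogate$shell)
  pred <- predict_rs_idx(surrogate, scan_idx)

  ord <- order(pred$rs_nn)  # lowest predicted score = best
  chosen <- integer(0L)
  chosen_seqs <- character(0L)
  for (j in ord) {
    sq <- idx_to_seqs(scan_idx[j, , drop = FALSE], surrogate$shell)
    if (sq %in% archive$sequences || sq %in% chosen_seqs) next
    chosen <- c(chosen, j)
    chosen_seqs <- c(chosen_seqs, sq)
    if (length(chosen) == n_new) break
  }
  if (length(chosen) < n_new)
    stop("scan produced only ", length(chosen),
         " novel candidates; increase Z (", cfg$Z, ")")

  sc <- score_sequences(oracle, chosen_seqs)
  archive <- archive_extend(archive, chosen_seqs, sc$ts)
  rs_nn_new <- pred$rs_nn[chosen]
  pcc <- if (sd(rs_nn_new) > 0 && sd(sc$rs_3dm) > 0)
    cor(rs_nn_new, sc$rs_3dm) else NA_real_

  elite <- seq_len(s - n_new)
  next_pool <- new_pool(
    c(pool$sequences[elite], chosen_seqs),
    rbind(pool$ts[elite, , drop = FALSE], sc$ts),
    iteration = pool$iteration + 1L,
    rs_nn = c(pool$rs_nn[elite], rs_nn_new))

  list(pool = next_pool, archive = archive, surrogate = surrogate,
       diagnostics = list(
         pcc = pcc, oracle_calls = n_new,
         cand = list(sequences = chosen_seqs, ts = sc$ts,
                     rs_3dm = sc$rs_3dm, rs_nn = rs_nn_new)))
}

ga_offspring <- function(pool, cfg, shell, k_max) {
  s <- length(pool$sequences)
  n_new <- s %/% 2L
  idx <- seqs_to_idx(pool$sequences, shell)
  parents <- sample_parents(pool, n_new)
  out <- matrix(0L, n_new, shell$n)
  for (i in seq_len(n_new)) {
    row <- idx[parents[i], ]
    if (cfg$crossover) {
      mate <- idx[sample_parents(pool, 1L), ]
      swap <- runif(shell$n) < 0.5
      row[swap] <- mate[swap]
    }
    k <- if (k_max == 1L) 1L else sample.int(k_max, 1L)
    out[i, ] <- mutate_idx_row(row, k, shell$n)
  }
  idx_to_seqs(out, shell)
}

#' One iteration of the GA / mmGA baseline
#'
#' `floor(s/2)` offspring are produced, each by mutating a parent drawn
#' rank-proportionally from the pool (single point mutation for the GA;
#' 1..n simultaneous mutations, uniformly drawn, for the mmGA). Offspring
#' are exactly scored (re-discovered archived sequences reuse their stored
#' score) and replace the pool's bottom half.
#'
#' @inheritParams nn_iteration
#' @param shell A [design_shell()].
#' @return List with `pool`, `archive`, and `diagnostics`
#'   (`oracle_calls`, `cand`).
#' @export
ga_iteration <- function(pool, oracle, cfg, shell, archive = NULL) {
  baseline_iteration(pool, oracle, cfg, shell, archive, k_max = 1L)
}

#' @rdname ga_iteration
#' @export
mmga_iteration <- function(pool, oracle, cfg, shell, archive = NULL) {
  k_max <- if (is.null(cfg$mmga_max_mutations)) shell$n else
    as.integer(cfg$mmga_max_mutations)
  if (k_max < 1L || k_max > shell$n)
    stop("mmga_max_mutations must be in 1..n")
  baseline_iteration(pool, oracle, cfg, shell, archive, k_max = k_max)
}

baseline_iteration <- function(pool, oracle, cfg, shell, archive, k_max) {
  if (is.null(archive)) archive <- new_archive(pool)
  s <- length(pool$sequences)
  n_new <- s %/% 2L
  offspring <- ga_offspring(pool, cfg, shell, k_max)
  sc <- score_with_cache(offspring, oracle, archive)
  elite <- seq_len(s - n_new)
  next_pool <- new_pool(
    c(pool$sequences[elite], offspring),
    rbind(pool$ts[elite, , drop = FALSE], sc$ts),
    iteration = pool$iteration + 1L)
  list(pool = next_pool, archive = sc$archive,
       diagnostics = list(pcc = NA_real_, oracle_calls = sc$oracle_calls,
                          cand = list(sequences = offspring, ts = sc$ts,
                                      rs_3dm = rowMeans(sc$ts),
                                      rs_nn = rep(NA_real_, n_new))))
}

#' Run a full design protocol
#'
#' Executes the configured protocol from a seed sequence until the
#' iteration budget or the plateau criterion is met, and records the full
#' trajectory: per-iteration pool snapshots, candidate sets, pool-mean
#' scores, oracle-call accounting and surrogate diagnostics. With a
#' synthetic-landscape oracle the run is bit-reproducible from `seed`.
#'
#' @param shell A [design_shell()].
#' @param oracle A scoring oracle.
#' @param cfg A [protocol_config()].
#' @param training A [training_config()] (NN protocol only).
#' @param scheme An [encoding_scheme()] (NN protocol only).
#' @param seed_seq Seed sequence; defaults to the shell's wild type.
#' @param seed Integer seed for the run's RNG (optional).
#' @return A `design_trajectory`.
#' @export
run_protocol <- function(shell, oracle, cfg, training = training_config(),
                         scheme = encoding_scheme(), seed_seq = NULL,
                         seed = NULL) {
  stopifnot(inherits(cfg, "protocol_config"))
  ## config consistency checks before any oracle call
  if (cfg$s - 1L > 19L * shell$n)
    stop("s = ", cfg$s, " exceeds the ", 19L * shell$n + 1L,
         " sequences within one mutation of the seed")
  if (!is.null(cfg$mmga_max_mutations) &&
      (cfg$mmga_max_mutations < 1L || cfg$mmga_max_mutations > shell$n))
    stop("mmga_max_mutations must be in 1..n")
  if (is.null(seed_seq)) seed_seq <- wild_type_sequence(shell)
  if (!is.null(seed)) set.seed(seed)

  m <- oracle_states(oracle)
  pool <- initialize_pool(seed_seq, cfg$s, oracle, shell)
  archive <- new_archive(pool)
  surrogate <- if (cfg$protocol == "nn")
    build_surrogate(shell, m, scheme) else NULL

  records <- vector("list", cfg$max_iterations)
  rs_opt <- numeric(0L)
  calls <- length(pool$sequences)
  records[[1L]] <- list(iteration = 1L, pool = pool,
                        rs_opt = mean(pool$rs_3dm), best = pool$rs_3dm[1L],
                        cand = NULL, pcc = NA_real_, oracle_calls = calls)
  rs_opt[1L] <- mean(pool$rs_3dm)

  r <- 1L
  while (r < cfg$max_iterations) {
    step <- switch(cfg$protocol,
      nn = nn_iteration(pool, archive, surrogate, oracle, cfg, training),
      ga = ga_iteration(pool, oracle, cfg, shell, archive),
      mmga = mmga_iteration(pool, oracle, cfg, shell, archive))
    pool <- step$pool
    archive <- step$archive
    if (!is.null(step$surrogate)) surrogate <- step$surrogate
    r <- r + 1L
    rs_opt[r] <- mean(pool$rs_3dm)
    calls <- calls + step$diagnostics$oracle_calls
    records[[r]] <- list(iteration = r, pool = pool, rs_opt = rs_opt[r],
                         best = pool$rs_3dm[1L],
                         cand = step$diagnostics$cand,
                         pcc = step$diagnostics$pcc,
                         oracle_calls = step$diagnostics$oracle_calls)
    if (cfg$stop_on_plateau && r > cfg$plateau_window &&
        rs_opt[r - cfg$plateau_window] - rs_opt[r] < cfg$plateau_eps)
      break
  }
  structure(
    list(protocol = cfg$protocol, config = cfg, shell = shell,
         records = records[seq_len(r)], rs_opt = rs_opt,
         oracle_calls_total = calls, seed = seed,
         config_hash = config_hash(list(config = unclass(cfg), seed = seed))),
    class = "design_trajectory")
}

#' @export
print.design_trajectory <- function(x, ...) {
  R <- length(x$records)
  cat("design_trajectory:", x$protocol, "protocol,", R, "iteration(s)\n")
  cat("  RS(OPT_1) =", format(x$rs_opt[1L]),
      " RS(OPT_", R, ") = ", format(x$rs_opt[R]), "\n", sep = "")
  cat("  oracle calls:", x$oracle_calls_total,
      " config hash:", x$config_hash, "\n")
  invisible(x)
}
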