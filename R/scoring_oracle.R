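## Multi-state score aggregation, the synthetic epistatic landscape oracle,
## a brute-force optimum oracle for small instances, and the file-based
## adapter for external scorers. Scores follow the Rosetta Energy Unit
## convention throughout: lower is better.

#' Aggregate per-state scores into a multi-state score
#'
#' The exact multi-state score of a candidate is the arithmetic mean of its
#' per-state total scores over the m states of the conformational ensemble.
#'
#' @param per_state_scores Numeric vector of finite per-state scores
#'   (length m >= 1).
#' @return The mean score (score units, lower is better).
#' @export
aggregate_multistate <- function(per_state_scores) {
  if (length(per_state_scores) < 1L) stop("no per-state scores supplied")
  if (!all(is.finite(per_state_scores)))
    stop("per-state scores must all be finite")
  mean(per_state_scores)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic multi-state epistatic fitness landscape
#'
#' A seeded stand-in for an expensive physics-based scorer. The score of a
#' sequence in each state is an additive per-position field plus pairwise
#' epistatic couplings on a random subset of position pairs, with small
#' independent per-state perturbations of both terms:
#' \deqn{ts_i(seq) = \sum_{p} [h + \delta^h_i](p, aa_p) +
#'       \sum_{(p,q) \in pairs} [J + \delta^J_i](p, q, aa_p, aa_q)}
#' Additive field entries are drawn Normal(0, sigma_h^2), couplings
#' Normal(0, sigma_j^2) on pairs selected with density `rho`, and per-state
#' perturbations Normal(0, sigma_state^2) on both terms, so the m states
#' disagree mildly on rankings, as near-identical conformations do.
#' Evaluation is deterministic given the seed.
#'
#' @param shell A [design_shell()].
#' @param m Number of states (>= 1).
#' @param sigma_h SD of the additive per-position field.
#' @param sigma_j SD of pairwise couplings.
#' @param rho Fraction of position pairs carrying a coupling, in \[0, 1\];
#'   `rho = 0` yields a purely additive landscape.
#' @param sigma_state SD of the per-state perturbations; 0 makes all states
#'   identical.
#' @param seed Integer seed for landscape construction (optional; when NULL
#'   the current RNG state is consumed).
#' @return An object of class `synthetic_landscape`.
#' @export
synthetic_landscape <- function(shell, m, sigma_h = 1, sigma_j = 1,
                                rho = 0.3, sigma_state = 0.1, seed = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  if (sigma_h < 0 || sigma_j < 0 || sigma_state < 0)
    stop("sigma parameters must be >= 0")
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  n <- shell$n
  na <- length(shell$alphabet)
  with_seed(seed, {
    h <- matrix(rnorm(n * na, sd = sigma_h), nrow = n, ncol = na)
    pairs <- if (n >= 2L) t(utils::combn(n, 2L)) else
      matrix(integer(0L), ncol = 2L)
    if (nrow(pairs)) pairs <- pairs[runif(nrow(pairs)) < rho, , drop = FALSE]
    P <- nrow(pairs)
    J <- lapply(seq_len(P), function(p)
      matrix(rnorm(na * na, sd = sigma_j), na, na))
    h_eff <- vector("list", m)
    J_eff <- vector("list", m)
    for (i in seq_len(m)) {
      h_eff[[i]] <- h + matrix(rnorm(n * na, sd = sigma_state), n, na)
      J_eff[[i]] <- lapply(seq_len(P), function(p)
        J[[p]] + matrix(rnorm(na * na, sd = sigma_state), na, na))
    }
    structure(
      list(shell = shell, m = m, state_ids = paste0("state_", seq_len(m)),
           h = h, pairs = pairs, J = J, h_eff = h_eff, J_eff = J_eff,
           params = list(sigma_h = sigma_h, sigma_j = sigma_j, rho = rho,
                         sigma_state = sigma_state),
           seed = seed),
      class = "synthetic_landscape")
  })
}

#' @export
print.synthetic_landscape <- function(x, ...) {
  cat("synthetic_landscape: n =", x$shell$n, ", m =", x$m,
      "states,", nrow(x$pairs), "epistatic pairs\n")
  cat("  sigma_h =", x$params$sigma_h, ", sigma_j =", x$params$sigma_j,
      ", rho =", x$params$rho, ", sigma_state =", x$params$sigma_state, "\n")
  invisible(x)
}

score_idx <- function(landscape, idx) {
  N <- nrow(idx)
  n <- ncol(idx)
  if (n != landscape$shell$n) stop("sequence length does not match landscape")
  ts <- matrix(0, N, landscape$m)
  P <- nrow(landscape$pairs)
  for (i in seq_len(landscape$m)) {
    he <- landscape$h_eff[[i]]
    acc <- numeric(N)
    for (pos in seq_len(n)) acc <- acc + he[pos, idx[, pos]]
    if (P) {
      Je <- landscape$J_eff[[i]]
      for (p in seq_len(P)) {
        a <- landscape$pairs[p, 1L]
        b <- landscape$pairs[p, 2L]
        acc <- acc + Je[[p]][cbind(idx[, a], idx[, b])]
      }
    }
    ts[, i] <- acc
  }
  colnames(ts) <- landscape$state_ids
  ts
}

#' Score sequences with an oracle
#'
#' Generic exact-scoring interface used by the optimizer. Methods exist for
#' [synthetic_landscape()] and [external_scorer()].
#'
#' @param oracle A scoring oracle.
#' @param seqs Character vector of shell sequences.
#' @return List with `ts` (N x m matrix of per-state scores) and `rs_3dm`
#'   (length-N vector of state-mean scores), in input order.
#' @export
score_sequences <- function(oracle, seqs) UseMethod("score_sequences")

#' @export
score_sequences.synthetic_landscape <- function(oracle, seqs) {
  ts <- score_idx(oracle, seqs_to_idx(seqs, oracle$shell))
  list(ts = ts, rs_3dm = rowMeans(ts))
}

#' Evaluate a synthetic landscape on sequences
#'
#' Convenience wrapper returning a scored-sequence data frame with one row
#' per input: the sequence, per-state scores `ts.<state>`, and the
#' state-mean `rs_3dm`.
#'
#' @param landscape A [synthetic_landscape()].
#' @param seqs Character vector of shell sequences.
#' @return A `data.frame`.
#' @export
evaluate_landscape <- function(landscape, seqs) {
  sc <- score_sequences(landscape, seqs)
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  ts <- sc$ts
  colnames(ts) <- paste0("ts.", seq_len(ncol(ts)))
  cbind(out, as.data.frame(ts), rs_3dm = sc$rs_3dm)
}

#' Brute-force global optimum of a landscape
#'
#' Exhaustively enumerates all |alphabet|^n sequences and returns the global
#' minimizer of the state-mean score. Ties are broken lexicographically in
#' alphabet order (enumeration is lexicographic and only strict improvements
#' are kept). Intended as an independent oracle on small instances.
#'
#' @param landscape A [synthetic_landscape()].
#' @param enumeration_cap Refuse to enumerate more than this many sequences.
#' @return One-row scored-sequence `data.frame` (see [evaluate_landscape()]).
#' @export
brute_force_optimum <- function(landscape, enumeration_cap = 1e6) {
  n <- landscape$shell$n
  na <- length(landscape$shell$alphabet)
  total <- na^n
  if (total > enumeration_cap)
    stop("search space (", format(total, big.mark = ","),
         " sequences) exceeds enumeration cap ", enumeration_cap)
  best_rs <- Inf
  best_idx <- NULL
  batch <- 100000L
  done <- 0
  while (done < total) {
    take <- as.integer(min(batch, total - done))
    ids <- done + seq_len(take) - 1  # 0-based lexicographic rank
    idx <- matrix(0L, take, n)
    rest <- ids
    for (pos in n:1) {              # last position varies fastest
      idx[, pos] <- as.integer(rest %% na) + 1L
      rest <- rest %/% na
    }
    rs <- rowMeans(score_idx(landscape, idx))
    w <- which.min(rs)
    if (rs[w] < best_rs) {
      best_rs <- rs[w]
      best_idx <- idx[w, , drop = FALSE]
    }
    done <- done + take
  }
  evaluate_landscape(landscape, idx_to_seqs(best_idx, landscape$shell))
}

#' External scorer adapter
#'
#' File-based contract for plugging in a real (expensive) scorer: candidates
#' are written as FASTA, the configured command is invoked as
#' `command [args] <candidates.fasta> <scores.tsv>`, and the TSV is read
#' back. The TSV must have a header `seq_id` followed by one score column
#' per state, one row per candidate, ids matching the FASTA headers.
#'
#' @param command Path to the executable.
#' @param m Expected number of states (score columns).
#' @param args Extra leading arguments for the command.
#' @param workdir Directory for the exchange files.
#' @return An object of class `adapter_oracle` usable with
#'   [score_sequences()].
#' @export
external_scorer <- function(command, m, args = character(),
                            workdir = tempfile("msdnn_adapter_")) {
  structure(list(command = command, m = as.integer(m), args = args,
                 workdir = workdir),
            class = "adapter_oracle")
}

#' @export
score_sequences.adapter_oracle <- function(oracle, seqs) {
  if (!dir.exists(oracle$workdir))
    dir.create(oracle$workdir, recursive = TRUE)
  ids <- sprintf("seq_%05d", seq_along(seqs))
  fa <- file.path(oracle$workdir, "candidates.fasta")
  tsv <- file.path(oracle$workdir, "scores.tsv")
  if (file.exists(tsv)) unlink(tsv)
  aas <- Biostrings::AAStringSet(seqs)
  names(aas) <- ids
  Biostrings::writeXStringSet(aas, fa)
  status <- system2(oracle$command, c(oracle$args, fa, tsv),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L)
    stop("adapter command '", oracle$command, "' exited with status ", status)
  if (!file.exists(tsv)) stop("adapter produced no score file: ", tsv)
  tab <- read.delim(tsv, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"seq_id" %in% colnames(tab))
    stop("adapter TSV lacks a seq_id column")
  score_cols <- setdiff(colnames(tab), "seq_id")
  if (length(score_cols) != oracle$m)
    stop("adapter TSV has ", length(score_cols),
         " score columns, expected m = ", oracle$m)
  hit <- match(ids, tab$seq_id)
  if (anyNA(hit))
    stop("adapter TSV is missing sequence id(s): ",
         paste(ids[is.na(hit)], collapse = ", "))
  ts <- as.matrix(tab[hit, score_cols, drop = FALSE])
  if (!all(is.finite(ts))) stop("adapter TSV contains non-finite scores")
  rownames(ts) <- NULL
  list(ts = ts, rs_3dm = rowMeans(ts))
}

oracle_states <- function(oracle) {
  if (inherits(oracle, "synthetic_landscape")) oracle$m
  else if (inherits(oracle, "adapter_oracle")) oracle$m
  else stop("unknown oracle type")
}
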