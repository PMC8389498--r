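#' msdnn: surrogate-assisted multi-state protein sequence design
#'
#' Iterative multi-state design: per-state neural-network surrogates are
#' trained on exactly scored candidate sequences, screen large random mutant
#' scans, and propose the best-predicted candidates for exact scoring.
#' Genetic-algorithm baselines, a synthetic epistatic landscape oracle, and
#' convergence/composition analytics are included.
#'
#' @useDynLib msdnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif cor sd
#' @importFrom utils read.delim write.table head
#' @keywords internal
"_PACKAGE"

#' The canonical amino acid alphabet
#'
#' The 20 canonical amino acids in the fixed order used for all one-hot
#' columns and frequency tables in this package: alphabetical by one-letter
#' code (A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y).
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Design shell specification
#'
#' A design shell is the set of n residue positions whose amino acid
#' occupancy the optimization is allowed to change. Candidate sequences in
#' this package are strings of length n over the shell positions only, not
#' full-protein sequences.
#'
#' @param positions Character or integer vector of unique position labels
#'   (e.g. residue numbers), length n >= 1. Order is preserved and defines
#'   the sequence coordinate.
#' @param wild_type Character vector of wild-type residues, one per position,
#'   or a single string of length n.
#' @param second_shell_count Integer metadata: number of second-shell
#'   (repacked but fixed-identity) residues. Not used computationally.
#' @param alphabet Residue alphabet; defaults to [aa_alphabet()].
#' @return An object of class `design_shell` with fields `positions`,
#'   `wild_type`, `n`, `second_shell_count`, `alphabet`.
#' @examples
#' sh <- design_shell(c("10", "24", "57"), c("A", "G", "W"))
#' wild_type_sequence(sh)
#' @export
design_shell <- function(positions, wild_type, second_shell_count = 0L,
                         alphabet = aa_alphabet()) {
  positions <- as.character(positions)
  if (length(positions) < 1L) stop("a design shell needs at least one position")
  if (anyDuplicated(positions))
    stop("duplicate position labels: ",
         paste(unique(positions[duplicated(positions)]), collapse = ", "))
  if (length(wild_type) == 1L && nchar(wild_type) == length(positions))
    wild_type <- strsplit(wild_type, "")[[1]]
  wild_type <- as.character(wild_type)
  if (length(wild_type) != length(positions))
    stop("wild_type must supply one residue per position")
  bad <- which(!(wild_type %in% alphabet))
  if (length(bad))
    stop("wild-type residue not in alphabet at position(s): ",
         paste(positions[bad], collapse = ", "))
  structure(
    list(positions = positions, wild_type = wild_type,
         n = length(positions),
         second_shell_count = as.integer(second_shell_count),
         alphabet = alphabet),
    class = "design_shell")
}

#' @export
print.design_shell <- function(x, ...) {
  cat("design_shell: n =", x$n, "positions,",
      x$second_shell_count, "second-shell residues\n")
  cat("  positions:", paste(x$positions, collapse = " "), "\n")
  cat("  wild type:", paste(x$wild_type, collapse = ""), "\n")
  invisible(x)
}

#' Wild-type sequence of a design shell
#'
#' @param shell A [design_shell()].
#' @return The wild-type residues as a single string of length n.
#' @export
wild_type_sequence <- function(shell) {
  paste(shell$wild_type, collapse = "")
}

## ---- internal index representation -------------------------------------
## Sequences are user-facing strings; hot paths work on integer index
## matrices (rows = sequences, cols = shell positions, values 1..20).

seqs_to_idx <- function(seqs, shell) {
  n <- shell$n
  len <- nchar(seqs)
  if (any(len != n))
    stop("sequence length ", len[which(len != n)[1L]],
         " does not match design shell n = ", n)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, ncol = length(seqs))
  idx <- match(chars, shell$alphabet)
  if (anyNA(idx)) {
    flat <- which(is.na(idx))[1L]
    pos <- (flat - 1L) %% n + 1L
    jseq <- (flat - 1L) %/% n + 1L
    stop("symbol '", chars[flat], "' not in alphabet at position ",
         shell$positions[pos], " (sequence ", jseq, ")")
  }
  matrix(idx, ncol = n, byrow = TRUE)
}

idx_to_seqs <- function(idx, shell) {
  if (!is.matrix(idx)) idx <- matrix(idx, nrow = 1L)
  cols <- lapply(seq_len(ncol(idx)), function(j) shell$alphabet[idx[, j]])
  do.call(paste0, cols)
}

#' Residue encoding scheme
#'
#' Two encodings of a shell residue are supported: `one_hot` (a 20-entry
#' indicator per position, the default) and `physchem` (five standardized
#' physicochemical descriptors per residue: volume, polarity, isoelectric
#' point, hydrophobicity, and mean solvent accessibility, read from the scale
#' table shipped in `extdata/physchem_scales.tsv` and standardized to zero
#' mean, unit variance over the 20 residues).
#'
#' @param mode `"one_hot"` or `"physchem"`.
#' @return An `encoding_scheme` with `mode`, `feature_width` (20 or 5) and,
#'   for `physchem`, the standardized 20 x 5 feature matrix.
#' @export
encoding_scheme <- function(mode = c("one_hot", "physchem")) {
  mode <- match.arg(mode)
  out <- list(mode = mode,
              feature_width = if (mode == "one_hot") 20L else 5L)
  if (mode == "physchem") {
    path <- system.file("extdata", "physchem_scales.tsv", package = "msdnn")
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(identical(tab$residue, aa_alphabet()))
    feat <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(feat) <- tab$residue
    out$physchem_table <- scale(feat)  # zero mean, unit variance per column
  }
  structure(out, class = "encoding_scheme")
}

encode_idx <- function(idx, scheme) {
  n <- ncol(idx)
  nr <- nrow(idx)
  w <- scheme$feature_width
  X <- matrix(0, nrow = nr, ncol = w * n)
  if (scheme$mode == "one_hot") {
    rows <- seq_len(nr)
    for (pos in seq_len(n))
      X[cbind(rows, (pos - 1L) * 20L + idx[, pos])] <- 1
  } else {
    feat <- scheme$physchem_table
    for (pos in seq_len(n))
      X[, (pos - 1L) * 5L + 1:5] <- feat[idx[, pos], , drop = FALSE]
  }
  X
}

#' Encode sequences as flat numeric vectors
#'
#' One-hot mode yields `20 * n` features per sequence with exactly one unit
#' entry per position block; physchem mode yields `5 * n` standardized
#' descriptor values.
#'
#' @param seqs Character vector of shell sequences.
#' @param shell A [design_shell()].
#' @param scheme An [encoding_scheme()].
#' @return Numeric matrix, one row per sequence (`encode_sequences`), or a
#'   plain vector for the single-sequence convenience [encode_sequence()].
#' @export
encode_sequences <- function(seqs, shell, scheme = encoding_scheme()) {
  encode_idx(seqs_to_idx(seqs, shell), scheme)
}

#' @rdname encode_sequences
#' @param seq A single shell sequence.
#' @export
encode_sequence <- function(seq, shell, scheme = encoding_scheme()) {
  drop(encode_sequences(seq[1L], shell, scheme))
}

#' Single point mutant
#'
#' Returns a copy of `seq` substituted at one uniformly chosen position with
#' a uniformly chosen different residue, so the Hamming distance to the input
#' is exactly 1. Uses R's global RNG; seed with [set.seed()] for
#' reproducibility.
#'
#' @param seq A shell sequence.
#' @param shell A [design_shell()].
#' @return The mutated sequence.
#' @export
point_mutant <- function(seq, shell) {
  idx <- seqs_to_idx(seq, shell)[1L, ]
  pos <- if (shell$n == 1L) 1L else sample.int(shell$n, 1L)
  d <- sample.int(19L, 1L)
  cur <- idx[pos]
  idx[pos] <- if (d >= cur) d + 1L else d  # uniform over the 19 other residues
  idx_to_seqs(matrix(idx, nrow = 1L), shell)
}

mutate_idx_row <- function(row, k, n) {
  pos <- if (n == 1L) 1L else sample.int(n, k)
  for (p in pos) {
    d <- sample.int(19L, 1L)
    row[p] <- if (d >= row[p]) d + 1L else d
  }
  row
}

#' Random mutant scan around a seed pool
#'
#' Generates `count` random mutants: each draws a seed uniformly from
#' `seed_pool`, a mutation count k uniform on 1..n, k distinct positions, and
#' for each a uniformly chosen different residue (identity substitutions are
#' excluded, so each mutant truly differs from its seed at k positions).
#' This is the scan that feeds the surrogate screen in the optimizer.
#'
#' @param seed_pool Non-empty character vector of shell sequences.
#' @param count Number of mutants to generate (>= 1).
#' @param shell A [design_shell()].
#' @return Character vector of `count` mutant sequences.
#' @export
sample_scan_mutants <- function(seed_pool, count, shell) {
  if (length(seed_pool) < 1L) stop("seed pool is empty")
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1")
  idx_to_seqs(scan_mutants_idx(seqs_to_idx(seed_pool, shell), count, shell),
              shell)
}

## compiled kernel; its RNG stream is seeded from R's RNG so results are
## reproducible under set.seed()
scan_mutants_idx <- function(seed_idx, count, shell) {
  cseed <- sample.int(2147483646L, 1L)
  scan_mutants_cpp(seed_idx, as.integer(count), length(shell$alphabet), cseed)
}

#' Pairwise sequence identity
#'
#' Fraction of matching positions between two equal-length sequences.
#'
#' @param a,b Shell sequences of equal length.
#' @return Identity in \[0, 1\].
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b), ")")
  mean(utf8ToInt(a) == utf8ToInt(b))
}

hamming_dist <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

#' Greedy redundancy filter
#'
#' Scans the input in order and retains a sequence only if its identity to
#' every already-retained sequence is at most `max_identity` (first
#' occurrence wins; deterministic). This is the construction used to derive
#' non-redundant training sets with a pairwise identity ceiling.
#'
#' @param seqs Character vector of equal-length sequences.
#' @param max_identity Identity ceiling in \[0, 1\] (e.g. 0.7).
#' @return The retained subset, in input order.
#' @export
nonredundant_subset <- function(seqs, max_identity) {
  if (length(seqs) == 0L) return(character(0L))
  len <- nchar(seqs)
  if (any(len != len[1L])) stop("sequences differ in length")
  M <- matrix(unlist(lapply(seqs, utf8ToInt), use.names = FALSE),
              ncol = len[1L], byrow = TRUE)
  keep <- integer(0L)
  for (i in seq_along(seqs)) {
    if (length(keep)) {
      ids <- rowMeans(M[keep, , drop = FALSE] ==
                        rep(M[i, ], each = length(keep)))
      if (any(ids > max_identity)) next
    }
    keep <- c(keep, i)
  }
  seqs[keep]
}

#' Minimum mutation count to a pool
#'
#' Minimum Hamming distance between `seq` and any member of `pool` — the
#' number of newly introduced mutations of a candidate relative to its
#' iteration's pool.
#'
#' @param seq A shell sequence.
#' @param pool Non-empty character vector of equal-length sequences.
#' @return Non-negative integer.
#' @export
min_mutations_to_pool <- function(seq, pool) {
  if (length(pool) < 1L) stop("pool is empty")
  s <- utf8ToInt(seq)
  if (any(nchar(pool) != length(s))) stop("sequences differ in length")
  min(vapply(pool, function(p) sum(utf8ToInt(p) != s), integer(1L),
             USE.NAMES = FALSE))
}
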