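## Per-state surrogate networks: a 4-layer fully connected feed-forward net
## per state (input 20n for one-hot, hidden 10 + 20n/2 and 5 + 20n/4, one
## linear output; tanh hidden activations; no bias in any layer), trained by
## minibatch SGD with momentum on z-scored exact scores.

#' Surrogate network layer widths
#'
#' Layer widths as a function of the design-shell size: input
#' `feature_width * n`, first hidden `10 + input/2`, second hidden
#' `5 + input/4` (floored when fractional), one linear output.
#'
#' @param n Number of design-shell positions.
#' @param feature_width Features per position (20 one-hot, 5 physchem).
#' @return List with `input`, `hidden1`, `hidden2`, `output`.
#' @export
network_spec <- function(n, feature_width = 20L) {
  input <- as.integer(feature_width) * as.integer(n)
  list(input = input,
       hidden1 = 10L + input %/% 2L,
       hidden2 = 5L + input %/% 4L,
       output = 1L)
}

init_network <- function(spec, sd = 0.05) {
  list(W1 = matrix(rnorm(spec$input * spec$hidden1, sd = sd),
                   spec$input, spec$hidden1),
       W2 = matrix(rnorm(spec$hidden1 * spec$hidden2, sd = sd),
                   spec$hidden1, spec$hidden2),
       W3 = matrix(rnorm(spec$hidden2, sd = sd), spec$hidden2, 1L))
}

#' Build an untrained surrogate ensemble
#'
#' One network per state, all with the widths of [network_spec()] and
#' random-normal initial weights (sd 0.05).
#'
#' @param shell A [design_shell()].
#' @param m Number of states.
#' @param scheme An [encoding_scheme()].
#' @param seed Optional integer seed for weight initialization.
#' @return An object of class `surrogate_ensemble` (untrained).
#' @export
build_surrogate <- function(shell, m, scheme = encoding_scheme(),
                            seed = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  spec <- network_spec(shell$n, scheme$feature_width)
  networks <- with_seed(seed, lapply(seq_len(m), function(i)
    init_network(spec)))
  structure(
    list(networks = networks, transforms = vector("list", m),
         shell = shell, scheme = scheme, spec = spec, m = m,
         trained = FALSE, train_mse = rep(NA_real_, m)),
    class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("surrogate_ensemble:", x$m, "state network(s), widths",
      paste(unlist(x$spec), collapse = " / "),
      if (x$trained) "(trained)\n" else "(untrained)\n")
  invisible(x)
}

#' z-score standardization of training targets
#'
#' Exact scores are converted to z-scores (population mean/SD) before
#' training; the returned transform inverts predictions back to score units.
#'
#' @param values Numeric vector, length >= 2, non-constant.
#' @return List with `values` (standardized) and `transform` (class
#'   `standardization`, fields `mean` and `sd`).
#' @export
standardize_targets <- function(values) {
  if (length(values) < 2L)
    stop("need at least 2 values to standardize")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))  # population SD
  if (!is.finite(sigma) || sigma < 1e-12)
    stop("targets are constant; standardization is degenerate")
  list(values = (values - mu) / sigma,
       transform = structure(list(mean = mu, sd = sigma),
                             class = "standardization"))
}

standardize_apply <- function(transform, x) (x - transform$mean) / transform$sd
destandardize <- function(transform, z) z * transform$sd + transform$mean

#' Training configuration for the surrogate
#'
#' Defaults: 100 epochs of minibatch SGD (batch 32, shuffled each epoch)
#' with learning rate 0.01 and momentum 0.9, warm-started from the previous
#' iteration's weights ("incremental" retraining over the full archive).
#'
#' @param epochs Training epochs per fit.
#' @param learning_rate SGD learning rate.
#' @param momentum Momentum coefficient.
#' @param batch_size Minibatch size.
#' @param warm_start Reuse previous weights (TRUE) or re-initialize each fit.
#' @return A `training_config`.
#' @export
training_config <- function(epochs = 100L, learning_rate = 0.01,
                            momentum = 0.9, batch_size = 32L,
                            warm_start = TRUE) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 warm_start = isTRUE(warm_start)),
            class = "training_config")
}

archive_ts_matrix <- function(archive, m) {
  if (is.data.frame(archive)) {
    cols <- paste0("ts.", seq_len(m))
    missing <- cols[!cols %in% colnames(archive)]
    if (length(missing))
      stop("training set lacks per-state score column(s): ",
           paste(missing, collapse = ", "))
    ts <- as.matrix(archive[, cols, drop = FALSE])
    seqs <- archive$sequence
  } else {
    ts <- archive$ts
    seqs <- archive$sequences
    if (is.null(ts) || is.null(seqs))
      stop("training set must carry sequences and per-state scores")
    if (ncol(ts) != m)
      stop("training set has ", ncol(ts), " states, ensemble expects ", m)
  }
  for (k in seq_len(m))
    if (anyNA(ts[, k]))
      stop("missing scores for state ", k)
  list(seqs = seqs, ts = ts)
}

#' Fit the surrogate ensemble on an archive of scored sequences
#'
#' Each state's network is fitted to that state's z-scored exact scores for
#' `cfg$epochs` epochs. With `warm_start = TRUE` training resumes from the
#' current weights; otherwise weights are re-initialized. Standardization is
#' refit from the supplied archive, per state. Uses R's global RNG (epoch
#' shuffling and any re-initialization), so fits are reproducible under
#' [set.seed()].
#'
#' @param ensemble A [build_surrogate()] ensemble.
#' @param archive Scored sequences: either a data frame with columns
#'   `sequence`, `ts.1` .. `ts.m` (as returned by [evaluate_landscape()]) or
#'   a list with `sequences` and an N x m `ts` matrix.
#' @param cfg A [training_config()].
#' @return The trained ensemble.
#' @export
fit_surrogate <- function(ensemble, archive, cfg = training_config()) {
  dat <- archive_ts_matrix(archive, ensemble$m)
  if (length(dat$seqs) < 2L) stop("need at least 2 scored sequences to fit")
  X <- encode_sequences(dat$seqs, ensemble$shell, ensemble$scheme)
  for (k in seq_len(ensemble$m)) {
    std <- standardize_targets(dat$ts[, k])
    net <- if (cfg$warm_start) ensemble$networks[[k]] else
      init_network(ensemble$spec)
    cseed <- sample.int(2147483646L, 1L)
    fit <- mlp_train_cpp(X, std$values, net$W1, net$W2, net$W3,
                         cfg$epochs, cfg$learning_rate, cfg$momentum,
                         cfg$batch_size, cseed)
    ensemble$networks[[k]] <- fit
    ensemble$transforms[[k]] <- std$transform
    ensemble$train_mse[k] <- mlp_mse_cpp(X, std$values,
                                         fit$W1, fit$W2, fit$W3)
  }
  ensemble$trained <- TRUE
  ensemble
}

predict_rs_idx <- function(ensemble, idx) {
  X <- encode_idx(idx, ensemble$scheme)
  per_state <- matrix(NA_real_, nrow(X), ensemble$m)
  for (k in seq_len(ensemble$m)) {
    net <- ensemble$networks[[k]]
    z <- as.numeric(mlp_predict_cpp(X, net$W1, net$W2, net$W3))
    per_state[, k] <- destandardize(ensemble$transforms[[k]], z)
  }
  list(rs_nn = rowMeans(per_state), per_state = per_state)
}

#' Predict multi-state scores with the surrogate
#'
#' Each state's network output is de-standardized back to score units, then
#' the m per-state predictions are averaged, mirroring the exact multi-state
#' aggregate. Deterministic given the trained weights; batch order is
#' preserved.
#'
#' @param ensemble A trained [surrogate_ensemble][build_surrogate()].
#' @param seqs Character vector of shell sequences.
#' @return Numeric vector of predicted scores, with the N x m per-state
#'   predictions attached as attribute `"per_state"`.
#' @export
predict_rs <- function(ensemble, seqs) {
  if (!isTRUE(ensemble$trained))
    stop("surrogate ensemble is untrained; call fit_surrogate() first")
  out <- predict_rs_idx(ensemble, seqs_to_idx(seqs, ensemble$shell))
  structure(out$rs_nn, per_state = out$per_state)
}
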