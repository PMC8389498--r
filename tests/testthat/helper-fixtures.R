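# Shared fixtures: tiny design shells and landscapes, built in code.

make_shell <- function(n, wt = NULL) {
  if (is.null(wt)) wt <- rep(aa_alphabet()[1:10], length.out = n)
  design_shell(sprintf("p%d", seq_len(n)), wt)
}

# epistatic study landscape family used across optimizer tests
make_landscape <- function(shell, m = 3, seed = 1, ...) {
  synthetic_landscape(shell, m = m, seed = seed, ...)
}

# small, fast protocol configuration
fast_config <- function(protocol, s = 12L, Z = 400L, max_iterations = 5L,
                        ...) {
  protocol_config(protocol, s = s, Z = Z, max_iterations = max_iterations,
                  stop_on_plateau = FALSE, ...)
}

# short training so unit tests stay fast; the production default is 100
fast_training <- function(epochs = 30L) training_config(epochs = epochs)

# independent reference: mean of per-position frequency-vector distances
brute_mean_dist <- function(fa, fb) {
  mean(sapply(seq_len(nrow(fa)), function(p) sqrt(sum((fa[p, ] - fb[p, ])^2))))
}
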