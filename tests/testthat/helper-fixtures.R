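# Small cohort specifications shared across tests.

tiny_spec <- function(..., seed = 1L) {
  cohort_spec(n_responders = 2L, n_nonresponders = 3L, roi_radius = 3L,
              seed = seed, ...)
}

noiseless_spec <- function(..., seed = 1L) {
  cohort_spec(n_responders = 1L, n_nonresponders = 1L, roi_radius = 4L,
              noise_dce = 0, snr_dwi = Inf, seed = seed, ...)
}

# selection fixture: informative + constant + duplicated columns
# (10 informative survivors expected)
selection_fixture <- function(n = 24L, seed = 42L) {
  set.seed(seed)
  informative <- matrix(rnorm(n * 10L, sd = 2), n, 10L,
                        dimnames = list(NULL, sprintf("feat%02d", 1:10)))
  constant <- matrix(rep(c(0, 1, 2.5, -3, 7), each = n), n, 5L,
                     dimnames = list(NULL, sprintf("const%d", 1:5)))
  # exact linear copies at half scale: r = 1, lower variance
  dup <- informative[, 1:5] * 0.5 + 3
  colnames(dup) <- sprintf("dup%d", 1:5)
  cbind(informative, constant, dup)
}
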