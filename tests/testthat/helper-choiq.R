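# Shared fixtures and independent oracles.

# Exhaustive pair-count AUC: the independent oracle for the Mann-Whitney
# estimator. Counts every (absent, present) pair, ties as 1/2.
auc_pair_count <- function(absent, present) {
  wins <- outer(absent, present, function(a, p) (p > a) + 0.5 * (p == a))
  mean(wins)
}

# Small default-design dataset, cheap enough for many tests.
tiny_config <- function(seed = 101L, ...) {
  synthetic_config(roi_size_px = 16L, n_signal_absent = 20L,
                   n_signal_present = 10L, noise_sd_hu = 10, seed = seed, ...)
}

# White-noise image stack (n x npix) without the config machinery.
white_stack <- function(n, n_px, sd = 10) {
  matrix(rnorm(n * n_px * n_px, sd = sd), n, n_px * n_px)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected), .Machine$double.eps),
            tol)
}
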