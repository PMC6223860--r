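stopifnot_scalar_num <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (integer && x != as.integer(x))
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  invisible(x)
}

# Run code with a private RNG stream seeded from `seed`, restoring the caller's
# RNG state afterwards so dataset generation never perturbs user simulations.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Unshifted DFT frequencies in cycles/sample for an N-point axis:
# 0, 1/N, ..., then negative frequencies, matching stats::fft ordering.
dft_freqs <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k < n / 2, k, k - n) / n
}

# Radial spatial-frequency magnitude (cycles/pixel) on the unshifted 2-D grid.
radial_freq_grid <- function(n) {
  f <- dft_freqs(n)
  sqrt(outer(f^2, f^2, `+`))
}
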