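test_that("ddog_response matches the closed form", {
  p <- channel_params()
  for (j in c(1L, 4L, 10L)) expect_identical(ddog_response(0, j, p), 0)
  # at rho = sigma_j the response is Q-only: exp(-1/(2 Q^2)) - exp(-1/2)
  const <- exp(-1 / (2 * 1.67^2)) - exp(-0.5)
  sig <- 0.005 * 1.4^(0:9)
  for (j in c(1L, 5L, 10L))
    expect_equal(ddog_response(sig[j], j, p), const, tolerance = 1e-12)
  # geometric width sequence (frozen from independent evaluation)
  expect_equal(sig[2], 0.007, tolerance = 1e-12)
  expect_equal(sig[10], 0.1033052339, tolerance = 1e-8)
  expect_error(ddog_response(0.1, 11L, p), "out of range")
  expect_error(ddog_response(-0.1, 1L, p), "rho")
})

test_that("channel bank templates are zero-DC, real and radially symmetric", {
  bank <- build_channel_bank(32)
  expect_identical(dim(bank$U), c(1024L, 10L))
  for (j in 1:10) {
    u <- matrix(bank$U[, j], 32, 32)
    expect_lt(abs(sum(u)), 1e-10 * sqrt(sum(u^2)))
    # symmetry: transpose and index negation (DFT wrap) leave u unchanged
    expect_lt(max(abs(u - t(u))), 1e-10)
    neg <- u[c(1, 32:2), c(1, 32:2)]
    expect_lt(max(abs(u - neg)), 1e-10)
    expect_identical(bank$freq_responses[1, 1, j], 0)
  }
})

test_that("spatial channelisation equals the frequency-domain inner product", {
  bank <- build_channel_bank(16)
  set.seed(31)
  g <- matrix(rnorm(256), 16, 16)
  v_spatial <- as.numeric(channelize(g, bank))
  G <- fft(g)
  # Parseval: sum(u * g) = Re(sum(C * Conj(G))) / N^2, and fft(u_j) = C_j
  v_freq <- vapply(1:10, function(j)
    Re(sum(bank$freq_responses[, , j] * Conj(G))) / 256, numeric(1))
  expect_rel_equal(v_spatial, v_freq, 1e-8)
})

test_that("channelize is linear, offset-invariant and size-checked", {
  bank <- build_channel_bank(16)
  set.seed(32)
  g1 <- matrix(rnorm(256), 16, 16); g2 <- matrix(rnorm(256), 16, 16)
  v12 <- as.numeric(channelize(3 * g1 - 2 * g2, bank))
  v_lin <- 3 * as.numeric(channelize(g1, bank)) - 2 * as.numeric(channelize(g2, bank))
  expect_rel_equal(v12, v_lin, 1e-10)
  # constant offsets vanish through zero-DC channels
  v_off <- as.numeric(channelize(g1 + 500, bank))
  expect_lt(max(abs(v_off - as.numeric(channelize(g1, bank)))),
            1e-8 * 500 * max(sqrt(colSums(bank$U^2))))
  expect_error(channelize(matrix(0, 8, 8), bank), "ROI size")
  expect_error(channelize(list(roi_image(matrix(0, 8, 8), 1, "signal_absent")),
                          bank), "8x8")
})

test_that("sinusoid responses agree with the brute-force frequency oracle", {
  bank <- build_channel_bank(64)
  p <- bank$params
  x <- 0:63
  # oracle: at a pure frequency k/64 the winning channel is the one whose
  # analytic response C_j is largest there (brute force over channels)
  for (k in c(2L, 4L, 6L, 8L, 12L)) {
    expected <- which.max(vapply(1:10, function(j)
      ddog_response(k / 64, j, p), numeric(1)))
    g <- cos(2 * pi * k * x / 64) %o% rep(1, 64)
    resp <- abs(as.numeric(channelize(g, bank)))
    expect_identical(which.max(resp), expected)
  }
  # and the top channels do win at their own (grid-snapped) peak frequency
  for (j in c(9L, 10L)) {
    sj <- p$sigma0 * p$alpha^(j - 1)
    rho_star <- sj * p$Q * sqrt(2 * log(p$Q^2) / (p$Q^2 - 1))  # d/drho = 0
    k <- round(rho_star * 64)
    expect_identical(which.max(vapply(1:10, function(jj)
      ddog_response(k / 64, jj, p), numeric(1))), j)
  }
})

test_that("covariance estimation matches hand and Monte-Carlo references", {
  expect_identical(estimate_covariance(rbind(c(1, 0), c(-1, 0))),
                   matrix(c(2, 0, 0, 0), 2))
  expect_identical(estimate_covariance(matrix(3, 5, 2)), matrix(0, 2, 2))
  expect_error(estimate_covariance(matrix(1, 1, 2)), "at least 2")
  # known generating covariance, 50,000 draws, 3 standard errors entrywise
  set.seed(33)
  A <- matrix(c(2, 0.5, 0, 1), 2)
  K_true <- A %*% t(A)
  x <- matrix(rnorm(2 * 50000), ncol = 2) %*% t(A)
  K_hat <- estimate_covariance(x)
  se <- sqrt((K_true^2 + tcrossprod(diag(K_true))) / 50000)
  expect_true(all(abs(K_hat - K_true) < 3 * se))
})

test_that("theoretical channelised signal is linear and non-degenerate", {
  bank <- build_channel_bank(64)
  v0 <- theoretical_signal_channelised(bank, 5, 370 / 512, 0)
  expect_identical(v0, rep(0, 10))
  v1 <- theoretical_signal_channelised(bank, 5, 370 / 512, 1)
  v2 <- theoretical_signal_channelised(bank, 5, 370 / 512, 2)
  expect_rel_equal(v2, 2 * v1, 1e-12)
  sig_norm <- sqrt(sum(make_gaussian_signal(64, 370 / 512, 5, 1)^2))
  expect_gt(max(abs(v1)), 1e-6 * sig_norm)
  expect_warning(theoretical_signal_channelised(bank, 5, 4), "aliasing")
})

test_that("build_template solves the regularised system", {
  v <- c(2, 4)
  expect_equal(as.numeric(build_template(diag(2), v)), v, tolerance = 1e-12)
  expect_equal(as.numeric(build_template(diag(c(2, 4)), v)), c(1, 1),
               tolerance = 1e-12)
  K_sing <- matrix(c(2, 0, 0, 0), 2)
  expect_error(build_template(K_sing, v), "singular")
  # a ridge rescues the singular case
  w <- build_template(K_sing, v, ridge = 1)
  expect_equal(as.numeric((K_sing + diag(1, 2)) %*% w), v, tolerance = 1e-10)
  expect_error(build_template(matrix(c(1, 2, 3, 4), 2), v), "symmetric")
})

test_that("decision variables are template dot products", {
  v <- rbind(c(3, 5, 1), c(0, 2, 2))
  s <- decision_variables(c(1, 0, 0), v, v)
  expect_identical(s$lambda_absent, c(3, 0))
  s0 <- decision_variables(c(0, 0, 0), v, v)
  expect_identical(s0$lambda_present, c(0, 0))
  expect_error(decision_variables(c(1, 0), v, v), "dimension")
})

test_that("scores are invariant to channel recombination and image scale", {
  cfg <- tiny_config()
  m <- generate_image_matrix(cfg)
  # sigma0 widened: the default 0.005 cycles/px channels have no support on
  # a 16-px DFT grid (first bin 1/16), which makes K numerically singular
  bank <- build_channel_bank(16, channel_params(sigma0 = 0.02))
  lab <- attr(m, "labels")
  v <- unclass(channelize(m, bank))
  va <- v[lab == "signal_absent", ]; vp <- v[lab == "signal_present", ]
  K <- estimate_covariance(va)
  vt <- theoretical_signal_channelised(bank, 5, cfg$pixel_spacing_mm)
  lam <- decision_variables(build_template(K, vt), va, vp)
  set.seed(34)
  for (rep in 1:5) {
    A <- matrix(rnorm(100), 10)
    K2 <- A %*% K %*% t(A)
    lam2 <- decision_variables(build_template((K2 + t(K2)) / 2, A %*% vt),
                               va %*% t(A), vp %*% t(A))
    expect_rel_equal(lam2$lambda_absent, lam$lambda_absent, 1e-8)
    expect_rel_equal(lam2$lambda_present, lam$lambda_present, 1e-8)
  }
  # image scale c: K scales c^2, w by 1/c^2, lambda by 1/c; AUC unchanged
  v_s <- v * 4
  K_s <- estimate_covariance(v_s[lab == "signal_absent", ])
  lam_s <- decision_variables(build_template(K_s, vt),
                              v_s[lab == "signal_absent", ],
                              v_s[lab == "signal_present", ])
  expect_rel_equal(lam_s$lambda_absent, lam$lambda_absent / 4, 1e-8)
  expect_identical(auc_mann_whitney(lam_s$lambda_absent, lam_s$lambda_present),
                   auc_mann_whitney(lam$lambda_absent, lam$lambda_present))
})

test_that("analytic AUC matches closed forms and Monte-Carlo scores", {
  expect_identical(analytic_cho_auc(diag(3), rep(0, 3)), 0.5)
  expect_equal(analytic_cho_auc(diag(3), c(1, 0, 0)), pnorm(1 / sqrt(2)),
               tolerance = 1e-12)
  expect_error(analytic_cho_auc(diag(c(1, -1)), c(1, 1)), "positive definite")
  # Monte-Carlo oracle: ideal observer on known diagonal Gaussian statistics
  set.seed(35)
  K <- diag(c(0.5, 2, 4))
  v <- c(0.6, 0.8, 0.4)
  w <- solve(K, v)
  n <- 1e6
  lam_a <- matrix(rnorm(3 * n), n, 3) %*% chol(K) %*% w
  lam_p <- (matrix(rnorm(3 * n), n, 3) %*% chol(K) +
              matrix(v, n, 3, byrow = TRUE)) %*% w
  mc_auc <- mean(lam_p > lam_a)     # paired comparison, 1e6 pairs
  expect_equal(analytic_cho_auc(K, v), mc_auc, tolerance = 0.002)
})

test_that("fit_cho supports the mean-signal alternative template", {
  cfg <- tiny_config(seed = 77)
  m <- generate_image_matrix(cfg)
  bank <- build_channel_bank(16, channel_params(sigma0 = 0.02))
  lab <- attr(m, "labels")
  v <- channelize(m, bank)
  va <- unclass(v)[lab == "signal_absent", ]
  vp <- unclass(v)[lab == "signal_present", ]
  m_theo <- fit_cho(va, bank, cfg$pixel_spacing_mm)
  m_mean <- fit_cho(va, bank, cfg$pixel_spacing_mm, signal_mode = "mean",
                    present = vp)
  expect_equal(m_mean$v_theo, colMeans(vp) - colMeans(va), tolerance = 1e-12)
  expect_error(fit_cho(va, bank, cfg$pixel_spacing_mm, signal_mode = "mean"),
               "requires")
  # both templates separate the classes on this easy task
  for (mod in list(m_theo, m_mean)) {
    s <- decision_variables(mod$w, va, vp)
    expect_gt(auc_mann_whitney(s$lambda_absent, s$lambda_present), 0.9)
  }
})
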