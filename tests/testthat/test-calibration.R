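std_logp <- c(0.62, 1.28, 1.81, 2.27, 2.70, 3.5)

test_that("an exact calibration line is recovered with r = 1, s = 0, F = Inf", {
  x <- (std_logp - 1) / 2  # logp = 2x + 1 exactly
  m <- fit_calibration(x, std_logp)
  expect_equal(m$a, 2, tolerance = 1e-10)
  expect_equal(m$b, 1, tolerance = 1e-10)
  expect_equal(m$r, 1, tolerance = 1e-12)
  expect_equal(m$s, 0, tolerance = 1e-10)
  expect_identical(m$F, Inf)
  expect_equal(m$p, 0)
})

test_that("F follows the correlation identity, including the r = 0.9684 case", {
  # pair with sample r rounding to 0.9684 at n = 5: identity gives ~45.23
  tbl <- gliflozin_logp_all()
  ps <- pairwise_stats_table(tbl, pairs = cbind("ALOGP", "MLOGP"))
  expect_equal(round(ps$r, 4), 0.9684)
  expect_equal(ps$F, 3 * ps$r^2 / (1 - ps$r^2), tolerance = 1e-12)
  expect_equal(3 * 0.9684^2 / (1 - 0.9684^2), 45.23, tolerance = 1e-3)
})

test_that("calibration diagnostics satisfy the F/r/s identities on random fits", {
  set.seed(31)
  for (i in 1:50) {
    inst <- random_instance()
    m <- fit_calibration(inst$x, inst$y)
    n <- m$n
    expect_equal(m$F, (n - 2) * m$r^2 / (1 - m$r^2), tolerance = 1e-8)
    syy <- sum((inst$y - mean(inst$y))^2)
    expect_equal(m$s^2, (1 - m$r^2) * syy / (n - 2), tolerance = 1e-8)
    expect_equal(m$p, pf(m$F, 1, n - 2, lower.tail = FALSE), tolerance = 1e-12)
    # oracle agreement
    o <- ols_oracle(inst$x, inst$y)
    expect_equal(m$a, o$slope, tolerance = 1e-10)
    expect_equal(m$b, o$intercept, tolerance = 1e-10)
  }
})

test_that("noisy calibrations recover the true line within Monte-Carlo error", {
  a_true <- 1.2
  b_true <- -0.5
  x <- seq(0.5, 4, length.out = 6)
  set.seed(32)
  est <- t(replicate(100, {
    m <- fit_calibration(x, a_true * x + b_true + rnorm(6, 0, 0.1))
    c(m$a, m$b)
  }))
  expect_lt(abs(mean(est[, 1]) - a_true), 3 * sd(est[, 1]) / sqrt(100))
  expect_lt(abs(mean(est[, 2]) - b_true), 3 * sd(est[, 2]) / sqrt(100))
})

test_that("prediction applies the published calibration line", {
  # published HPLC RP18/methanol coefficients: a = 1.071, b = 0.264
  co <- calibration_coefficients()
  rp18 <- co[co$method == "HPLC.RP18.MeOH", ]
  x <- seq(0, 3, by = 1)
  m <- fit_calibration(x, rp18$slope_a * x + rp18$intercept_b)
  expect_equal(predict_logp(m, 0), 0.264, tolerance = 1e-10)
  expect_equal(predict_logp(m, 4.0), 4.548, tolerance = 1e-10)

  ident <- fit_calibration(c(0, 1, 2), c(0, 1, 2))
  expect_equal(predict_logp(ident, 2.5), 2.5, tolerance = 1e-10)

  pred <- predict_logp(m, c(1, 10), flag_range = TRUE)
  expect_identical(attr(pred, "extrapolated"), c(FALSE, TRUE))
})

test_that("back-fit residuals sum to zero and match the oracle", {
  x <- (std_logp - 1) / 2
  m <- fit_calibration(x, std_logp, compound = paste0("S", 1:6))
  expect_equal(backfit_residuals(m)$residual, rep(0, 6), tolerance = 1e-10)

  set.seed(33)
  for (i in 1:10) {
    inst <- random_instance()
    m <- fit_calibration(inst$x, inst$y)
    res <- backfit_residuals(m)
    expect_lt(abs(sum(res$residual)), 1e-10)
    o <- ols_oracle(inst$x, inst$y)
    expect_equal(res$residual, -o$residuals, tolerance = 1e-10)
  }
  expect_error(
    backfit_residuals(fit_calibration(x, std_logp, compound = paste0("S", 1:6)),
                      tibble::tibble(compound = "S9", logp_lit = 1)),
    "S9"
  )
})

test_that("affine rescaling of the index changes (a, b) but not r, s, F or predictions", {
  set.seed(34)
  inst <- random_instance()
  m0 <- fit_calibration(inst$x, inst$y)
  c_ <- 2.5
  d_ <- -1.3
  m1 <- fit_calibration(c_ * inst$x + d_, inst$y)
  expect_equal(m1$a, m0$a / c_, tolerance = 1e-10)
  expect_equal(m1$b, m0$b - m0$a * d_ / c_, tolerance = 1e-10)
  expect_equal(m1$r, m0$r, tolerance = 1e-12)
  expect_equal(m1$s, m0$s, tolerance = 1e-10)
  expect_equal(m1$F, m0$F, tolerance = 1e-6)
  expect_equal(m1$p, m0$p, tolerance = 1e-10)
  expect_equal(predict_logp(m1, c_ * inst$x + d_), predict_logp(m0, inst$x),
               tolerance = 1e-10)
})

test_that("degenerate or undersized calibrations error out", {
  expect_error(fit_calibration(rep(1, 4), std_logp[1:4]), "Degenerate")
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "3 standards")
})
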