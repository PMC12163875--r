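# closed-form normal-equations oracle, independent of the lm-based path
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

test_that("exact collinear points give an exact fit", {
  f <- fit_line(c(0, 5, 10), c(2, 4, 6))
  expect_equal(f$slope, 0.4)
  expect_equal(f$intercept, 2)
  expect_equal(f$r2, 1)
  expect_equal(f$s_yx, 0)
  expect_equal(coef(f), c(intercept = 2, slope = 0.4))
  expect_equal(predict(f, 20), 10)
  expect_error(fit_line(c(3, 3, 3), c(1, 2, 3)), "singular")
})

test_that("fit_line matches the normal-equations oracle on random designs", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    n <- sample(3:10, 1)
    x <- round(runif(n, 0, 50), 2)
    if (length(unique(x)) < 2) next
    y <- rnorm(n, 1 + 0.3 * x, 2)
    f <- fit_line(x, y)
    o <- ols_oracle(x, y)
    worst <- max(worst, abs(f$slope - o["slope"]),
                 abs(f$intercept - o["intercept"]))
  }
  expect_lt(worst, 1e-10)
})

test_that("x-intercept extrapolation and its flags follow the fit", {
  f <- fit_line(c(0, 5, 10), c(2, 4, 6))
  q <- qsa_concentration(f)
  expect_equal(q$conc, 5)
  expect_equal(q$sd, 0)     # collinear points: no residual uncertainty
  expect_equal(q$flag, "ok")

  # negative slope -> non-quantifiable, not an exception
  fneg <- fit_line(c(0, 5, 10), c(6, 4, 2))
  qneg <- qsa_concentration(fneg)
  expect_equal(qneg$flag, "neg_slope")
  expect_true(is.na(qneg$conc))

  # negative intercept -> flagged negative concentration
  fnc <- fit_line(c(0, 5, 10), c(-1, 1, 3))
  expect_equal(qsa_concentration(fnc)$flag, "neg_conc")
})

test_that("extrapolation sd matches the Monte-Carlo spread of x-intercepts", {
  # 6-point curves, multiplicative 10% noise, fixed design
  x <- c(0, 5, 10, 15, 20, 25)
  C <- 10
  sdlog <- sqrt(log(1.01))
  est <- numeric(2000); sds <- numeric(2000)
  set.seed(11)
  for (i in seq_along(est)) {
    y <- (C + x) * exp(rnorm(6, -sdlog^2 / 2, sdlog))
    f <- fit_line(x, y)
    q <- qsa_concentration(f)
    est[i] <- q$conc; sds[i] <- q$sd
  }
  expect_equal(median(sds) / sd(est), 1, tolerance = 0.15)
})

test_that("sd shrinks with noise and with a wider addition range", {
  x_narrow <- c(0, 2, 4, 6, 8, 10)
  x_wide <- c(0, 10, 20, 30, 40, 50)
  mk <- function(x, sigma, seed) {
    set.seed(seed)
    qsa_concentration(fit_line(x, 10 + x + rnorm(6, 0, sigma)))$sd
  }
  # residuals orthogonal to the design leave slope/intercept fixed, so the
  # sd is exactly proportional to the noise scale
  set.seed(3)
  e <- residuals(lm(rnorm(6) ~ x_narrow))
  f1 <- qsa_concentration(fit_line(x_narrow, 10 + x_narrow + 1 * e))$sd
  f2 <- qsa_concentration(fit_line(x_narrow, 10 + x_narrow + 0.1 * e))$sd
  expect_equal(f2 / f1, 0.1, tolerance = 1e-9)
  # wider range (larger Sxx) tightens the extrapolation at equal noise
  mean_narrow <- mean(vapply(1:50, function(s) mk(x_narrow, 1, s), 0))
  mean_wide <- mean(vapply(1:50, function(s) mk(x_wide, 1, s), 0))
  expect_lt(mean_wide, mean_narrow)
})

test_that("one-point IS calibration is exact and flags dead IS channels", {
  expect_equal(qis_concentration(0.01, 0.01, 10)$conc, 10)
  expect_equal(qis_concentration(0.02, 0.01, 10)$conc, 20)
  q <- qis_concentration(c(1, 2), c(0, 1), 10)
  expect_true(is.na(q$conc[1]))
  expect_equal(q$flag, c("non_quantifiable", "ok"))
})

test_that("external calibration inverts its own line and flags negatives", {
  ec <- fit_line(c(0, 10, 20), c(1, 3, 5))   # y = 1 + 0.2 x
  expect_equal(qec_concentration(1 + 0.2 * 15, ec)$conc, 15)
  q <- qec_concentration(0.5, ec)   # response below the intercept
  expect_lt(q$conc, 0)
  expect_equal(q$flag, "neg_conc")
  # nonpositive slope is non-quantifiable
  bad <- fit_line(c(0, 10, 20), c(5, 3, 1))
  expect_equal(qec_concentration(2, bad)$flag, "non_quantifiable")
})

test_that("qSA is invariant to common response rescaling; qEC bias equals
           the suppression factor", {
  x <- c(0, 15, 30)
  y <- 0.8 * (12 + x)          # suppression 0.8, gain 1
  for (c_scale in c(0.01, 0.5, 3, 1000)) {
    q <- qsa_concentration(fit_line(x, c_scale * y))
    expect_equal(q$conc, 12, tolerance = 1e-9)
  }
  # suppression-free (solvent-only) calibration y = g*x; a suppressed
  # pixel's response g*s*C inverts to s*C: recovered/true = s
  ec <- fit_line(x, 2 * x)
  for (s in c(0.3, 0.5, 0.9)) {
    resp <- 2 * s * 12
    expect_equal(qec_concentration(resp, ec)$conc / 12, s,
                 tolerance = 1e-9)
  }
})

test_that("lack-of-fit p-values are present only with replicates and are
           well calibrated under the null", {
  # no replicates -> no test
  expect_true(is.na(fit_line(c(0, 5, 10), c(2, 4.1, 6))$lof_pvalue))
  # replicated linear data with pure noise: p uniform; check type-I error
  set.seed(21)
  x <- rep(c(0, 5, 10, 15), each = 3)
  rej <- 0; nrep <- 2000
  for (i in 1:nrep) {
    y <- 1 + 0.5 * x + rnorm(length(x), 0, 0.3)
    p <- fit_line(x, y)$lof_pvalue
    if (p < 0.05) rej <- rej + 1
  }
  # 99% binomial band around 0.05 at 2000 reps
  expect_gt(rej / nrep, 0.05 - 2.576 * sqrt(0.05 * 0.95 / nrep))
  expect_lt(rej / nrep, 0.05 + 2.576 * sqrt(0.05 * 0.95 / nrep))
  # curvature is detected
  y_curved <- 1 + 0.5 * x + 0.05 * x^2
  expect_lt(fit_line(x, y_curved + rnorm(length(x), 0, 0.05))$lof_pvalue,
            0.01)
})
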