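test_that("noiseless power-law data is recovered exactly", {
  x <- c(0.5, 1, 2, 5, 10, 40)
  y <- 10^1 * x^2
  f <- fit_loglog(x, y)
  expect_equal(f$slope, 2, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_error(fit_loglog(1:2, 1:2), "at least 3")
  expect_error(fit_loglog(c(-1, 1, 2), c(1, 2, 3)), "domain error")
})

test_that("through-origin fit uses the closed form sum(xy)/sum(x^2)", {
  f <- fit_through_origin(1:5, 2 * (1:5))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_identical(f$intercept, 0)
  expect_true(all(is.na(f$intercept_ci)))
  expect_equal(fit_through_origin(c(1, 2), c(1, 5))$slope, 11 / 5,
               tolerance = 1e-12)
  expect_equal(fit_through_origin(1:4, rep(0, 4))$slope, 0)
  expect_error(fit_through_origin(rep(0, 3), 1:3), "degenerate")
})

test_that("slope CIs achieve nominal coverage on simulated populations", {
  withr::local_seed(99)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    lx <- runif(60, 0, 3)
    ly <- 2.716 * lx - 4.078 + rnorm(60, 0, 0.15)
    f <- fit_loglog(10^lx, 10^ly)
    hits <- hits + (f$slope_ci[1] <= 2.716 && 2.716 <= f$slope_ci[2])
  }
  expect_gt(hits / reps, 0.89)
  expect_lt(hits / reps, 0.99)
})

test_that("the published equations evaluate and scale as power laws", {
  expect_equal(predict_mass_mch(1e-3), 10^0.215, tolerance = 1e-12)
  expect_equal(predict_mass_mch(1), 10^(0.968 * 3 + 0.215), tolerance = 1e-12)
  expect_equal(predict_mass_ss(60, 40), 10^(2.716 * 2 - 4.078),
               tolerance = 1e-12)
  expect_equal(predict_mass_ss(6, 4), 10^(2.716 - 4.078), tolerance = 1e-12)
  # density power law and monotonicity
  expect_equal(predict_mass_mch(0.02, density = 1500),
               1.5^0.968 * predict_mass_mch(0.02, density = 1000),
               tolerance = 1e-12)
  expect_equal(predict_mass_ss(120, 80), 2^2.716 * predict_mass_ss(60, 40),
               tolerance = 1e-12)
  v <- sort(runif(20, 1e-4, 1))
  expect_true(all(diff(predict_mass_mch(v)) > 0))
  cc <- sort(runif(20, 5, 500))
  expect_true(all(diff(predict_mass_ss(cc, cc)) > 0))
  expect_error(predict_mass_mch(-1), "domain")
  expect_error(predict_mass_ss(0, 10), "domain")
})

test_that("PPE follows both conventions and is scale invariant", {
  expect_equal(ppe(10, 10)$ppe, 0)
  p1 <- ppe(100, 125)
  expect_equal(p1$ppe, 20)
  expect_equal(p1$signed_ppe, 25)
  p2 <- ppe(125, 100)
  expect_equal(p2$ppe, 25)
  expect_equal(p2$signed_ppe, -20)
  expect_equal(ppe(100 * 7, 125 * 7)$ppe, p1$ppe, tolerance = 1e-12)
  expect_error(ppe(-1, 10), "domain")
})

test_that("logged PPE is a sign-preserving log10 with fixed zero", {
  expect_identical(logged_ppe(0), 0)
  expect_equal(logged_ppe(99), 2)
  expect_equal(logged_ppe(-9), -1)
  s <- c(-250, -30, -1, 0, 1, 30, 250)
  expect_equal(logged_ppe(s), -logged_ppe(-s))
  expect_true(all(diff(logged_ppe(s)) > 0))
})

test_that("mean PPE confidence intervals use the t distribution", {
  m <- mean_ppe_ci(c(10, 10, 10))
  expect_equal(m$mean_ppe, 10)
  expect_equal(m$ci95_halfwidth, 0)
  m2 <- mean_ppe_ci(c(0, 20))
  expect_equal(m2$mean_ppe, 10)
  expect_equal(m2$ci95_halfwidth, 127.0620, tolerance = 1e-6)
  expect_error(mean_ppe_ci(5), "at least 2")
})

test_that("subsampling is exhaustive at full n, seeded, and consistent", {
  withr::local_seed(123)
  vals <- abs(rnorm(40, 20, 5))
  full <- subsample_mean_ppe(vals, subsample_n = 40, iterations = 5, seed = 9)
  expect_true(all(abs(full$mean_ppe - mean(vals)) < 1e-12))
  a <- subsample_mean_ppe(vals, 15, 50, seed = 4)
  b <- subsample_mean_ppe(vals, 15, 50, seed = 4)
  expect_identical(a, b)
  big <- subsample_mean_ppe(vals, 15, 1000, seed = 5)
  expect_lt(abs(mean(big$mean_ppe) - mean(vals)) / mean(vals), 0.01)
  expect_error(subsample_mean_ppe(vals, 41, 10), "exceeds")
})

test_that("allometry calls follow the CI-null trichotomy", {
  fit_with_ci <- function(lo, hi) {
    masshull:::new_scaling_fit(mean(c(lo, hi)), 0, c(lo, hi), c(NA, NA),
                               0.9, 0.001, 30, "log10-log10")
  }
  # published examples: mammal circ~length, crocodylian circ~length,
  # fossil robustness~mass
  expect_identical(classify_allometry(fit_with_ci(1.007, 1.069), 1)$verdict,
                   "positive")
  expect_identical(classify_allometry(fit_with_ci(0.896, 1.074), 1)$verdict,
                   "isometry")
  expect_identical(classify_allometry(fit_with_ci(0.034, 0.150), 0)$verdict,
                   "positive")
  # antisymmetry under reflecting the CI about the null
  null <- 1
  for (ci in list(c(1.2, 1.5), c(0.4, 0.8), c(0.9, 1.1))) {
    v1 <- classify_allometry(fit_with_ci(ci[1], ci[2]), null)$verdict
    refl <- sort(2 * null - ci)
    v2 <- classify_allometry(fit_with_ci(refl[1], refl[2]), null)$verdict
    expected <- c(positive = "negative", negative = "positive",
                  isometry = "isometry")[[v1]]
    expect_identical(v2, expected)
  }
})

test_that("robustness is a guarded ratio", {
  expect_equal(robustness(50, 100), 0.5)
  expect_equal(robustness(70, 70), 1)
  expect_error(robustness(-1, 10), "domain")
  expect_error(robustness(10, 0), "domain")
})

test_that("residual diagnostics use Blom positions and detect skew", {
  # symmetric residuals: skewness exactly 0
  expect_equal(masshull:::sample_skewness(c(-1, -0.5, 0.5, 1)), 0)
  # exact fit: all-zero residuals report skewness 0 by convention
  f <- fit_loglog(c(1, 10, 100, 1000), 10^(0.5 * log10(c(1, 10, 100, 1000))))
  d <- residual_diagnostics(f)
  expect_equal(d$skewness, 0)
  expect_equal(d$qq$theoretical,
               qnorm(((1:4) - 3 / 8) / (4 + 1 / 4)))
  # exponential residuals: skewness near 2
  withr::local_seed(31)
  lx <- runif(200, 0, 3)
  ly <- lx + (rexp(200) - 1) * 0.2
  fe <- fit_loglog(10^lx, 10^ly)
  expect_lt(abs(residual_diagnostics(fe)$skewness - 2), 1.0)
})

test_that("tidy and glance summarise fits; JSON round-trips", {
  f <- fit_loglog(c(1, 3, 9, 30, 90), c(2, 5, 13, 33, 95))
  td <- tidy(f)
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(td$conf.low[2] <= f$slope && f$slope <= td$conf.high[2])
  g <- glance(f)
  expect_identical(g$n, 5L)
  path <- withr::local_tempfile(fileext = ".json")
  write_scaling_fits(list(mch_fit = f, ss_fit = ss_reference_fit()), path)
  back <- read_scaling_fits(path)
  expect_equal(back$mch_fit$slope, f$slope, tolerance = 1e-12)
  expect_equal(back$ss_fit$intercept, -4.078)
})
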