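test_that("z-score transform identities", {
  m <- lms_constant(L = 1, M = 100, S = 0.1)
  expect_equal(lms_zscore(m, 5, 110), 1.0)
  expect_equal(lms_zscore(m, 5, 100), 0.0)
  m0 <- lms_constant(L = 0, M = 100, S = 0.1)
  expect_equal(lms_zscore(m0, 5, 100 * exp(0.1)), 1.0)
  expect_equal(lms_zscore(m0, 5, 100), 0.0)
  mneg <- lms_constant(L = -1, M = 100, S = 0.1)
  expect_equal(lms_zscore(mneg, 5, 100), 0.0)
  expect_error(lms_zscore(m, 5, -3), "> 0")
})

test_that("percentile and z-score are exact inverses", {
  for (L in c(-1, 0, 1)) {
    m <- lms_constant(L = L, M = 250, S = 0.15)
    for (a in c(0.03, 0.1, 0.5, 0.9, 0.97)) {
      v <- lms_percentile(m, 10, a)
      expect_equal(lms_zscore(m, 10, v), qnorm(a), tolerance = 1e-10)
    }
    expect_equal(lms_percentile(m, 10, 0.5), 250, tolerance = 1e-12)
  }
  expect_error(lms_percentile(lms_constant(1, 100, 0.1), 5, 1.2), "alpha")
})

test_that("z is continuous in L at 0", {
  me <- lms_constant(L = 1e-8, M = 100, S = 0.1)
  m0 <- lms_constant(L = 0, M = 100, S = 0.1)
  for (y in c(70, 100, 140))
    expect_lt(abs(lms_zscore(me, 5, y) - lms_zscore(m0, 5, y)), 1e-6)
})

test_that("fitting recovers known constant-parameter truth", {
  set.seed(3)
  age <- runif(400, 0, 30)
  # L = 1 truth: y ~ N(100, 10)
  y <- 100 * (1 + 0.1 * rnorm(400))
  m <- fit_lms(y, age)
  # evaluate where the reference is supported (central 90% of ages);
  # spline boundaries carry the usual extra ML variance
  grid <- seq(quantile(age, 0.05), quantile(age, 0.95), length.out = 20)
  expect_true(all(abs(predict(m, grid) / 100 - 1) < 0.03))
  # log-normal truth (L = 0): fitted L close to 0 on average
  Ls <- sapply(1:5, function(s) {
    set.seed(100 + s)
    yy <- 100 * exp(0.15 * rnorm(400))
    mean(peritomorph:::lms_eval(fit_lms(yy, age), grid)$L)
  })
  expect_lt(abs(mean(Ls)), 0.3)
})

test_that("degenerate or invalid inputs are rejected", {
  age <- runif(50, 0, 10)
  expect_error(fit_lms(rep(5, 50), age), "zero variance")
  expect_error(fit_lms(c(-1, runif(49)), age), "positive")
  expect_error(fit_lms(runif(10), runif(10)), "30")
})

test_that("model-simulated data are calibrated against the centiles", {
  set.seed(4)
  age <- runif(500, 0, 40)
  m <- lms_constant(L = 0.5, M = 200, S = 0.12)
  sim <- simulate(m, nsim = 1, seed = 11, ages = age)[[1]]
  p90 <- lms_percentile(m, age, 0.9)
  frac <- mean(sim < p90)
  ci <- qbinom(c(0.0005, 0.9995), 500, 0.9) / 500
  expect_gte(frac, ci[1]); expect_lte(frac, ci[2])
  # z-scores of simulated data are standard normal (KS over 20 seeds)
  rej <- sapply(1:20, function(s) {
    y <- simulate(m, seed = s, ages = age)[[1]]
    ks.test(lms_zscore(m, age, y), "pnorm")$p.value < 0.01
  })
  expect_lte(mean(rej), 0.2)
})

test_that("model methods and serialization round-trip", {
  set.seed(5)
  age <- runif(120, 0, 20)
  y <- 300 * exp(0.2 * rnorm(120))
  m <- fit_lms(y, age)
  expect_s3_class(m, "lms_model")
  expect_output(print(m), "LMS reference model")
  expect_output(print(summary(m)), "Curve values")
  expect_named(coef(m), c("L", "M", "S"))
  expect_length(residuals(m), 120)
  expect_equal(fitted(m), predict(m), tolerance = 1e-12)
  expect_warning(lms_zscore(m, 59, 300), "extrapolating")
  f <- tempfile(fileext = ".json")
  write_lms(m, f)
  m2 <- read_lms(f)
  aa <- c(0.3, 2, 11, 19)
  expect_equal(predict(m2, aa), predict(m, aa), tolerance = 1e-8)
  expect_equal(lms_percentile(m2, aa, 0.9), lms_percentile(m, aa, 0.9),
               tolerance = 1e-8)
  ct <- centile_table(m, ages = aa)
  expect_equal(ct$p50, predict(m, aa), tolerance = 1e-12)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(m))
})
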