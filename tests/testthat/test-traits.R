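test_that("noiseless data are interpolated exactly", {
  set.seed(81)
  d <- synth_bee_population(12, 3, intercept = 259.2, slope = -7.57,
                            bee_sd = 0, resid_sd = 0)
  fit <- fit_freq_trait(d, "wing_length")
  expect_equal(fit$slope, -7.57, tolerance = 1e-6)
  expect_equal(fit$intercept, 259.2, tolerance = 1e-5)
  expect_equal(fit$marginal_r2, 1, tolerance = 1e-6)
})

test_that("a zero-slope truth is not mistaken for a trait effect", {
  set.seed(82)
  d <- synth_bee_population(28, 5, intercept = 200, slope = 0,
                            bee_sd = 5, resid_sd = 10)
  fit <- fit_freq_trait(d, "wing_length")
  se <- sqrt(diag(fit$model$varFix))[2]
  expect_true(abs(fit$slope) < 2.5 * se)   # CI covers 0
  expect_lt(fit$marginal_r2, 0.15)
})

test_that("slope recovery is nearly unbiased at the study size", {
  set.seed(83)
  est <- t(replicate(60, {
    d <- synth_bee_population(28, 5)
    f <- fit_freq_trait(d, "wing_length")
    c(f$slope, f$marginal_r2)
  }))
  expect_lt(abs(mean(est[, 1]) - (-7.57)), 0.05 * 7.57)  # bias < 5%
  expect_true(all(est[, 2] >= 0 & est[, 2] <= 1))
})

test_that("marginal r2 rises as the residual noise shrinks", {
  set.seed(84)
  r2 <- sapply(c(30, 10, 2), function(s) {
    d <- synth_bee_population(28, 5, resid_sd = s, bee_sd = 2)
    fit_freq_trait(d, "wing_length")$marginal_r2
  })
  expect_true(all(diff(r2) > 0))
})

test_that("degenerate trait designs raise explicit errors", {
  d <- synth_bee_population(5, 2)
  d$wing_length <- 10
  expect_error(fit_freq_trait(d, "wing_length"), "no trait variance")
  d2 <- synth_bee_population(2, 3)
  expect_error(fit_freq_trait(d2, "wing_length"), "at least 3 bees")
})

test_that("ANCOVA separates a real tongue effect from a body-size artifact", {
  set.seed(85)
  ## tongue is a noisy copy of wing; frequency driven by wing only
  p_artifact <- replicate(80, {
    d <- synth_bee_population(28, 5, trait = "wing_length")
    d$tongue_length <- d$wing_length + rnorm(nrow(d), 0, 1)[
      as.integer(factor(d$bee_id))]
    an <- ancova_tongue_with_wing(d)
    an$p[an$term == "tongue_length"]
  })
  expect_gte(mean(p_artifact > 0.05), 0.9)

  ## genuinely independent tongue effect
  p_real <- replicate(80, {
    d <- synth_bee_population(28, 5, trait = "tongue_length",
                              intercept = 238.2, slope = -7.96,
                              trait_range = c(5, 14))
    an <- ancova_tongue_with_wing(d)
    an$p[an$term == "tongue_length"]
  })
  expect_gte(mean(p_real < 0.05), 0.9)

  d <- synth_bee_population(10, 2)
  d$tongue_length <- 2 * d$wing_length
  expect_error(ancova_tongue_with_wing(d), "collinear")
})

test_that("weighted mean follows its definition and invariances", {
  expect_equal(weighted_mean(c(100, 200), c(1, 3)), 175)
  expect_equal(weighted_mean(c(3, 7, 11), c(2, 2, 2)), mean(c(3, 7, 11)))
  expect_equal(weighted_mean(42, 5), 42)
  expect_equal(weighted_mean(c(1, 9), c(2, 6)),
               weighted_mean(c(1, 9), c(2, 6) * 1000))
  expect_error(weighted_mean(numeric(0), numeric(0)), "no values")
  expect_error(weighted_mean(c(1, 2), c(1, 0)), "positive")
})

test_that("literature collapsing and the log-linear model recover truth", {
  ## multiple records per species x caste collapse by weighted mean
  lit <- data.frame(
    species = c("a", "a", "b", "c", "d"),
    caste = c("queen", "queen", "worker", "queen", "worker"),
    freq_hz = c(100, 200, 150, 180, 210),
    freq_n = c(1, 3, 2, 1, 1),
    tongue_mm = c(6, 6, 8, 10, 5), tongue_n = 1)
  col <- collapse_literature(lit)
  expect_equal(nrow(col), 4L)
  expect_equal(col$freq_hz[col$species == "a"], 175)

  ## noiseless generation from freq = exp(6 - 0.376 * tongue)
  tongues <- seq(5, 13, length.out = 10)
  gen <- data.frame(species = letters[1:10], caste = "worker",
                    freq_hz = exp(6 - 0.376 * tongues),
                    tongue_mm = tongues)
  fit <- fit_literature_model(gen)
  expect_equal(fit$rate, -0.376, tolerance = 1e-6)
  expect_equal(fit$intercept, 6, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(predict(fit, 8), exp(6 - 0.376 * 8), tolerance = 1e-6)

  gen$tongue_mm <- 7
  expect_error(fit_literature_model(gen), "rank-deficient")
  gen$tongue_mm <- tongues; gen$freq_hz[1] <- -5
  expect_error(fit_literature_model(gen), "log transform")

  ## 4-point toy set vs hand-solved normal equations
  toy <- data.frame(species = letters[1:4], caste = "q",
                    freq_hz = c(120, 150, 200, 260),
                    tongue_mm = c(10, 8, 6, 4))
  f <- fit_literature_model(toy)
  x <- toy$tongue_mm; y <- log(toy$freq_hz)
  b_hand <- (sum(x * y) - 4 * mean(x) * mean(y)) /
    (sum(x^2) - 4 * mean(x)^2)
  a_hand <- mean(y) - b_hand * mean(x)
  expect_equal(f$rate, b_hand, tolerance = 1e-12)
  expect_equal(f$intercept, a_hand, tolerance = 1e-12)
})

test_that("trait prediction from frequency inverts the fitted line", {
  set.seed(86)
  d <- synth_bee_population(10, 3, bee_sd = 0, resid_sd = 0)
  fit <- fit_freq_trait(d, "wing_length")
  ## on the Fig-2-style line: f0 at trait 10 mm maps back to 10 mm
  f10 <- 259.2 - 7.57 * 10
  est <- predict_trait_from_frequency(fit, f10)
  expect_equal(est$trait, 10, tolerance = 1e-4)
  expect_false(est$extrapolated)
  ## round trip predict then invert is the identity
  tr <- c(9, 12.5, 15)
  expect_equal(predict_trait_from_frequency(fit, predict(fit, tr))$trait,
               tr, tolerance = 1e-6)
  ## f0 = intercept maps to trait 0, far outside the fitted range
  est0 <- predict_trait_from_frequency(fit, fit$intercept)
  expect_equal(est0$trait, 0, tolerance = 1e-6)
  expect_true(est0$extrapolated)
  fit$slope <- 0
  expect_error(predict_trait_from_frequency(fit, 200), "zero slope")
})
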