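test_that("noise fit recovers Gaussian parameters from pure noise", {
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(1e5, 5, 2))
    nm <- fitNoiseDistribution(x)
    expect_lt(abs(nm@mean - 5), 0.1)
    expect_lt(abs(nm@sd - 2), 0.1)
  }
})

test_that("noise fit survives a 10% log-normal signal contamination", {
  for (s in 1:5) {
    x <- withr::with_seed(s, c(rnorm(9e4, 5, 2),
                               5 + rlnorm(1e4, log(30), 1)))
    nm <- fitNoiseDistribution(x)
    expect_lt(abs(nm@mean - 5), 0.15)
    expect_lt(abs(nm@sd / 2 - 1), 0.1)
  }
})

test_that("degenerate and left-thin inputs are flagged", {
  expect_error(fitNoiseDistribution(rep(7, 5000)), "degenerate")
  # half-normal sample: the mode sits at the left edge, leaving too
  # few points for a stable mirrored fit
  x <- withr::with_seed(3, abs(rnorm(150)))
  expect_warning(fitNoiseDistribution(x), "fewer than 50")
})

test_that("normalization identities hold at the noise mean and threshold", {
  nm <- methods::new("NoiseModel", mean = 10, sd = 2)
  at_mean <- normalizeArray(10, nm)
  expect_equal(at_mean$normalized, 0)
  expect_equal(at_mean$log10, 0)   # floored at 1 -> log10 = 0
  expect_false(at_mean$expressed)
  at_thr <- normalizeArray(16, nm)  # exactly 3 SD above noise
  expect_equal(at_thr$normalized, 3)
  expect_equal(at_thr$log10, 0.4771213, tolerance = 1e-6)
  expect_true(at_thr$expressed)
  below <- normalizeArray(6, nm)
  expect_lt(below$normalized, 0)
  expect_equal(below$log10, 0)
  expect_false(below$expressed)
})

test_that("normalized pure noise is standard normal to within 0.05", {
  x <- withr::with_seed(4, rnorm(1e5, 40, 7))
  nm <- fitNoiseDistribution(x)
  z <- normalizeArray(x, nm)$normalized
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("normalization is invariant to affine rescaling of a raw array", {
  be <- simulateExpression(expressionSimConfig(n_probes = 8000,
                                               seed = 21))
  raw <- rawValues(be)
  be1 <- normalizeExperiment(be)
  raw2 <- raw
  raw2[, 2] <- 1.9 * raw[, 2] + 11   # rescale one array
  be2 <- normalizeExperiment(BeaconExperiment(raw2, classLabels(be)))
  expect_equal(normalizedValues(be2), normalizedValues(be1),
               tolerance = 1e-8)
  expect_identical(expressedMask(be2), expressedMask(be1))
})

test_that("robust alignment inverts exact affine distortions", {
  z <- withr::with_seed(2, {
    base <- c(rnorm(1500, 0, 1), rlnorm(500, log(40), 1))
    cbind(a1 = base + rnorm(2000, 0, 0.05),
          a2 = base + rnorm(2000, 0, 0.05))
  })
  # identity case: identical arrays stay untouched
  id <- alignArrays(cbind(z[, 1], z[, 1]))
  expect_equal(id$params$slope, c(1, 1), tolerance = 1e-8)
  expect_equal(id$params$intercept, c(0, 0), tolerance = 1e-8)
  # exact affine distortion is inverted
  zd <- z
  zd[, 2] <- 2 * z[, 1] + 1
  al <- alignArrays(zd)
  # reference is the probe-wise median; both arrays map onto a common
  # scale, so the distorted array must coincide with the clean one
  expect_lt(max(abs(al$values[, 2] - al$values[, 1])), 1e-6)
})

test_that("bisquare alignment resists gross outliers where OLS fails", {
  z <- withr::with_seed(7, {
    base <- c(rnorm(1500, 0, 1), rlnorm(500, log(40), 1))
    cbind(a1 = base, a2 = 2 * base + 1)
  })
  out_idx <- withr::with_seed(8, sample.int(2000, 20))
  z[out_idx, 2] <- 100 * abs(z[out_idx, 2]) + 100
  ref <- z[, 1]
  keep <- ref >= 3 | z[, 2] >= 3
  ols <- unname(coef(lm(z[keep, 2] ~ ref[keep]))[2])
  expect_gt(abs(ols / 2 - 1), 0.05)  # OLS slope is pulled off by > 5%
  al <- alignArrays(z)
  rob <- al$params$slope[2] / al$params$slope[1]
  expect_lt(abs(rob / 2 - 1), 0.05)
})

test_that("a second alignment pass changes values only within tolerance", {
  be <- simulateExpression(expressionSimConfig(n_probes = 6000,
                                               seed = 31))
  be <- normalizeExperiment(be)
  z1 <- normalizedValues(be)
  al2 <- alignArrays(z1, expressedMask(be))
  # a second pass re-estimates the median reference, so idempotence
  # holds up to a slope within 1e-3 of unity and an intercept within
  # a tenth of a noise SD of zero
  expect_true(all(abs(al2$params$slope - 1) < 1e-3))
  expect_true(all(abs(al2$params$intercept) < 0.1))
  expect_lt(max(abs(al2$values - z1) /
                  (2e-3 * pmax(abs(z1), 1) + 0.1)), 1)
})

test_that("expression summaries count saturation, truth and emptiness", {
  sat <- makeNormalizedBe(matrix(10, 50, 4),
                          rep(c("class1", "class2"), each = 2))
  expect_identical(expressionSummary(sat)$expressed_in_all, 50L)
  none <- makeNormalizedBe(matrix(1, 50, 4),
                           rep(c("class1", "class2"), each = 2))
  expect_identical(expressionSummary(none)$expressed_in_all, 0L)
  be <- normalizeExperiment(simulateExpression(
    expressionSimConfig(n_probes = 6000, seed = 17)))
  n_expr <- length(truthExpressed(be))
  got <- expressionSummary(be, k = c(10, 20))
  expect_lt(abs(got$expressed_in_all / n_expr - 1), 0.1)
  expect_true(all(got$above_k <= got$expressed_in_all))
})
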