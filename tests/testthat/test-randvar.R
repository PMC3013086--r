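test_that("quantile normalization matches the hand-worked example", {
  m <- cbind(a = c(1, 2, 3), b = c(2, 4, 6))
  out <- quantileNormalize(m)
  expect_equal(unname(out[, "a"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "b"]), c(1.5, 3, 4.5))
  # identical columns are left unchanged
  m2 <- cbind(x = c(5, 1, 3), y = c(5, 1, 3))
  expect_equal(quantileNormalize(m2), m2)
  # column means always equalize
  m3 <- withr::with_seed(1, matrix(rexp(200), 50, 4))
  expect_lt(diff(range(colMeans(quantileNormalize(m3)))), 1e-12)
})

test_that("variance-prior shape is recovered from model-simulated data", {
  a_true <- 2; b_true <- 1.5; d <- 4
  s2 <- withr::with_seed(11, {
    tau <- rgamma(10000, shape = a_true, scale = b_true)
    (1 / tau) * rchisq(10000, d) / d
  })
  prior <- fitVariancePrior(s2, d)
  expect_lt(abs(prior@a / a_true - 1), 0.15)
})

test_that("equal variances collapse to the fixed-variance limit", {
  prior <- fitVariancePrior(rep(2, 500), 4)
  expect_gte(prior@a, 1e6)
  expect_equal(1 / (prior@a * prior@b), 2, tolerance = 1e-9)
  m <- withr::with_seed(2, matrix(rnorm(40), 10, 4))
  res <- rvmTTest(m, c("c1", "c1", "c2", "c2"), prior)
  expect_equal(res$s2_reg, rep(2, 10), tolerance = 1e-4)
})

test_that("without a prior the statistic equals the ordinary pooled t", {
  m <- withr::with_seed(5, matrix(rnorm(60, sd = 2), 10, 6))
  cl <- rep(c("c1", "c2"), each = 3)
  res <- rvmTTest(m, cl, prior = NULL)
  for (i in 1:10) {
    tt <- t.test(m[i, cl == "c2"], m[i, cl == "c1"],
                 var.equal = TRUE)
    expect_equal(res$statistic[i], unname(tt$statistic),
                 tolerance = 1e-12)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("the shrunken variance lies between sample and prior target", {
  prior <- methods::new("VariancePrior", a = 3, b = 0.5,
                        logLik = NA_real_, nGenes = 100L)
  target <- 1 / (3 * 0.5)
  m <- withr::with_seed(3, matrix(rnorm(48, sd = 3), 8, 6))
  res <- rvmTTest(m, rep(c("c1", "c2"), each = 3), prior)
  above <- res$s2 > target
  expect_true(all(res$s2_reg[above] < res$s2[above]))
  expect_true(all(res$s2_reg[above] > target))
  expect_true(all(res$s2_reg[!above] > res$s2[!above]))
})

test_that("nominal 0.001 type-I error holds under model-simulated nulls", {
  d <- 3; n1 <- 2; n2 <- 3
  counts <- vapply(1:3, function(s) {
    m <- withr::with_seed(100 + s, {
      tau <- rgamma(10000, shape = 2, scale = 1)
      sig <- sqrt(1 / tau)
      matrix(rnorm(10000 * 5), 10000, 5) * sig
    })
    prior <- fitVariancePrior(rowVarsPooled(m, n1), d)
    res <- rvmTTest(m, c("c1", "c1", "c2", "c2", "c2"), prior)
    sum(res$p_value < 0.001)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 3))
})

test_that("class comparison recovers planted fold-4 genes as up-regulated", {
  for (s in 1:2) {
    be <- strongSignalStudy(s, n_de = 50, fold_changes = 4)
    rv <- classComparison(be)
    td <- truthDe(be)
    hit <- rv[rv$gene %in% names(td), ]
    expect_true(all(hit$passed_filters))
    expect_true(all(hit$direction == "up"))
  }
})

test_that("a single gene with a huge shift is significant, either direction", {
  m <- matrix(c(1, 1.1, 9, 9.2, 8.9), 1,
              dimnames = list("g", NULL))
  cl <- c("c1", "c1", "c2", "c2", "c2")
  res <- rvmTTest(m, cl, prior = NULL)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$statistic, 0)
  res_dn <- rvmTTest(10 - m, cl, prior = NULL)
  expect_lt(res_dn$statistic, 0)
  expect_equal(res_dn$p_value, res$p_value, tolerance = 1e-12)
})
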