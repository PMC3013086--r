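classes32 <- c("class1", "class1", "class2", "class2", "class2")

test_that("reference group admits ~(1 - alpha) of equal-variance genes", {
  frac <- vapply(1:20, function(s) {
    z <- withr::with_seed(s,
      matrix(rnorm(1000 * 5, mean = 40), 1000, 5))
    be <- makeNormalizedBe(z, classes32)
    rg <- selectReferenceGroup(be)
    length(referenceGeneIds(rg)) / 1000
  }, numeric(1))
  # admitted fraction tracks 1 - f_test_alpha within Monte-Carlo error
  expect_lt(abs(mean(frac) - 0.95), 0.01)
})

test_that("high-variance genes are almost never admitted to the reference", {
  z <- withr::with_seed(3, rbind(
    matrix(rnorm(900 * 5, mean = 40, sd = 1), 900, 5),
    matrix(rnorm(100 * 5, mean = 40, sd = 10), 100, 5)))
  rownames(z) <- sprintf("g%04d", 1:1000)
  be <- makeNormalizedBe(z, classes32)
  rg <- selectReferenceGroup(be)
  n_high <- sum(referenceGeneIds(rg) %in% sprintf("g%04d", 901:1000))
  expect_lte(n_high, 5)
  # pooled SD close to the technical SD of the low-variance genes
  expect_lt(abs(pooledSd(rg) - 1), 0.1)
})

test_that("too few expressed genes raises a reference-too-small error", {
  z <- matrix(1, 50, 5)  # nothing above 3 SD
  be <- makeNormalizedBe(z, classes32)
  expect_error(selectReferenceGroup(be), "too small")
})

test_that("a gene matching the other class mean scores t = 0, p = 1", {
  ref <- unitReference()
  vals <- matrix(c(5, 7, 6, 6, 6), 1,
                 dimnames = list("g1", NULL))  # class1 mean = 6
  res <- associativeTTest(vals, classes32, ref)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("a 10-SD shift against a 1000-residual pool is overwhelming", {
  ref <- unitReference(1000)
  vals <- matrix(c(0, 0, 10, 10.1, 9.9), 1,
                 dimnames = list("g1", NULL))
  res <- associativeTTest(vals, classes32, ref)
  expect_lt(res$p_value, 1e-6)
  # closed-form oracle on the same numbers
  d <- c(10, 10.1, 9.9) - 0
  N <- 1000; df_r <- 999L
  s2p <- (2 * var(d) + df_r * 1) / (2 + df_r)
  t_exp <- mean(d) / sqrt(s2p * (1 / 3 + 1 / 2 + 1 / N))
  expect_equal(res$statistic, t_exp, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_exp), 2 + df_r),
               tolerance = 1e-12)
})

test_that("fold and expression filters exclude boundary cases", {
  tab <- data.frame(
    gene = c("low_fold", "low_expr", "good"),
    mean_class1 = c(30, 4, 30),
    mean_class2 = c(42, 12, 90),
    p_value = c(1e-9, 1e-9, 1e-9))
  tab$fold <- pmax(tab$mean_class2 / tab$mean_class1,
                   tab$mean_class1 / tab$mean_class2)
  out <- applyDeFilters(tab, alpha = 1e-5)
  expect_identical(out$passed_filters,
                   c(FALSE, FALSE, TRUE))  # 1.4-fold and 12-SD excluded
  expect_identical(out$direction, c("up", "up", "up"))
})

test_that("planted strong fold-4 genes are recovered exactly", {
  for (s in 1:3) {
    be <- normalizeExperiment(strongSignalStudy(s, n_de = 50,
                                                fold_changes = 4))
    de <- associativeDE(be)
    expect_setequal(de$gene[de$passed_filters], names(truthDe(be)))
    expect_true(all(de$direction[de$passed_filters] == "up"))
  }
})

test_that("planted DE genes never contaminate the reference group", {
  for (s in 1:3) {
    be <- normalizeExperiment(strongSignalStudy(s))
    de <- associativeDE(be)
    rg <- attr(de, "reference")
    expect_length(intersect(referenceGeneIds(rg),
                            names(truthDe(be))), 0)
  }
})

test_that("pure-null studies yield an empty filtered list almost always", {
  nonempty <- 0L
  for (s in 1:40) {
    be <- normalizeExperiment(simulateExpression(
      expressionSimConfig(n_probes = 3000, n_de = 0, seed = 400 + s)))
    de <- associativeDE(be)
    if (any(de$passed_filters)) nonempty <- nonempty + 1L
  }
  expect_lte(nonempty, 2L)
})

test_that("detection rate is monotone in the planted fold change", {
  folds <- c(1.5, 2, 4, 8)
  rates <- vapply(folds, function(f) {
    hits <- vapply(1:5, function(s) {
      be <- normalizeExperiment(simulateExpression(expressionSimConfig(
        n_probes = 3000, n_de = 40, fold_changes = f,
        signal_log_mean = log(2000), signal_log_sd = 0.4,
        seed = 50 + s)))
      de <- associativeDE(be)
      mean(names(truthDe(be)) %in% de$gene[de$passed_filters])
    }, numeric(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(diff(rates) >= -0.05))
  expect_gt(rates[4], 0.95)
})

test_that("a global intensity rescaling leaves the filtered list unchanged", {
  be <- strongSignalStudy(9)
  de1 <- associativeDE(normalizeExperiment(be))
  be2 <- BeaconExperiment(rawValues(be) * 7.3, classLabels(be))
  de2 <- associativeDE(normalizeExperiment(be2))
  expect_identical(de1$gene[de1$passed_filters],
                   de2$gene[de2$passed_filters])
})
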