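test_that("generators are deterministic under a fixed seed", {
  cfg <- expressionSimConfig(n_probes = 1500, n_de = 10, seed = 42)
  expect_identical(rawValues(simulateExpression(cfg)),
                   rawValues(simulateExpression(cfg)))
  cc <- corpusSimConfig(n_genes = 6, n_abstracts = 25, seed = 42)
  expect_identical(simulateCorpus(cc)$corpus, simulateCorpus(cc)$corpus)
  tc <- treSimConfig(n_genes = 300, n_tres = 5, seed = 42)
  expect_identical(simulateTreTable(tc), simulateTreTable(tc))
})

test_that("raw arrays are right-skewed and unimodal at the noise mode", {
  cfg <- expressionSimConfig(n_probes = 20000, seed = 5)
  be <- simulateExpression(cfg)
  raw <- rawValues(be)
  md <- S4Vectors::metadata(be)
  for (j in seq_len(ncol(raw))) {
    x <- raw[, j]
    # sample skewness is clearly positive
    sk <- mean((x - mean(x))^3) / sd(x)^3
    expect_gt(sk, 1)
    # histogram mode close to the transformed noise mean; restrict the
    # histogram to the noise-dominated range so bins stay narrow
    expected_mode <- cfg$noise_mean * md$array_scales[j] +
      md$array_offsets[j]
    xl <- x[x < quantile(x, 0.6)]
    h <- hist(xl, breaks = 100, plot = FALSE)
    mode_est <- h$mids[which.max(h$counts)]
    expect_lt(abs(mode_est - expected_mode), cfg$noise_sd)
  }
})

test_that("with no expressed probes each array is a plain Gaussian sample", {
  be <- simulateExpression(expressionSimConfig(
    n_probes = 50000, fraction_expressed = 0, n_de = 0, seed = 8))
  x <- rawValues(be)[, 1]
  sk <- mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(sk), 0.05)
})

test_that("planted truth is bookkept and fold changes are honoured", {
  be <- simulateExpression(expressionSimConfig(
    n_probes = 5000, n_de = 50, fold_changes = 4, seed = 13))
  td <- truthDe(be)
  expect_length(td, 50)
  expect_true(all(names(td) %in% truthExpressed(be)))
  expect_true(all(td == 4))
  # class-2 / class-1 ratio of the generated signal component itself
  sig <- S4Vectors::metadata(be)$signal
  cl <- classLabels(be)
  ratio <- rowMeans(sig[names(td), cl == "class2", drop = FALSE]) /
    rowMeans(sig[names(td), cl == "class1", drop = FALSE])
  expect_equal(unname(ratio), rep(4, 50), tolerance = 1e-12)
})

test_that("invalid simulation configs are rejected", {
  expect_error(expressionSimConfig(n_probes = 100, n_de = 90,
                                   fraction_expressed = 0.5), "n_de")
  expect_error(expressionSimConfig(noise_sd = 0), "noise_sd")
  expect_error(expressionSimConfig(fold_changes = c(2, -1)),
               "fold_changes")
  expect_error(corpusSimConfig(background_rate = 1.5), "\\[0, 1\\]")
  expect_error(treSimConfig(background_rates = -0.1), "\\[0, 1\\]")
})

test_that("planted same-sentence links occur at the configured rate", {
  sim <- simulateCorpus(corpusSimConfig(
    n_genes = 2, n_keywords = 1, n_abstracts = 10, background_rate = 0,
    planted_links = list(list(genes = "gene2", keyword = "kw1",
                              rate = 1)), seed = 3))
  # hand count of same-sentence co-mention events
  events <- sum(vapply(sim$corpus, function(a)
    any(vapply(a$sentences, function(s)
      all(c("GENE2", "KW1") %in% toupper(s)), logical(1))),
    logical(1)))
  expect_identical(events, 10L)
  # and the network tallies them at the sentence weight
  net <- buildNetwork(sim$corpus, sim$thesaurus)
  expect_equal(networkWeights(net)["gene2", "kw1"], 10 * 0.8)
})

test_that("the thesaurus carries a hyphenated variant mapping to one id", {
  sim <- simulateCorpus(corpusSimConfig(n_genes = 3, n_abstracts = 5,
                                        seed = 2))
  th <- sim$thesaurus
  g1 <- th$synonym[th$object_id == "gene1"]
  expect_length(g1, 2)
  expect_true(any(grepl("-", g1)))
  hits <- recognizeObjects(list(paste(g1, collapse = " and ")), th)
  expect_identical(hits[[1]], "gene1")
})

test_that("TRE tables honour saturation, null and planted enrichment", {
  sat <- simulateTreTable(treSimConfig(n_genes = 50, n_tres = 4,
                                       background_rates = 1, seed = 1))
  expect_true(all(sat == 1L))
  null <- simulateTreTable(treSimConfig(n_genes = 4000, n_tres = 6,
                                        background_rates = 0.2,
                                        seed = 6))
  expect_true(all(abs(colMeans(null) - 0.2) <
                    3 * sqrt(0.2 * 0.8 / 4000)))
  gs <- sprintf("gene%04d", 1:10)
  m <- simulateTreTable(treSimConfig(
    n_genes = 1000, n_tres = 10, background_rates = 0.05,
    enriched_tre = "TRE1", enriched_gene_set = gs,
    enriched_rate = 0.8, seed = 2))
  cnt <- sum(m[gs, "TRE1"])  # expected 8, Binomial(10, 0.8)
  expect_lt(abs(cnt - 8), 3 * sqrt(10 * 0.8 * 0.2) + 1e-9)
})
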