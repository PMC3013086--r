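test_that("spelling variants collapse to one object", {
  th <- data.frame(object_id = "il2", kind = "gene", synonym = "IL2")
  expect_identical(
    recognizeObjects(list("IL-2 activates T cells"), th)[[1]], "il2")
  expect_identical(recognizeObjects(list("il 2 is absent here"),
                                    th)[[1]], character(0))
  expect_identical(recognizeObjects(list(), th), list())
})

test_that("overlapping matches resolve longest-first", {
  th <- data.frame(object_id = c("klk3", "klk"), kind = "gene",
                   synonym = c("KLK3", "KLK"))
  hits <- recognizeObjects(list("KLK3 is elevated", "and KLK too"), th)
  expect_identical(hits[[1]], "klk3")
  expect_identical(hits[[2]], "klk")
  # each object counts at most once per sentence
  hits2 <- recognizeObjects(list("KLK and KLK and KLK"), th)
  expect_identical(hits2[[1]], "klk")
})

test_that("co-occurrence weights follow the 0.8 / 0.5 per-abstract rule", {
  th <- data.frame(object_id = c("g1", "k1"),
                   kind = c("gene", "phenotype"),
                   synonym = c("GEN1", "KW1"))
  corp <- list(
    list(id = "A1", sentences = list(c("GEN1", "KW1"))),       # 0.8
    list(id = "A2", sentences = list("GEN1", "KW1")))          # 0.5
  net <- buildNetwork(corp, th)
  W <- networkWeights(net)
  expect_equal(W["g1", "k1"], 1.3)
  expect_equal(W, t(W))
  expect_equal(unname(documentFrequency(net)), c(2, 2))
  # removing an abstract never increases a weight; weights are additive
  net1 <- buildNetwork(corp[1], th)
  net2 <- buildNetwork(corp[2], th)
  expect_true(all(networkWeights(net1) <= W))
  expect_equal(networkWeights(net1) + networkWeights(net2), W)
  # a never-co-mentioned pair keeps weight 0
  corp0 <- list(list(id = "A3", sentences = list("GEN1")))
  expect_equal(networkWeights(buildNetwork(corp0, th))["g1", "k1"], 0)
})

test_that("unmentioned genes are discarded and counted", {
  th <- data.frame(object_id = paste0("g", 1:10), kind = "gene",
                   synonym = paste0("SYM", 1:10))
  corp <- list(list(id = "A1",
                    sentences = list(paste0("SYM", 1:7))))
  net <- buildNetwork(corp, th)
  flt <- filterUnmentioned(paste0("g", 1:10), net)
  expect_length(flt$retained, 7)
  expect_identical(flt$n_discarded, 3L)
  expect_identical(filterUnmentioned(character(0), net)$retained,
                   character(0))
})

test_that("Monte-Carlo null matches exhaustive enumeration on a toy corpus", {
  sim <- simulateCorpus(corpusSimConfig(
    n_genes = 8, n_keywords = 3, n_abstracts = 150,
    background_rate = 0.10,
    planted_links = list(list(genes = c("gene1", "gene2", "gene3"),
                              keyword = "kw1", rate = 0.6)),
    seed = 4))
  net <- buildNetwork(sim$corpus, sim$thesaurus)
  cfg <- litnetConfig(n_random_sets = 1000, seed = 9)
  query <- c("gene1", "gene2", "gene3")
  enr <- sharedTermEnrichment(query, net, cfg)
  W <- networkWeights(net)
  genes_all <- paste0("gene", 1:8)
  for (term in intersect(enr$term, paste0("kw", 1:3))) {
    stats <- apply(combn(8, 3), 2,
                   function(ix) sum(W[term, genes_all[ix]]))
    mu <- mean(stats); sdv <- sd(stats)
    row <- enr[enr$term == term, ]
    expect_lt(abs(row$expected - mu), 3 * sdv / sqrt(1000))
    # doubling the null size moves the estimate by < 2 standard errors
    enr2 <- sharedTermEnrichment(query, net,
      litnetConfig(n_random_sets = 2000, seed = 10))
    row2 <- enr2[enr2$term == term, ]
    expect_lt(abs(row2$expected - mu), 3 * sdv / sqrt(2000))
  }
  # determinism under the seed
  expect_identical(enr, sharedTermEnrichment(query, net, cfg))
})

test_that("a strongly planted keyword is called significant", {
  planted <- paste0("gene", 1:5)
  hits <- vapply(1:20, function(s) {
    sim <- simulateCorpus(corpusSimConfig(
      n_genes = 50, n_keywords = 3, n_abstracts = 60,
      background_rate = 0.01,
      planted_links = list(list(genes = planted, keyword = "kw1",
                                rate = 1)),
      seed = 600 + s))
    net <- buildNetwork(sim$corpus, sim$thesaurus)
    enr <- sharedTermEnrichment(planted, net,
      litnetConfig(n_random_sets = 500, seed = s))
    isTRUE(enr$significant[enr$term == "kw1"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate nulls and empty queries are handled", {
  ids <- c(paste0("g", 1:4), "k")
  W <- matrix(0, 5, 5, dimnames = list(ids, ids))
  W["k", paste0("g", 1:4)] <- 1
  W[paste0("g", 1:4), "k"] <- 1
  net <- methods::new("CooccurrenceNetwork", weights = W,
    docFreq = stats::setNames(rep(1, 5), ids),
    objects = data.frame(object_id = ids,
                         kind = c(rep("gene", 4), "phenotype")))
  # every same-size draw gives the same sum: null SD = 0 -> NA z
  enr <- sharedTermEnrichment(c("g1", "g2"), net,
                              litnetConfig(n_random_sets = 200,
                                           seed = 1))
  row <- enr[enr$term == "k", ]
  expect_true(is.na(row$z_score))
  expect_false(row$significant)
  expect_identical(nrow(sharedTermEnrichment(character(0), net)), 0L)
})
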