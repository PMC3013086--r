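#' Configuration for the expression-matrix generator
#'
#' Defines the generative model used by [simulateExpression()]: every
#' probe on every array receives Gaussian background noise
#' (\code{Normal(noise_mean, noise_sd)}); a minority of probes
#' (\code{fraction_expressed}) additionally carry a per-probe log-normal
#' signal, which for planted differentially expressed probes is
#' multiplied by a linear fold change in the second class; each array is
#' finally distorted by its own affine map \code{scale * x + offset} and
#' floored at zero. The resulting per-array raw-intensity histogram is
#' right-skewed and unimodal with its mode at the (transformed) noise
#' mean, the shape the noise-anchored normalization assumes.
#'
#' @param n_probes Number of probes; default 48702, the probe count of
#'   the Illumina HumanWG-6 v2 chip emulated here.
#' @param n_arrays_per_class Integer scalar or length-2 vector of arrays
#'   per class; default \code{c(2, 3)} (2 control clones vs 3
#'   overexpression clones, the design this pipeline targets).
#' @param fraction_expressed Proportion of probes carrying signal, in
#'   \code{[0, 1)}; default 0.25.
#' @param noise_mean,noise_sd Gaussian noise parameters in (arbitrary)
#'   intensity units; defaults 100 and 20. Only relative structure
#'   matters downstream.
#' @param signal_log_mean,signal_log_sd Meanlog/sdlog of the per-probe
#'   log-normal signal; defaults \code{log(800)} and 1, putting the
#'   median expressed probe 40 noise-SD above background.
#' @param n_de Number of planted DE probes (drawn from the expressed
#'   set); default 100.
#' @param fold_changes Linear fold changes (> 0) recycled over the
#'   planted DE probes; folds < 1 plant down-regulation. Default 4.
#' @param array_scales,array_offsets Per-array affine distortion; when
#'   \code{NULL}, scales are drawn uniformly from \code{[0.8, 1.25]} and
#'   offsets from \code{[-0.5, 0.5] * noise_sd}.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{ExpressionSimConfig}.
#' @export
expressionSimConfig <- function(n_probes = 48702L,
                                n_arrays_per_class = c(2L, 3L),
                                fraction_expressed = 0.25,
                                noise_mean = 100, noise_sd = 20,
                                signal_log_mean = log(800),
                                signal_log_sd = 1,
                                n_de = 100L, fold_changes = 4,
                                array_scales = NULL,
                                array_offsets = NULL,
                                seed = 1L) {
  n_probes <- checkCount(n_probes, "n_probes")
  if (length(n_arrays_per_class) == 1L)
    n_arrays_per_class <- rep(n_arrays_per_class, 2L)
  n_arrays_per_class <- vapply(n_arrays_per_class, checkCount,
                               integer(1), name = "n_arrays_per_class")
  checkProb(fraction_expressed, "fraction_expressed")
  if (!is.finite(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (any(fold_changes <= 0)) stop("fold_changes must all be > 0")
  if (n_de < 0 || n_de > fraction_expressed * n_probes)
    stop("n_de must satisfy 0 <= n_de <= fraction_expressed * n_probes")
  n_arrays <- sum(n_arrays_per_class)
  if (!is.null(array_scales)) {
    if (length(array_scales) != n_arrays || any(array_scales <= 0))
      stop("array_scales must be ", n_arrays, " positive values")
  }
  if (!is.null(array_offsets) && length(array_offsets) != n_arrays)
    stop("array_offsets must have one value per array")
  structure(list(n_probes = n_probes,
                 n_arrays_per_class = n_arrays_per_class,
                 fraction_expressed = fraction_expressed,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 signal_log_mean = signal_log_mean,
                 signal_log_sd = signal_log_sd,
                 n_de = as.integer(n_de), fold_changes = fold_changes,
                 array_scales = array_scales,
                 array_offsets = array_offsets,
                 seed = as.integer(seed)),
            class = "ExpressionSimConfig")
}

#' Simulate a two-class expression study with planted truth
#'
#' Generates a raw probe-by-array intensity matrix under the model of
#' [expressionSimConfig()] and records the planted truth (which probes
#' are expressed; which are differentially expressed and at what fold)
#' in the object's metadata. Identical config and seed give bit-identical
#' output.
#'
#' @param config An \code{ExpressionSimConfig}.
#' @return A \linkS4class{BeaconExperiment} with assay \code{"raw"};
#'   \code{metadata()} holds \code{truth_expressed}, \code{truth_de},
#'   \code{signal} (the pre-distortion signal component, for
#'   bookkeeping), and the config.
#' @examples
#' be <- simulateExpression(expressionSimConfig(n_probes = 2000, seed = 7))
#' be
#' length(truthDe(be))
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "ExpressionSimConfig"))
  withSeed(config$seed, {
    npc <- config$n_arrays_per_class
    n_arrays <- sum(npc)
    n <- config$n_probes
    classes <- rep(c("class1", "class2"), times = npc)
    probe_ids <- sprintf("probe_%05d", seq_len(n))
    array_ids <- sprintf("array_%02d", seq_len(n_arrays))

    n_expr <- round(config$fraction_expressed * n)
    expressed <- sort(sample.int(n, n_expr))
    de <- if (config$n_de > 0) sort(sample(expressed, config$n_de))
          else integer(0)
    folds <- rep_len(config$fold_changes, length(de))

    scales <- config$array_scales
    if (is.null(scales)) scales <- runif(n_arrays, 0.8, 1.25)
    offsets <- config$array_offsets
    if (is.null(offsets))
      offsets <- runif(n_arrays, -0.5, 0.5) * config$noise_sd

    noise <- matrix(rnorm(n * n_arrays, config$noise_mean,
                          config$noise_sd), n, n_arrays)
    signal <- matrix(0, n, n_arrays)
    if (n_expr > 0) {
      base <- rlnorm(n_expr, config$signal_log_mean, config$signal_log_sd)
      signal[expressed, ] <- base
      if (length(de))
        signal[de, classes == "class2"] <-
          signal[de, classes == "class2"] * folds
    }
    raw <- noise + signal
    raw <- sweep(sweep(raw, 2L, scales, "*"), 2L, offsets, "+")
    raw <- pmax(raw, 0)
    dimnames(raw) <- list(probe_ids, array_ids)
    dimnames(signal) <- dimnames(raw)

    truth_de <- stats::setNames(folds, probe_ids[de])
    BeaconExperiment(raw, classes, metadata = list(
      truth_expressed = probe_ids[expressed],
      truth_de = truth_de,
      signal = signal,
      array_scales = scales,
      array_offsets = offsets,
      config = config))
  })
}

#' Configuration for the toy literature-corpus generator
#'
#' @param n_genes,n_keywords,n_abstracts Counts of gene objects, keyword
#'   objects and abstracts.
#' @param sentences_per_abstract Sentences emitted per abstract.
#' @param background_rate Probability that any object is mentioned in any
#'   given sentence, independently (the null co-mention structure).
#' @param planted_links List of \code{list(genes =, keyword =, rate =)}
#'   entries: with probability \code{rate} per abstract, the keyword and
#'   the listed genes are co-mentioned in one randomly chosen sentence.
#' @param gene_ids,keyword_ids Optional explicit object ids (e.g. probe
#'   ids from an expression study); defaults \code{gene1..} /
#'   \code{kw1..}.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{CorpusSimConfig}.
#' @export
corpusSimConfig <- function(n_genes = 20L, n_keywords = 5L,
                            n_abstracts = 100L,
                            sentences_per_abstract = 5L,
                            background_rate = 0.05,
                            planted_links = list(),
                            gene_ids = NULL, keyword_ids = NULL,
                            seed = 1L) {
  n_genes <- checkCount(n_genes, "n_genes")
  n_keywords <- checkCount(n_keywords, "n_keywords")
  n_abstracts <- checkCount(n_abstracts, "n_abstracts")
  sentences_per_abstract <- checkCount(sentences_per_abstract,
                                       "sentences_per_abstract")
  checkProb(background_rate, "background_rate")
  for (pl in planted_links) {
    if (!all(c("genes", "keyword", "rate") %in% names(pl)))
      stop("each planted link needs genes, keyword, rate")
    checkProb(pl$rate, "planted link rate")
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(n_genes))
  if (is.null(keyword_ids))
    keyword_ids <- sprintf("kw%d", seq_len(n_keywords))
  stopifnot(length(gene_ids) == n_genes,
            length(keyword_ids) == n_keywords)
  structure(list(n_genes = n_genes, n_keywords = n_keywords,
                 n_abstracts = n_abstracts,
                 sentences_per_abstract = sentences_per_abstract,
                 background_rate = background_rate,
                 planted_links = planted_links,
                 gene_ids = gene_ids, keyword_ids = keyword_ids,
                 seed = as.integer(seed)),
            class = "CorpusSimConfig")
}

#' Simulate a sentence-segmented abstract corpus plus thesaurus
#'
#' Emits abstracts as ordered lists of sentences, each sentence a vector
#' of surface strings, together with a thesaurus mapping object ids to
#' synonyms. The first gene object always carries a hyphenated spelling
#' variant of its name (e.g. \code{"GEN1"} and \code{"GEN-1"}) so that
#' variant-collapsing recognition is exercised. Planted (gene set,
#' keyword) links co-occur in the same sentence at their configured
#' per-abstract rates; all other mentions are independent at
#' \code{background_rate}.
#'
#' @param config A \code{CorpusSimConfig}.
#' @return List with \code{corpus} (list of
#'   \code{list(id, sentences)}), \code{thesaurus} (data.frame
#'   \code{object_id}, \code{kind}, \code{synonym}) and the config.
#' @examples
#' sim <- simulateCorpus(corpusSimConfig(n_genes = 4, n_abstracts = 10,
#'   planted_links = list(list(genes = "gene2", keyword = "kw1",
#'                             rate = 1)), background_rate = 0, seed = 3))
#' sim$corpus[[1]]$sentences
#' @export
simulateCorpus <- function(config) {
  stopifnot(inherits(config, "CorpusSimConfig"))
  withSeed(config$seed, {
    genes <- config$gene_ids
    kws <- config$keyword_ids
    surface <- function(id) toupper(gsub("[^A-Za-z0-9]", "", id))
    thesaurus <- rbind(
      data.frame(object_id = genes, kind = "gene",
                 synonym = surface(genes), stringsAsFactors = FALSE),
      data.frame(object_id = kws, kind = "phenotype",
                 synonym = surface(kws), stringsAsFactors = FALSE))
    # hyphenated spelling variant for the first gene, e.g. GEN1 / GEN-1
    v <- sub("([A-Z]+)([0-9]+)$", "\\1-\\2", surface(genes[1]))
    if (v != surface(genes[1]))
      thesaurus <- rbind(thesaurus,
        data.frame(object_id = genes[1], kind = "gene", synonym = v,
                   stringsAsFactors = FALSE))
    all_ids <- c(genes, kws)
    syn_of <- split(thesaurus$synonym, thesaurus$object_id)

    corpus <- vector("list", config$n_abstracts)
    for (a in seq_len(config$n_abstracts)) {
      sents <- replicate(config$sentences_per_abstract, {
        hit <- all_ids[runif(length(all_ids)) < config$background_rate]
        vapply(hit, function(id) sample(syn_of[[id]], 1L), character(1),
               USE.NAMES = FALSE)
      }, simplify = FALSE)
      for (pl in config$planted_links) {
        if (runif(1) < pl$rate) {
          s <- sample.int(config$sentences_per_abstract, 1L)
          add <- c(pl$genes, pl$keyword)
          add_surf <- vapply(add, function(id) sample(syn_of[[id]], 1L),
                             character(1), USE.NAMES = FALSE)
          sents[[s]] <- unique(c(sents[[s]], add_surf))
        }
      }
      corpus[[a]] <- list(id = sprintf("A%04d", a), sentences = sents)
    }
    list(corpus = corpus, thesaurus = thesaurus, config = config)
  })
}

#' Configuration for the TRE incidence-table generator
#'
#' @param n_genes,n_tres Numbers of genes and transcription-regulatory
#'   elements (TREs).
#' @param background_rates Per-TRE presence probability (scalar recycled
#'   or length \code{n_tres}).
#' @param enriched_tre TRE id (or index) planted as enriched, or
#'   \code{NULL} for a pure-null table.
#' @param enriched_gene_set Gene ids (or indices) of the enriched set.
#' @param enriched_rate Presence probability of the enriched TRE within
#'   the enriched gene set.
#' @param gene_ids Optional explicit gene ids.
#' @param seed Integer RNG seed.
#' @return A validated list of class \code{TRESimConfig}.
#' @export
treSimConfig <- function(n_genes = 1000L, n_tres = 20L,
                         background_rates = 0.05,
                         enriched_tre = NULL, enriched_gene_set = NULL,
                         enriched_rate = NULL, gene_ids = NULL,
                         seed = 1L) {
  n_genes <- checkCount(n_genes, "n_genes")
  n_tres <- checkCount(n_tres, "n_tres")
  checkProb(background_rates, "background_rates")
  if (!is.null(enriched_rate)) checkProb(enriched_rate, "enriched_rate")
  if (!is.null(enriched_tre) && is.null(enriched_rate))
    stop("enriched_tre requires enriched_rate and enriched_gene_set")
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  stopifnot(length(gene_ids) == n_genes)
  structure(list(n_genes = n_genes, n_tres = n_tres,
                 background_rates = rep_len(background_rates, n_tres),
                 enriched_tre = enriched_tre,
                 enriched_gene_set = enriched_gene_set,
                 enriched_rate = enriched_rate,
                 gene_ids = gene_ids, seed = as.integer(seed)),
            class = "TRESimConfig")
}

#' Simulate a binary gene-by-TRE incidence table
#'
#' Each entry indicates whether a TRE occurs within the (notional) 2-kb
#' 5'-flanking region of a gene. Entries are independent Bernoulli draws
#' at the per-TRE background rate, except that the planted enriched TRE
#' is present in the enriched gene set at \code{enriched_rate}.
#'
#' @param config A \code{TRESimConfig}.
#' @return Binary integer matrix, genes in rows (rownames = gene ids),
#'   TREs in columns (\code{TRE1..}); the row universe is the array-wide
#'   background for [treOverrepresentation()].
#' @export
simulateTreTable <- function(config) {
  stopifnot(inherits(config, "TRESimConfig"))
  withSeed(config$seed, {
    m <- vapply(seq_len(config$n_tres), function(j)
      rbinom(config$n_genes, 1L, config$background_rates[j]),
      integer(config$n_genes))
    dimnames(m) <- list(config$gene_ids,
                        sprintf("TRE%d", seq_len(config$n_tres)))
    if (!is.null(config$enriched_tre)) {
      tre <- config$enriched_tre
      if (is.numeric(tre)) tre <- colnames(m)[tre]
      gs <- config$enriched_gene_set
      if (is.numeric(gs)) gs <- rownames(m)[gs]
      m[gs, tre] <- rbinom(length(gs), 1L, config$enriched_rate)
    }
    m
  })
}
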