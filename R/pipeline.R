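#' Full-pipeline configuration
#'
#' Bundles the input source, every stage's configuration and the output
#' directory. One global seed fans out deterministically to per-stage
#' seeds (counter-based), so adding a stage never perturbs the draws of
#' earlier stages. All the pipeline's thresholds (3 SD expression call,
#' 1.5 fold, 20 SD, P < 0.001, TRE P < 0.05 / FDR < 0.3, co-occurrence
#' weights 0.5/0.8, z >= 3) live in the stage configs with those values
#' as defaults.
#'
#' @param input An [expressionSimConfig()] (synthetic study), or
#'   \code{list(expression_tsv =, classes_tsv =)}, or
#'   \code{list(series_matrix =, class_map =)}.
#' @param corpus A [corpusSimConfig()], or
#'   \code{list(corpus_path =, thesaurus_path =)}, or \code{NULL} to
#'   skip the literature stage.
#' @param tre A [treSimConfig()], a TRE-matrix TSV path, or \code{NULL}
#'   to skip the promoter stage.
#' @param normalization,associative,rvm,litnet Stage configurations.
#' @param tre_n_random Resampling size of the TRE null; default 10000.
#' @param out_dir Output directory (created if needed).
#' @param seed Global integer seed.
#' @return A list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(input = expressionSimConfig(),
                           corpus = NULL, tre = NULL,
                           normalization = normalizationConfig(),
                           associative = associativeConfig(),
                           rvm = rvmConfig(),
                           litnet = litnetConfig(),
                           tre_n_random = 10000L,
                           out_dir = tempfile("beacon_run_"),
                           seed = 1L) {
  structure(list(input = input, corpus = corpus, tre = tre,
                 normalization = normalization,
                 associative = associative, rvm = rvm, litnet = litnet,
                 tre_n_random = as.integer(tre_n_random),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

writeTsv <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

#' Run the full analysis pipeline
#'
#' Executes, in order: input (simulate or ingest), noise-anchored
#' normalization with alignment and expression calling, the associative
#' DE arm, the random-variance DE arm, beacon-list integration, and —
#' when configured — literature-network keyword enrichment and TRE
#' overrepresentation for each beacon direction. All intermediate
#' tables are written to \code{out_dir} as TSV/plain text; a
#' deterministic run report (parameters and counts) is written to
#' \code{report.tsv}. Identical config and seed give identical outputs;
#' a stage failure aborts with the failing stage named, retaining the
#' outputs of completed stages.
#'
#' @param config A [pipelineConfig()].
#' @return The run report: a list of per-stage parameters, counts and
#'   warnings, plus elapsed time per stage (timings are not written to
#'   disk so that reports are reproducible byte-for-byte).
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(
#'   input = expressionSimConfig(n_probes = 4000, n_de = 30,
#'     fold_changes = c(4, 0.25), signal_log_mean = log(2000),
#'     signal_log_sd = 0.4),
#'   tre = treSimConfig(n_genes = 4000),
#'   out_dir = tempfile())
#' rep <- runPipeline(cfg)
#' rep$counts
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  report <- list(seed = config$seed, counts = list(),
                 warnings = character(0), elapsed = list())
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    report$elapsed[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  # ---- input -------------------------------------------------------
  be <- stage("input", {
    inp <- config$input
    if (inherits(inp, "ExpressionSimConfig")) {
      inp$seed <- stageSeed(config$seed, "expression")
      simulateExpression(inp)
    } else if (!is.null(inp$series_matrix)) {
      readSeriesMatrix(inp$series_matrix, inp$class_map)
    } else if (!is.null(inp$expression_tsv)) {
      readExpressionTsv(inp$expression_tsv, inp$classes_tsv)
    } else stop("unrecognized input source")
  })
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  writeExpressionTsv(be, file.path(config$out_dir, "raw.tsv"),
                     file.path(config$out_dir, "classes.tsv"))

  # ---- normalization ----------------------------------------------
  be <- stage("normalize", normalizeExperiment(be, config$normalization))
  nm <- noiseModels(be)
  nm <- cbind(nm, alignmentParams(be)[, c("slope", "intercept")])
  writeTsv(nm, file.path(config$out_dir, "noise_models.tsv"))
  z <- normalizedValues(be)
  writeTsv(data.frame(probe_id = rownames(z), round(z, 6),
                      check.names = FALSE),
           file.path(config$out_dir, "normalized.tsv"))
  summ <- expressionSummary(be)
  report$counts$expressed_in_all <- summ$expressed_in_all

  # ---- DE arms -----------------------------------------------------
  assoc <- stage("de_assoc", associativeDE(be, config$associative))
  writeTsv(assoc, file.path(config$out_dir, "de_assoc.tsv"))
  rvm <- stage("de_rvm", classComparison(be, config$rvm))
  writeTsv(rvm, file.path(config$out_dir, "de_rvm.tsv"))
  lists <- stage("integrate", integrateLists(assoc, rvm))
  writeLines(lists@upBeacon,
             file.path(config$out_dir, "beacon_up.txt"))
  writeLines(lists@downBeacon,
             file.path(config$out_dir, "beacon_down.txt"))
  writeTsv(lists@report, file.path(config$out_dir, "overlap_report.tsv"))
  report$counts$assoc_up <- length(lists@upAssoc)
  report$counts$assoc_down <- length(lists@downAssoc)
  report$counts$rvm_up <- length(lists@upRvm)
  report$counts$rvm_down <- length(lists@downRvm)
  report$counts$beacon_up <- length(lists@upBeacon)
  report$counts$beacon_down <- length(lists@downBeacon)
  report$beacon_lists <- lists

  # ---- literature network -----------------------------------------
  if (!is.null(config$corpus)) {
    lit <- stage("litnet", {
      cc <- config$corpus
      if (inherits(cc, "CorpusSimConfig")) {
        cc$seed <- stageSeed(config$seed, "corpus")
        sim <- simulateCorpus(cc)
      } else {
        sim <- list(corpus = readCorpus(cc$corpus_path),
                    thesaurus = readThesaurus(cc$thesaurus_path))
      }
      lconf <- config$litnet
      lconf$seed <- stageSeed(config$seed, "litnet")
      net <- buildNetwork(sim$corpus, sim$thesaurus, lconf)
      res <- list()
      for (dir in c("up", "down")) {
        genes <- beaconGenes(lists, dir)
        flt <- filterUnmentioned(
          intersect(genes, sim$thesaurus$object_id), net)
        report$counts[[paste0("lit_discarded_", dir)]] <-
          flt$n_discarded + length(setdiff(genes,
                                           sim$thesaurus$object_id))
        if (length(flt$retained) >= 2L) {
          enr <- sharedTermEnrichment(flt$retained, net, lconf)
          writeTsv(enr, file.path(config$out_dir,
                                  paste0("litnet_", dir, ".tsv")))
          report$counts[[paste0("lit_significant_", dir)]] <-
            sum(enr$significant)
          res[[dir]] <- enr
        }
      }
      res
    })
    report$litnet <- lit
  }

  # ---- TRE overrepresentation -------------------------------------
  if (!is.null(config$tre)) {
    trer <- stage("tre_enrich", {
      tc <- config$tre
      if (inherits(tc, "TRESimConfig")) {
        tc$seed <- stageSeed(config$seed, "tre")
        if (tc$n_genes == nrow(be))
          tc$gene_ids <- rownames(be)
        tm <- simulateTreTable(tc)
      } else tm <- readTreMatrix(tc)
      res <- list()
      for (dir in c("up", "down")) {
        genes <- intersect(beaconGenes(lists, dir), rownames(tm))
        if (length(genes) >= 1L) {
          tr <- treOverrepresentation(
            genes, tm, n_random = config$tre_n_random,
            seed = stageSeed(config$seed, "tre_enrich"))
          writeTsv(tr, file.path(config$out_dir,
                                 paste0("tre_", dir, ".tsv")))
          report$counts[[paste0("tre_significant_", dir)]] <-
            sum(tr$significant)
          res[[dir]] <- tr
        }
      }
      res
    })
    report$tre <- trer
  }

  # ---- deterministic report file ----------------------------------
  cnt <- report$counts
  writeTsv(data.frame(key = c("seed", names(cnt)),
                      value = c(config$seed,
                                unlist(cnt, use.names = FALSE))),
           file.path(config$out_dir, "report.tsv"))
  report
}
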