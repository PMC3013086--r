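# Readers and writers for the pipeline's plain-text interchange formats.

#' Read / write an expression matrix as tab-separated text
#'
#' The matrix dialect is: header row of array ids, first column probe
#' ids, tab-separated numeric intensities; the sidecar class table is a
#' two-column TSV (\code{array_id}, \code{class_label}).
#'
#' @param path Matrix TSV path.
#' @param classes_path Sidecar class-table TSV path.
#' @return \code{readExpressionTsv}: a \linkS4class{BeaconExperiment}.
#' @export
readExpressionTsv <- function(path, classes_path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (!file.exists(classes_path))
    stop("input file not found: ", classes_path)
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  cls <- utils::read.delim(classes_path, check.names = FALSE)
  labels <- stats::setNames(as.character(cls[[2L]]),
                            as.character(cls[[1L]]))
  if (!all(colnames(m) %in% names(labels)))
    stop("class table does not cover all arrays")
  BeaconExperiment(m, labels[colnames(m)])
}

#' @rdname readExpressionTsv
#' @param be A \linkS4class{BeaconExperiment}.
#' @export
writeExpressionTsv <- function(be, path, classes_path = NULL) {
  m <- rawValues(be)
  out <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(classes_path))
    utils::write.table(
      data.frame(array_id = colnames(m), class_label = classLabels(be)),
      classes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix text file
#'
#' Parses the Series Matrix dialect: metadata lines prefixed with
#' \code{!}, with the expression table delimited by
#' \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}.
#' Quoted fields and scientific notation are handled. Sample classes are
#' taken from a user-supplied mapping, never guessed from metadata.
#'
#' @param path Series Matrix file path.
#' @param class_map Named character vector mapping sample/array ids to
#'   class labels.
#' @return A \linkS4class{BeaconExperiment}.
#' @export
readSeriesMatrix <- function(path, class_map) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path)
  lo <- tolower(lines)
  begin <- which(startsWith(lo, "!series_matrix_table_begin"))
  end <- which(startsWith(lo, "!series_matrix_table_end"))
  if (length(begin) != 1L)
    stop("parse error: missing !series_matrix_table_begin marker in ",
         path)
  if (length(end) != 1L || end <= begin + 1L)
    stop("parse error: missing or empty table block (line ",
         begin, ")")
  block <- lines[(begin + 1L):(end - 1L)]
  tab <- tryCatch(
    utils::read.delim(text = block, check.names = FALSE, quote = "\""),
    error = function(e)
      stop("parse error in table block starting at line ", begin + 1L,
           ": ", conditionMessage(e)))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m))
    stop("parse error: non-numeric expression values (table begins at ",
         "line ", begin + 1L, ")")
  rownames(m) <- as.character(tab[[1L]])
  if (!all(colnames(m) %in% names(class_map)))
    stop("class_map must name every sample: missing ",
         paste(setdiff(colnames(m), names(class_map)), collapse = ", "))
  BeaconExperiment(m, as.character(class_map[colnames(m)]))
}

#' Read / write a thesaurus as TSV
#'
#' Columns: \code{object_id}, \code{kind}, \code{synonym}; one synonym
#' per row.
#' @param path File path.
#' @return \code{readThesaurus}: the thesaurus data.frame.
#' @export
readThesaurus <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  utils::read.delim(path, colClasses = "character")
}

#' @rdname readThesaurus
#' @param thesaurus Thesaurus data.frame.
#' @export
writeThesaurus <- function(thesaurus, path) {
  utils::write.table(thesaurus, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a corpus as line-delimited records
#'
#' One abstract per line: abstract id, then sentences separated by
#' \code{" | "}, tokens within a sentence separated by \code{" ; "}.
#'
#' @param path File path.
#' @return \code{readCorpus}: list of \code{list(id, sentences)}.
#' @export
readCorpus <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lapply(readLines(path), function(line) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    sents <- if (length(parts) > 1L)
      lapply(strsplit(parts[-1L], " ; ", fixed = TRUE), trimws)
    else list()
    list(id = parts[1L], sentences = sents)
  })
}

#' @rdname readCorpus
#' @param corpus List of abstracts as produced by [simulateCorpus()].
#' @export
writeCorpus <- function(corpus, path) {
  lines <- vapply(corpus, function(a) {
    sents <- vapply(a$sentences, paste, character(1), collapse = " ; ")
    paste(c(a$id, sents), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a binary gene-by-TRE incidence table as TSV
#'
#' Genes in rows (first column gene ids), TREs in columns, 0/1 entries.
#' @param path File path.
#' @return \code{readTreMatrix}: binary integer matrix.
#' @export
readTreMatrix <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("TRE matrix must be binary")
  m
}

#' @rdname readTreMatrix
#' @param m Binary incidence matrix.
#' @export
writeTreMatrix <- function(m, path) {
  utils::write.table(data.frame(gene_id = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
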