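#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Monotone step-up adjusted values; element-wise at least the raw
#' p-value and order-preserving.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted FDR values.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.5))
#' @export
fdrAdjust <- function(p) {
  checkProb(p, "p")
  stats::p.adjust(p, method = "BH")
}

#' TRE overrepresentation against the array-wide background
#'
#' For each transcription-regulatory element (TRE), counts its presence
#' among the query genes and compares against the same count over
#' random gene sets of equal size drawn uniformly from the background
#' universe (all genes of the incidence table):
#' \code{p = (1 + #[random count >= observed]) / (n_random + 1)}. The
#' one-sided hypergeometric tail is computed alongside as an analytic
#' cross-check, and Benjamini-Hochberg FDR values are added over all
#' tested TREs. A TRE is significant when \code{p < p_threshold}
#' (default 0.05) and \code{fdr < fdr_threshold} (default 0.3).
#'
#' @param gene_list Character vector of query gene ids; must be a
#'   subset of the incidence-table universe.
#' @param tre_matrix Binary gene-by-TRE incidence matrix (genes in
#'   rows); see [simulateTreTable()] / [readTreMatrix()].
#' @param n_random Number of resampled gene sets; default 10000.
#' @param seed Integer RNG seed.
#' @param p_threshold,fdr_threshold Significance thresholds; defaults
#'   0.05 and 0.3.
#' @return data.frame per TRE: \code{tre}, \code{count_in_list},
#'   \code{list_size}, \code{count_in_background},
#'   \code{background_size}, \code{p_resampled},
#'   \code{p_hypergeometric}, \code{fdr}, \code{significant}.
#' @export
treOverrepresentation <- function(gene_list, tre_matrix,
                                  n_random = 10000L, seed = 1L,
                                  p_threshold = 0.05,
                                  fdr_threshold = 0.3) {
  if (length(gene_list) == 0L)
    return(data.frame(tre = character(0), count_in_list = integer(0),
                      list_size = integer(0),
                      count_in_background = integer(0),
                      background_size = integer(0),
                      p_resampled = numeric(0),
                      p_hypergeometric = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  m <- as.matrix(tre_matrix)
  if (!all(m %in% c(0, 1))) stop("tre_matrix must be binary")
  if (!all(gene_list %in% rownames(m)))
    stop("gene_list must be a subset of the background universe")
  n_random <- checkCount(n_random, "n_random")
  bg_count <- colSums(m)
  present <- bg_count > 0
  if (any(!present))
    message("skipping ", sum(!present),
            " TRE(s) absent from the background")
  m <- m[, present, drop = FALSE]
  bg_count <- bg_count[present]
  N <- nrow(m)
  k <- length(gene_list)
  obs <- colSums(m[gene_list, , drop = FALSE])

  null_counts <- withSeed(seed, {
    vapply(seq_len(n_random), function(i)
      colSums(m[sample.int(N, k), , drop = FALSE]),
      numeric(ncol(m)))
  })
  null_counts <- rbind(null_counts)  # TREs x n_random
  hits <- rowSums(null_counts >= obs)
  p_res <- (1 + hits) / (n_random + 1)
  p_hyp <- phyper(obs - 1, bg_count, N - bg_count, k,
                  lower.tail = FALSE)
  fdr <- fdrAdjust(p_res)
  data.frame(tre = colnames(m), count_in_list = as.integer(obs),
             list_size = k, count_in_background = as.integer(bg_count),
             background_size = N, p_resampled = p_res,
             p_hypergeometric = p_hyp, fdr = fdr,
             significant = p_res < p_threshold & fdr < fdr_threshold,
             row.names = NULL)
}
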