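#' Literature-network configuration
#'
#' @param abstract_weight Weight of a same-abstract co-mention; default
#'   0.5.
#' @param sentence_weight Weight of a same-sentence co-mention; default
#'   0.8. Must be >= \code{abstract_weight}.
#' @param n_random_sets Monte-Carlo null size; default 1000.
#' @param z_threshold Significance rule: enrichment z-score >=
#'   \code{z_threshold} standard deviations above the null mean; default
#'   3 (empirically about P <= 0.01).
#' @param weighting \code{"exclusive"} (default): each co-mentioning
#'   abstract contributes the sentence weight if the pair shares at
#'   least one sentence in it, else the abstract weight;
#'   \code{"additive"}: abstract weight plus sentence weight when a
#'   sentence is shared.
#' @param seed Integer RNG seed for the Monte-Carlo null.
#' @return A list of class \code{LitNetConfig}.
#' @export
litnetConfig <- function(abstract_weight = 0.5, sentence_weight = 0.8,
                         n_random_sets = 1000L, z_threshold = 3,
                         weighting = c("exclusive", "additive"),
                         seed = 1L) {
  if (abstract_weight <= 0 || sentence_weight < abstract_weight)
    stop("need sentence_weight >= abstract_weight > 0")
  structure(list(abstract_weight = abstract_weight,
                 sentence_weight = sentence_weight,
                 n_random_sets = checkCount(n_random_sets,
                                            "n_random_sets"),
                 z_threshold = z_threshold,
                 weighting = match.arg(weighting),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "LitNetConfig")
}

#' Canonicalize a surface string for thesaurus matching
#'
#' Lower-cases the string and strips hyphens, underscores and (for
#' thesaurus entries) spaces between alphabetic and numeric runs, so
#' that common spelling variants such as \code{"IL2"} and \code{"IL-2"}
#' collapse to one form. Inside running text only hyphens and
#' underscores are stripped, so that whitespace keeps separating words.
#'
#' @param x Character vector.
#' @param text Set \code{TRUE} when canonicalizing sentence text rather
#'   than a dictionary entry (keeps spaces intact).
#' @return Canonicalized character vector.
#' @examples
#' canonicalizeTerm(c("IL-2", "IL 2", "il2"))
#' @export
canonicalizeTerm <- function(x, text = FALSE) {
  x <- tolower(x)
  sep <- if (text) "[-_]" else "[-_ ]"
  x <- gsub(paste0("(?<=[a-z])", sep, "+(?=[0-9])"), "", x, perl = TRUE)
  gsub(paste0("(?<=[0-9])", sep, "+(?=[a-z])"), "", x, perl = TRUE)
}

# Compile the thesaurus into a matching table sorted longest-first.
compileThesaurus <- function(thesaurus) {
  stopifnot(all(c("object_id", "synonym") %in% colnames(thesaurus)))
  if (any(!nzchar(thesaurus$synonym))) stop("empty synonym in thesaurus")
  canon <- canonicalizeTerm(thesaurus$synonym)
  tab <- data.frame(object_id = thesaurus$object_id, canon = canon,
                    nchar = nchar(canon), stringsAsFactors = FALSE)
  tab <- unique(tab[, c("object_id", "canon", "nchar")])
  tab[order(-tab$nchar, tab$canon), ]
}

#' Recognize thesaurus objects in a sentence-segmented document
#'
#' Case-insensitive longest-match recognition over canonicalized surface
#' forms (see [canonicalizeTerm()]); overlapping matches are resolved
#' longest-first, then left-most, and each object counts at most once
#' per sentence.
#'
#' @param document List (or character vector) of sentences; a sentence
#'   may be a single string or a character vector of tokens.
#' @param thesaurus data.frame with columns \code{object_id},
#'   \code{synonym} (and optionally \code{kind}).
#' @return List of per-sentence character vectors of recognized object
#'   ids.
#' @examples
#' th <- data.frame(object_id = "il2", synonym = "IL2")
#' recognizeObjects(list("IL-2 activates T cells"), th)
#' @export
recognizeObjects <- function(document, thesaurus) {
  tab <- compileThesaurus(thesaurus)
  lapply(document, function(sentence) {
    text <- canonicalizeTerm(paste(sentence, collapse = " "),
                             text = TRUE)
    if (!nzchar(text)) return(character(0))
    taken <- rep(FALSE, nchar(text))
    found <- character(0)
    for (i in seq_len(nrow(tab))) {
      pat <- paste0("(?<![a-z0-9])",
                    gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1",
                         tab$canon[i]),
                    "(?![a-z0-9])")
      m <- gregexpr(pat, text, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      for (k in seq_along(m)) {
        span <- m[k]:(m[k] + len[k] - 1L)
        if (!any(taken[span])) {
          taken[span] <- TRUE
          found <- c(found, tab$object_id[i])
          break  # one mention per object per sentence is enough
        }
      }
    }
    unique(found)
  })
}

#' Build the weighted term co-occurrence network
#'
#' For every abstract and every pair of objects co-mentioned in it, the
#' pair's edge weight grows by the sentence weight (0.8) if the two
#' objects share at least one sentence in that abstract, otherwise by
#' the abstract weight (0.5); weights are summed over abstracts. Also
#' tallies each object's document frequency (number of abstracts
#' mentioning it).
#'
#' @param corpus List of abstracts, each \code{list(id, sentences)} with
#'   sentences as in [recognizeObjects()].
#' @param thesaurus data.frame with \code{object_id}, \code{kind},
#'   \code{synonym}.
#' @param config A [litnetConfig()].
#' @return A \linkS4class{CooccurrenceNetwork}.
#' @export
buildNetwork <- function(corpus, thesaurus,
                         config = litnetConfig()) {
  objects <- unique(thesaurus[, c("object_id",
                                  if ("kind" %in% colnames(thesaurus))
                                    "kind")])
  if (!("kind" %in% colnames(objects))) objects$kind <- "other"
  ids <- objects$object_id
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  df <- stats::setNames(numeric(n), ids)
  for (abs_ in corpus) {
    sent_objs <- recognizeObjects(abs_$sentences, thesaurus)
    mentioned <- unique(unlist(sent_objs))
    if (length(mentioned) == 0L) next
    df[mentioned] <- df[mentioned] + 1
    if (length(mentioned) < 2L) next
    # pairs sharing at least one sentence in this abstract
    sent_pair <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (so in sent_objs)
      if (length(so) >= 2L) sent_pair[so, so] <- TRUE
    idx <- match(mentioned, ids)
    for (ai in seq_along(idx)[-1L]) for (bi in seq_len(ai - 1L)) {
      a <- idx[ai]; b <- idx[bi]
      w <- if (sent_pair[a, b]) {
        if (config$weighting == "exclusive") config$sentence_weight
        else config$abstract_weight + config$sentence_weight
      } else config$abstract_weight
      W[a, b] <- W[a, b] + w
      W[b, a] <- W[a, b]
    }
  }
  methods::new("CooccurrenceNetwork", weights = W, docFreq = df,
               objects = objects)
}

#' Discard genes absent from the literature
#'
#' Genes with zero document frequency cannot share literature-based
#' commonalities with any other gene and are removed before enrichment.
#'
#' @param gene_list Character vector of gene/object ids.
#' @param network A \linkS4class{CooccurrenceNetwork}.
#' @return List with \code{retained} (ids with nonzero document
#'   frequency) and \code{n_discarded}.
#' @export
filterUnmentioned <- function(gene_list, network) {
  df <- network@docFreq
  mentioned <- gene_list[gene_list %in% names(df) & df[gene_list] > 0]
  list(retained = mentioned,
       n_discarded = length(gene_list) - length(mentioned))
}

# Observed statistic of one term against a gene set: summed edge weight,
# and the number of connected set members.
termStat <- function(W, term, genes) {
  w <- W[term, genes]
  c(obs = sum(w), n_connected = sum(w > 0))
}

#' Keyword enrichment over a gene set via a Monte-Carlo random-set null
#'
#' For every non-query term connected to at least 2 query genes, the
#' observed statistic is the term's summed edge weight to the query set.
#' The null distribution of that statistic is obtained over
#' \code{n_random_sets} random gene sets of the same size drawn
#' uniformly (without replacement) from all literature-mentioned genes;
#' the expected value is the null mean and the z-score is
#' \code{(obs - mean) / sd}. Terms at or above \code{z_threshold}
#' (default 3 SD, about P <= 0.01) are significant. Terms whose null SD
#' is zero are reported with \code{NA} z and are never significant.
#'
#' @param gene_set Character vector of query gene ids; all must be
#'   mentioned in the literature (see [filterUnmentioned()]).
#' @param network A \linkS4class{CooccurrenceNetwork}.
#' @param config A [litnetConfig()].
#' @return data.frame: \code{term}, \code{kind}, \code{observed},
#'   \code{n_connected}, \code{expected}, \code{obs_exp_ratio},
#'   \code{z_score}, \code{significant}, sorted by decreasing z.
#' @export
sharedTermEnrichment <- function(gene_set, network,
                                 config = litnetConfig()) {
  if (length(gene_set) == 0L)
    return(data.frame(term = character(0), kind = character(0),
                      observed = numeric(0), n_connected = integer(0),
                      expected = numeric(0), obs_exp_ratio = numeric(0),
                      z_score = numeric(0), significant = logical(0)))
  W <- network@weights
  df <- network@docFreq
  genes_all <- network@objects$object_id[
    network@objects$kind == "gene" & df[network@objects$object_id] > 0]
  if (!all(gene_set %in% genes_all))
    stop("gene_set must be literature-mentioned gene objects")
  terms <- setdiff(names(df)[df > 0], gene_set)
  if (length(terms) == 0L)
    return(sharedTermEnrichment(character(0), network, config))
  obs_mat <- vapply(terms, termStat, numeric(2), W = W,
                    genes = gene_set)
  keep <- obs_mat["n_connected", ] >= 2
  terms <- terms[keep]
  if (length(terms) == 0L)
    return(sharedTermEnrichment(character(0), network, config))
  obs <- obs_mat["obs", keep]
  n_conn <- obs_mat["n_connected", keep]

  k <- length(gene_set)
  Wt <- W[terms, genes_all, drop = FALSE]
  null <- withSeed(config$seed, {
    vapply(seq_len(config$n_random_sets), function(i) {
      rowSums(Wt[, sample.int(length(genes_all), k), drop = FALSE])
    }, numeric(length(terms)))
  })
  null <- rbind(null)  # terms x n_random_sets
  mu <- rowMeans(null)
  sdv <- apply(null, 1L, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, NA_real_)
  kind <- network@objects$kind[match(terms, network@objects$object_id)]
  out <- data.frame(term = terms, kind = kind, observed = obs,
                    n_connected = as.integer(n_conn), expected = mu,
                    obs_exp_ratio = ifelse(mu > 0, obs / mu, NA_real_),
                    z_score = z,
                    significant = !is.na(z) & z >= config$z_threshold,
                    row.names = NULL)
  out[order(-ifelse(is.na(out$z_score), -Inf, out$z_score)), ]
}
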