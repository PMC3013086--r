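# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Counter-based fan-out of one global seed into per-stage seeds, so adding
# a stage never perturbs the draws of earlier stages.
stageSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2017L + match(
    stage,
    c("expression", "corpus", "tre", "normalize", "de_assoc", "de_rvm",
      "integrate", "litnet", "tre_enrich"),
    nomatch = 0L) * 7919L
}

# Row variances of a numeric matrix (denominator n - 1).
rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Row medians without a matrixStats dependency.
rowMedians <- function(m) apply(m, 1L, stats::median)

checkProb <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(name, " must lie in [0, 1]")
  invisible(x)
}

checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(name, " must be a single integer >= ", min)
  invisible(as.integer(x))
}
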