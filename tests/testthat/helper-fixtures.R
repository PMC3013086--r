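# Shared fixture builders (all data generated in code at test time).

# Wrap an already-normalized matrix (noise-SD units) in a
# BeaconExperiment, filling the raw/log10/expressed assays consistently.
makeNormalizedBe <- function(z, classes, threshold = 3) {
  if (is.null(rownames(z)))
    rownames(z) <- sprintf("g%04d", seq_len(nrow(z)))
  if (is.null(colnames(z)))
    colnames(z) <- sprintf("a%02d", seq_len(ncol(z)))
  be <- BeaconExperiment(pmax(z, 0), classes)
  SummarizedExperiment::assay(be, "normalized") <- z
  SummarizedExperiment::assay(be, "log10") <- log10(pmax(z, 1))
  SummarizedExperiment::assay(be, "expressed") <- (z >= threshold) + 0L
  be
}

# A small strong-signal study in which every planted gene is far above
# the 20-SD filter, so both DE arms should recover the truth exactly.
strongSignalStudy <- function(seed, n_probes = 4000, n_de = 30,
                              fold_changes = c(4, 0.25)) {
  simulateExpression(expressionSimConfig(
    n_probes = n_probes, n_de = n_de, fold_changes = fold_changes,
    signal_log_mean = log(2000), signal_log_sd = 0.4, seed = seed))
}

# Pooled two-class residual variance, first n1 columns = class 1.
rowVarsPooled <- function(m, n1) {
  x1 <- m[, seq_len(n1), drop = FALSE]
  x2 <- m[, -seq_len(n1), drop = FALSE]
  (rowSums((x1 - rowMeans(x1))^2) + rowSums((x2 - rowMeans(x2))^2)) /
    (ncol(m) - 2)
}

# Reference group with a standard-normal residual pool of known df.
unitReference <- function(n = 1000, seed = 1) {
  r <- withr::with_seed(seed, rnorm(n))
  r <- (r - mean(r)) / sd(r)
  methods::new("ReferenceGroup", geneIds = sprintf("r%04d", 1:10),
               pooledResiduals = r, pooledSd = 1,
               df = as.integer(n - 1))
}
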