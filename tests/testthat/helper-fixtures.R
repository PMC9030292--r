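# Shared fixture builders. Everything is generated in code; no files on disk.

make_samples <- function(reps = 3) {
  stages <- c("ST1", "ST2", "ST3")
  data.frame(
    sample_id = paste0(rep(stages, each = reps), "_r", rep(seq_len(reps), 3)),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), 3),
    stringsAsFactors = FALSE
  )
}

make_counts <- function(values, samples, feature_class = "circ",
                        feature_ids = NULL) {
  m <- matrix(as.integer(values), ncol = nrow(samples), byrow = TRUE)
  rownames(m) <- feature_ids %||% sprintf("f%02d", seq_len(nrow(m)))
  colnames(m) <- samples$sample_id
  count_matrix(m, samples, feature_class)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal DE table for classifier tests
make_de_table <- function(ids, lfc, padj) {
  data.frame(feature_id = ids, base_mean = 100, log2FC = lfc,
             se = 0.1, wald = lfc / 0.1, pvalue = padj, padj = padj,
             is_de = abs(lfc) >= 1 & padj <= 0.05,
             stringsAsFactors = FALSE)
}

# independent brute-force BH: literal step-up definition, double loop
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  s <- p[o]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(s[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# independent rule evaluator for sponge classification (scalar, if-chains)
classify_brute <- function(circ_lfc, circ_padj, gene_lfc, gene_padj,
                           lfc_min = 1, fdr_max = 0.05) {
  # vectors over the three contrasts
  type <- 0L
  for (i in seq_along(circ_lfc)) {
    mag <- abs(circ_lfc[i]) >= lfc_min && abs(gene_lfc[i]) >= lfc_min
    same <- sign(circ_lfc[i]) == sign(gene_lfc[i]) && sign(circ_lfc[i]) != 0
    fdr <- circ_padj[i] <= fdr_max && gene_padj[i] <= fdr_max
    if (mag && same && fdr) return(2L)
    if (mag && same) type <- max(type, 1L)
  }
  type
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
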