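#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median, over features with
#' positive counts in every sample, of that feature's count divided by its
#' geometric mean across samples. Identical columns therefore get factors
#' of exactly 1, and a single-sample matrix gets factor 1.
#'
#' @param counts a [count_matrix()] or a numeric matrix.
#' @param pseudo_reference if `TRUE`, fall back to a pseudo-reference
#'   computed over the positive counts of each feature (usable when no
#'   feature is positive in all samples, e.g. very sparse data).
#' @return named numeric vector of per-sample positive scale factors.
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  logm <- log(m)
  if (pseudo_reference) {
    # geometric mean over the positive entries of each feature
    loggeo <- apply(logm, 1L, function(x) {
      x <- x[is.finite(x)]
      if (length(x)) mean(x) else -Inf
    })
  } else {
    loggeo <- rowMeans(logm)   # -Inf whenever a zero is present
    if (!any(is.finite(loggeo)))
      stop("no feature has positive counts in every sample; ",
           "re-run with pseudo_reference = TRUE", call. = FALSE)
  }
  sf <- apply(logm, 2L, function(lc) {
    r <- lc - loggeo
    r <- r[is.finite(r)]
    if (!length(r))
      stop("cannot compute a size factor: no usable feature ratios", call. = FALSE)
    exp(stats::median(r))
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor estimated", call. = FALSE)
  sf
}

#' Per-feature negative-binomial dispersion estimates
#'
#' Method-of-moments estimator on normalized counts: the within-group
#' pooled variance s2 and the grand mean mu give a raw
#' alpha = max(0, (s2 - mu) / mu^2) per feature (variance model
#' mu + alpha * mu^2). Raw estimates are then shrunk halfway toward the
#' trimmed mean of raw estimates across features, and floored at
#' `alpha_min`. All-zero features get `alpha_min` and are flagged.
#'
#' @param counts [count_matrix()] or numeric matrix.
#' @param size_factors per-sample scale factors.
#' @param groups factor/character of group membership per sample; taken
#'   from the sample sheet stages when `counts` is a `count_matrix` and
#'   `groups` is missing.
#' @param alpha_min dispersion floor (default 1e-8).
#' @param shrink weight of the trimmed-mean prior in the shrinkage
#'   (default 0.5 — halfway).
#' @param trim trimming fraction for the across-feature mean.
#' @return data.frame with `feature_id`, `alpha`, `raw_alpha`,
#'   `all_zero`; attribute `method`.
#' @export
estimate_dispersions <- function(counts, size_factors, groups,
                                 alpha_min = 1e-8, shrink = 0.5, trim = 0.1) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (missing(groups)) {
    if (!inherits(counts, "count_matrix"))
      stop("groups must be given for a plain matrix", call. = FALSE)
    groups <- counts$samples$stage
  }
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("need >= 2 samples per group", call. = FALSE)
  norm <- sweep(m, 2L, size_factors, "/")

  n <- ncol(norm)
  g_idx <- split(seq_len(n), groups)
  # pooled within-group variance: sum of squared residuals / (n - G)
  ssr <- 0
  for (idx in g_idx) {
    sub <- norm[, idx, drop = FALSE]
    ssr <- ssr + rowSums((sub - rowMeans(sub))^2)
  }
  s2 <- ssr / (n - length(g_idx))
  mu <- rowMeans(norm)
  all_zero <- mu == 0
  raw <- ifelse(all_zero, alpha_min, pmax(0, (s2 - mu) / mu^2))
  prior <- mean(raw[!all_zero], trim = trim)
  if (!is.finite(prior)) prior <- alpha_min
  alpha <- pmax(alpha_min, (1 - shrink) * raw + shrink * prior)
  alpha[all_zero] <- alpha_min
  out <- data.frame(feature_id = rownames(m), alpha = alpha, raw_alpha = raw,
                    all_zero = all_zero, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "mom_pooled_shrunk"
  out
}

#' Negative-binomial Wald test for one pairwise stage contrast
#'
#' Group means of normalized counts are the maximum-likelihood NB means
#' given fixed dispersion. The fold change is
#' `log2((mu_num + c) / (mu_den + c))` with pseudo-mean `c` for stability
#' at zero; its standard error comes from the delta method on the NB
#' log-mean difference,
#' `se^2 = (1/ln 2)^2 * sum_g (1/n_g) * (1/mu_g + alpha)`,
#' using the un-pseudocounted means when both are positive. The Wald
#' statistic `log2FC / se` is referenced to the standard normal
#' (two-sided).
#'
#' @param counts [count_matrix()].
#' @param size_factors per-sample scale factors.
#' @param dispersions data.frame from [estimate_dispersions()] (or a
#'   numeric vector of per-feature alphas in matrix row order).
#' @param contrast ordered pair `c(numerator_stage, denominator_stage)`,
#'   e.g. `c("ST2", "ST1")` for the ST2 vs ST1 comparison.
#' @param lfc_min minimum absolute log2 fold change to call a feature
#'   differentially expressed (default 1).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @param alpha_strict if `TRUE` use `padj < alpha` instead of the default
#'   inclusive `padj <= alpha`.
#' @param pseudo_mean pseudo-mean `c` added inside the fold change
#'   (default 0.5).
#' @return `DETable` data.frame: `feature_id`, `base_mean`, `log2FC`,
#'   `se`, `wald`, `pvalue`, `padj`, `is_de`.
#' @export
wald_de <- function(counts, size_factors, dispersions, contrast,
                    lfc_min = 1, alpha = 0.05, alpha_strict = FALSE,
                    pseudo_mean = 0.5) {
  stopifnot(inherits(counts, "count_matrix"), length(contrast) == 2L)
  stages <- counts$samples$stage
  for (st in contrast)
    if (sum(stages == st) < 2L)
      stop("contrast group absent or with < 2 replicates: ", st, call. = FALSE)
  norm <- normalized_counts(counts, size_factors)
  disp <- if (is.data.frame(dispersions)) {
    stopifnot(identical(dispersions$feature_id, rownames(norm)))
    dispersions$alpha
  } else as.numeric(dispersions)

  i_num <- which(stages == contrast[1L])
  i_den <- which(stages == contrast[2L])
  mu_num <- rowMeans(norm[, i_num, drop = FALSE])
  mu_den <- rowMeans(norm[, i_den, drop = FALSE])
  n1 <- length(i_num); n2 <- length(i_den)

  log2fc <- log2((mu_num + pseudo_mean) / (mu_den + pseudo_mean))
  both_pos <- mu_num > 0 & mu_den > 0
  m1 <- ifelse(both_pos, mu_num, mu_num + pseudo_mean)
  m2 <- ifelse(both_pos, mu_den, mu_den + pseudo_mean)
  se <- sqrt((1 / log(2))^2 * ((1 / m1 + disp) / n1 + (1 / m2 + disp) / n2))
  wald <- ifelse(log2fc == 0, 0, log2fc / se)
  pvalue <- 2 * stats::pnorm(-abs(wald))

  padj <- benjamini_hochberg(pvalue)
  sig <- if (alpha_strict) padj < alpha else padj <= alpha
  data.frame(
    feature_id = rownames(norm),
    base_mean = rowMeans(norm),
    log2FC = log2fc,
    se = se,
    wald = wald,
    pvalue = pvalue,
    padj = padj,
    is_de = abs(log2fc) >= lfc_min & sig,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classical step-up adjusted p-values: `min_{j >= i} p_(j) * m / j`,
#' clipped at 1, returned in the input order. Tied p-values receive equal
#' adjusted values.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must be finite and in [0, 1]", call. = FALSE)
  m <- length(pvalues)
  o <- order(pvalues)
  ranked <- pvalues[o] * m / seq_len(m)
  adj <- pmin(1, rev(cummin(rev(ranked))))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' All three pairwise stage contrasts
#'
#' Runs [wald_de()] for the three comparisons ST2 vs ST1, ST3 vs ST1 and
#' ST3 vs ST2, applying the BH adjustment within each contrast
#' separately.
#'
#' @inheritParams wald_de
#' @param size_factors optional; estimated from `counts` when missing.
#' @param dispersions optional; estimated when missing.
#' @return named list of `DETable`s with keys `ST2vsST1`, `ST3vsST1`,
#'   `ST3vsST2`.
#' @export
pairwise_de_all <- function(counts, size_factors = NULL, dispersions = NULL,
                            lfc_min = 1, alpha = 0.05, alpha_strict = FALSE,
                            pseudo_mean = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  stages_present <- unique(counts$samples$stage)
  if (!all(c("ST1", "ST2", "ST3") %in% stages_present))
    stop("all three stages ST1/ST2/ST3 are required", call. = FALSE)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts, size_factors)
  contrasts <- list(ST2vsST1 = c("ST2", "ST1"),
                    ST3vsST1 = c("ST3", "ST1"),
                    ST3vsST2 = c("ST3", "ST2"))
  lapply(contrasts, function(ct)
    wald_de(counts, size_factors, dispersions, ct,
            lfc_min = lfc_min, alpha = alpha, alpha_strict = alpha_strict,
            pseudo_mean = pseudo_mean))
}

#' Simplified variance-stabilizing transform
#'
#' `log2(normalized count + 1)`. A deliberately simple, fully specified
#' transform for exploratory analysis (PCA, sample clustering); it is not
#' the mean-dispersion-fitted VST of the DESeq2 family.
#'
#' @inheritParams wald_de
#' @return real-valued matrix, same dimensions as the counts.
#' @export
vst_transform <- function(counts, size_factors = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  log2(sweep(m, 2L, size_factors, "/") + 1)
}

#' Differentially expressed feature ids across a set of DE tables
#'
#' @param de_tables named list of `DETable`s (one per contrast).
#' @return character vector of feature ids flagged `is_de` in any table.
#' @export
de_feature_ids <- function(de_tables) {
  unique(unlist(lapply(de_tables, function(t) t$feature_id[t$is_de]),
                use.names = FALSE))
}
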