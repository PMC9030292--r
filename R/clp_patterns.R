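#' Circular-to-linear expression proportion per stage
#'
#' For each circRNA and stage, back-splice-junction counts and linear
#' host-gene counts are pooled (summed) across replicates within the
#' stage, and CLP = circ / (circ + linear). The ratio of sums is the ML
#' estimate under a binomial split of the host expression, and is robust
#' at low counts. A CLP of 0.5 means equal circular and linear counts.
#' Cells with a zero denominator are returned as `NA` with
#' `defined = FALSE`, never silently as 0.
#'
#' @param circ [count_matrix()] of back-splice junction counts.
#' @param linear [count_matrix()] of linear host counts; must share
#'   feature ids (row keys) and samples with `circ` one-to-one.
#' @return `CLPTable` data.frame: `circ_id`, `stage`, `circ_pooled`,
#'   `linear_pooled`, `clp`, `defined`.
#' @export
compute_clp <- function(circ, linear) {
  stopifnot(inherits(circ, "count_matrix"), inherits(linear, "count_matrix"))
  if (!identical(rownames(circ$counts), rownames(linear$counts)))
    stop("circ and linear matrices must share feature ids in the same order",
         call. = FALSE)
  if (!identical(circ$samples$sample_id, linear$samples$sample_id))
    stop("circ and linear matrices must share samples", call. = FALSE)
  stages <- sort(unique(circ$samples$stage))
  out <- do.call(rbind, lapply(stages, function(st) {
    idx <- which(circ$samples$stage == st)
    cp <- rowSums(circ$counts[, idx, drop = FALSE])
    lp <- rowSums(linear$counts[, idx, drop = FALSE])
    tot <- cp + lp
    data.frame(circ_id = rownames(circ$counts), stage = st,
               circ_pooled = cp, linear_pooled = lp,
               clp = ifelse(tot > 0, cp / tot, NA_real_),
               defined = tot > 0,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Row-wise z-score profiles
#'
#' Each feature (row) is centered by its mean and scaled by its sample
#' standard deviation (n - 1 denominator). Constant rows are set to
#' all-zero and flagged in the `constant_rows` attribute.
#'
#' @param mat real-valued features x samples matrix with >= 2 columns.
#' @return z-scored matrix; attribute `constant_rows` holds the row names
#'   (or indices) of flagged constant rows.
#' @export
zscore_profiles <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need >= 2 samples to z-score", call. = FALSE)
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  z <- (mat - mu) / ifelse(const, 1, s)
  z[const, ] <- 0
  attr(z, "constant_rows") <-
    if (is.null(rownames(mat))) which(const) else rownames(mat)[const]
  z
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with complete ("full") linkage on Euclidean
#' distances between the rows of `z`, cut into `k` clusters. Apply to the
#' transposed matrix to cluster samples instead of features.
#'
#' @param z numeric matrix (typically z-score profiles), rows clustered.
#' @param k number of clusters; must not exceed the number of rows.
#' @param linkage agglomeration method (default `"complete"`).
#' @param metric distance metric (default `"euclidean"`).
#' @return `ClusterAssignment` list: `labels` (named integer vector in
#'   1..k), `k`, `linkage`, `metric`, and the `hclust` tree.
#' @export
cluster_features <- function(z, k, linkage = "complete", metric = "euclidean") {
  z <- as.matrix(z)
  if (k > nrow(z)) stop("k exceeds the number of rows", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  d <- stats::dist(z, method = metric)
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(labels = labels, k = as.integer(k),
                 linkage = linkage, metric = metric, hclust = hc),
            class = "cluster_assignment")
}

#' Select the number of clusters by mean silhouette width
#'
#' Cuts the complete-linkage tree at every k in `k_range` and picks the k
#' maximizing the mean silhouette width (ties broken toward the smallest
#' k). When the data carry no usable structure (all pairwise distances
#' zero), no k is chosen and `no_structure` is set instead of returning
#' an arbitrary answer.
#'
#' @param z numeric matrix, rows are the objects to cluster.
#' @param k_range integer vector of candidate k, within `[2, nrow - 1]`.
#' @param index validity index: `"silhouette"` (default) or `"ch"`
#'   (Calinski-Harabasz).
#' @param linkage,metric passed to [cluster_features()].
#' @return list: `k` (chosen, or `NA` if no structure), `scores` (named
#'   per-k index values), `no_structure` flag.
#' @export
select_cluster_number <- function(z, k_range = 2:8, index = c("silhouette", "ch"),
                                  linkage = "complete", metric = "euclidean") {
  index <- match.arg(index)
  z <- as.matrix(z)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > nrow(z) - 1L))
    stop("k_range must lie within [2, nrow(z) - 1]", call. = FALSE)
  d <- stats::dist(z, method = metric)
  if (max(d) == 0)
    return(list(k = NA_integer_, scores = stats::setNames(rep(NA_real_, length(k_range)),
                                                          k_range),
                no_structure = TRUE))
  hc <- stats::hclust(d, method = linkage)
  scores <- vapply(k_range, function(k) {
    labels <- stats::cutree(hc, k = k)
    if (length(unique(labels)) < 2L) return(NA_real_)
    if (index == "silhouette") {
      mean(cluster::silhouette(labels, d)[, "sil_width"])
    } else {
      calinski_harabasz(z, labels)
    }
  }, numeric(1))
  names(scores) <- k_range
  if (all(is.na(scores)))
    return(list(k = NA_integer_, scores = scores, no_structure = TRUE))
  best <- k_range[which.max(scores)]   # which.max takes the first maximum -> smallest k
  list(k = best, scores = scores, no_structure = FALSE)
}

calinski_harabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  grand <- colMeans(x)
  ssb <- 0; ssw <- 0
  for (g in unique(labels)) {
    sub <- x[labels == g, , drop = FALSE]
    cm <- colMeans(sub)
    ssb <- ssb + nrow(sub) * sum((cm - grand)^2)
    ssw <- ssw + sum(sweep(sub, 2L, cm)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Principal component analysis of sample profiles
#'
#' Centered (not scaled by default) PCA via singular value decomposition.
#' Constant features are dropped before the decomposition. The percent
#' variance explained sums to 100 over the returned components.
#'
#' @param mat samples x features numeric matrix (e.g. the transpose of a
#'   vst-transformed count matrix).
#' @param center,scale. passed to [stats::prcomp()].
#' @return `PCAResult` list: `scores` (samples x components),
#'   `percent_var` (per component), and the `prcomp` fit.
#' @export
run_pca <- function(mat, center = TRUE, scale. = FALSE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stop("need >= 2 samples for PCA", call. = FALSE)
  v <- apply(mat, 2L, stats::var)
  keep <- is.finite(v) & v > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-constant features", call. = FALSE)
  fit <- stats::prcomp(mat[, keep, drop = FALSE], center = center, scale. = scale.)
  pv <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x, percent_var = pv, fit = fit)
}

#' Venn-region counts for three differential-expression sets
#'
#' Counts the 7 disjoint regions of a three-set Venn diagram. Region
#' names are built from the set names: `"A"` means in A only,
#' `"A&B"` in A and B but not C, `"A&B&C"` the center.
#'
#' @param de_sets named list of exactly 3 character vectors (feature
#'   ids per contrast).
#' @return named integer vector of 7 region counts; sums to the size of
#'   the union.
#' @export
venn_regions <- function(de_sets) {
  if (!is.list(de_sets) || length(de_sets) != 3L)
    stop("exactly 3 sets are required", call. = FALSE)
  nm <- names(de_sets)
  if (is.null(nm) || any(!nzchar(nm))) nm <- c("A", "B", "C")
  sets <- lapply(de_sets, unique)
  all_ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1L)
  combos <- list(c(1), c(2), c(3), c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  counts <- vapply(combos, function(cm) {
    inside <- rowSums(member[, cm, drop = FALSE]) == length(cm)
    outside <- rowSums(member[, -cm, drop = FALSE]) == 0 | length(cm) == 3L
    sum(inside & outside)
  }, integer(1))
  names(counts) <- vapply(combos, function(cm) paste(nm[cm], collapse = "&"), "")
  counts
}

#' Per-stage mean z-score profiles
#'
#' Collapses a z-score matrix to stage-level means (one column per
#' stage), the summary used for cluster expression-pattern boxplots.
#'
#' @param z features x samples z-score matrix.
#' @param samples sample sheet matching the columns of `z`.
#' @return features x stages matrix of mean z-scores.
#' @export
stage_profiles <- function(z, samples) {
  samples <- validate_sample_sheet(samples)
  stopifnot(identical(colnames(z), samples$sample_id))
  stages <- sort(unique(samples$stage))
  out <- vapply(stages, function(st)
    rowMeans(z[, samples$stage == st, drop = FALSE]), numeric(nrow(z)))
  colnames(out) <- stages
  out
}
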