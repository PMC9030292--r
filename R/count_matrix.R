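#' Staged count matrix
#'
#' Container for a non-negative integer feature-by-sample count table tied
#' to a sample sheet. All expression statistics in the package operate on
#' objects of this class. Columns are always stored in sample-sheet order.
#'
#' @param counts integer matrix, features in rows, samples in columns.
#'   Must have unique rownames (feature ids) and colnames (sample ids).
#' @param samples sample sheet `data.frame` with columns `sample_id`,
#'   `stage` (one of `"ST1"`, `"ST2"`, `"ST3"`) and `replicate`.
#' @param feature_class one of `"circ"`, `"linear"`, `"mrna"`.
#'
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `samples` and `feature_class`.
#' @export
count_matrix <- function(counts, samples, feature_class = c("circ", "linear", "mrna")) {
  feature_class <- match.arg(feature_class)
  samples <- validate_sample_sheet(samples)
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count matrix needs feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicated feature_id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  missing_in_sheet <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing_in_sheet))
    stop("sample(s) absent from sample sheet: ",
         paste(missing_in_sheet, collapse = ", "), call. = FALSE)
  missing_in_counts <- setdiff(samples$sample_id, colnames(counts))
  if (length(missing_in_counts))
    stop("sample(s) in sheet but not in counts: ",
         paste(missing_in_counts, collapse = ", "), call. = FALSE)
  counts <- counts[, samples$sample_id, drop = FALSE]
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at feature '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])), call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, samples = samples, feature_class = feature_class),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples (stages: %s)\n",
              x$feature_class, nrow(x$counts), ncol(x$counts),
              paste(sort(unique(x$samples$stage)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Validate a sample sheet
#'
#' @param samples data.frame with `sample_id`, `stage`, `replicate`.
#' @return The validated data.frame (row order preserved).
#' @export
validate_sample_sheet <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "stage", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id in sample sheet", call. = FALSE)
  bad <- setdiff(unique(samples$stage), c("ST1", "ST2", "ST3"))
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(samples$replicate) | samples$replicate < 1 |
            samples$replicate != round(samples$replicate)))
    stop("replicate must be a positive integer", call. = FALSE)
  samples$sample_id <- as.character(samples$sample_id)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)
  samples
}

# normalized counts given size factors (internal)
normalized_counts <- function(counts, size_factors) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  sweep(m, 2L, size_factors, "/")
}
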