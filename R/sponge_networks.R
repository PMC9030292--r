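#' Filter circRNA-miRNA binding sites by context score percentile
#'
#' Keeps sites whose context score percentile is strictly greater than
#' `min_percentile` (a site at exactly the threshold is dropped).
#'
#' @param sites binding-site data.frame (`circ_id`, `mirna_id`,
#'   `context_score_percentile`).
#' @param min_percentile strict lower bound (default 95).
#' @return filtered data.frame; attribute `distinct_mirnas` reports the
#'   number of distinct miRNAs kept.
#' @export
filter_binding_sites <- function(sites, min_percentile = 95) {
  sites <- validate_binding_sites(sites)
  kept <- sites[sites$context_score_percentile > min_percentile, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "distinct_mirnas") <- length(unique(kept$mirna_id))
  kept
}

#' Filter miRNA-gene targets by cumulative weighted context score
#'
#' Keeps pairs whose score is less than or equal to `max_score`
#' (inclusive: a pair at exactly the threshold is kept; more negative
#' means stronger predicted targeting).
#'
#' @param targets target data.frame (`mirna_id`, `gene_id`,
#'   `cumulative_weighted_context`).
#' @param max_score inclusive upper bound (default -1).
#' @return filtered data.frame.
#' @export
filter_targets <- function(targets, max_score = -1) {
  targets <- validate_targets(targets)
  kept <- targets[targets$cumulative_weighted_context <= max_score, , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Assemble candidate circRNA-miRNA-gene triplets
#'
#' Joins the filtered binding sites (collapsed to distinct circ-miRNA
#' pairs) with the filtered targets, then keeps only triplets whose gene
#' is differentially expressed in at least one of the three stage
#' contrasts. Duplicate triplets are collapsed.
#'
#' @param sites_kept filtered binding-site table.
#' @param targets_kept filtered target table.
#' @param de_gene_ids character vector of genes DE in any contrast.
#' @return data.frame of distinct triplets (`circ_id`, `mirna_id`,
#'   `gene_id`), untyped.
#' @export
assemble_networks <- function(sites_kept, targets_kept, de_gene_ids) {
  pairs_cm <- unique(sites_kept[, c("circ_id", "mirna_id"), drop = FALSE])
  pairs_mg <- unique(targets_kept[, c("mirna_id", "gene_id"), drop = FALSE])
  pairs_mg <- pairs_mg[pairs_mg$gene_id %in% de_gene_ids, , drop = FALSE]
  trip <- merge(pairs_cm, pairs_mg, by = "mirna_id")
  trip <- unique(trip[, c("circ_id", "mirna_id", "gene_id"), drop = FALSE])
  trip <- trip[order(trip$circ_id, trip$mirna_id, trip$gene_id), , drop = FALSE]
  rownames(trip) <- NULL
  trip
}

#' Classify sponge networks as Type 2 / 1 / 0
#'
#' Each of the three stage contrasts is evaluated independently for each
#' triplet:
#' * Type 2 ("strongly possible sponge"): in at least one contrast, both
#'   the circRNA and the gene have `|log2FC| >= lfc_min`, the fold
#'   changes share the sign, and both adjusted p-values (FDR) are
#'   `<= fdr_max`.
#' * Type 1 ("possible sponge"): the magnitude-and-sign conditions hold
#'   in at least one contrast, but no contrast also passes both FDR
#'   checks.
#' * Type 0 ("no sponge"): anything else.
#'
#' The supporting contrasts (those meeting the magnitude-and-sign
#' conditions, and for Type 2 additionally the FDR conditions) are
#' recorded, together with the circ and gene statistics of the first
#' supporting contrast. miRNA expression is not part of the rule — these
#' networks are hypotheses about sponging, not measured interactions.
#'
#' @param networks triplet data.frame from [assemble_networks()].
#' @param circ_de,gene_de named lists of `DETable`s per contrast
#'   (`ST2vsST1`, `ST3vsST1`, `ST3vsST2`).
#' @param lfc_min minimum absolute log2 fold change (default 1).
#' @param fdr_max inclusive FDR cutoff (default 0.05).
#' @return the triplet data.frame with added columns `type`,
#'   `supporting_contrasts` (comma-separated), `best_contrast`,
#'   `circ_lfc`, `circ_padj`, `gene_lfc`, `gene_padj`.
#' @export
classify_sponge <- function(networks, circ_de, gene_de,
                            lfc_min = 1, fdr_max = 0.05) {
  contrasts <- c("ST2vsST1", "ST3vsST1", "ST3vsST2")
  stopifnot(all(contrasts %in% names(circ_de)), all(contrasts %in% names(gene_de)))
  networks <- as.data.frame(networks)
  n <- nrow(networks)
  type <- integer(n)
  support <- character(n)
  best <- rep(NA_character_, n)
  clfc <- cpadj <- glfc <- gpadj <- rep(NA_real_, n)

  lut <- function(tab, ids, col) {
    i <- match(ids, tab$feature_id)
    if (anyNA(i)) {
      missing <- unique(ids[is.na(i)])
      stop("feature absent from DE table: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    tab[[col]][i]
  }

  if (n) {
    sign_ok <- mag_ok <- fdr_ok <- matrix(FALSE, n, 3L,
                                          dimnames = list(NULL, contrasts))
    cl <- cp <- gl <- gp <- matrix(NA_real_, n, 3L, dimnames = list(NULL, contrasts))
    for (ct in contrasts) {
      cl[, ct] <- lut(circ_de[[ct]], networks$circ_id, "log2FC")
      cp[, ct] <- lut(circ_de[[ct]], networks$circ_id, "padj")
      gl[, ct] <- lut(gene_de[[ct]], networks$gene_id, "log2FC")
      gp[, ct] <- lut(gene_de[[ct]], networks$gene_id, "padj")
      mag_ok[, ct] <- abs(cl[, ct]) >= lfc_min & abs(gl[, ct]) >= lfc_min
      sign_ok[, ct] <- sign(cl[, ct]) == sign(gl[, ct]) & sign(cl[, ct]) != 0
      fdr_ok[, ct] <- cp[, ct] <= fdr_max & gp[, ct] <= fdr_max
    }
    cond1 <- mag_ok & sign_ok            # rule (b): magnitude + same sign
    cond2 <- cond1 & fdr_ok              # rule (a): plus both FDRs
    for (i in seq_len(n)) {
      if (any(cond2[i, ])) {
        type[i] <- 2L
        sup <- contrasts[cond2[i, ]]
      } else if (any(cond1[i, ])) {
        type[i] <- 1L
        sup <- contrasts[cond1[i, ]]
      } else {
        type[i] <- 0L
        sup <- character(0)
      }
      support[i] <- paste(sup, collapse = ",")
      if (length(sup)) {
        best[i] <- sup[1L]
        clfc[i] <- cl[i, sup[1L]]; cpadj[i] <- cp[i, sup[1L]]
        glfc[i] <- gl[i, sup[1L]]; gpadj[i] <- gp[i, sup[1L]]
      }
    }
  }
  networks$type <- type
  networks$supporting_contrasts <- support
  networks$best_contrast <- best
  networks$circ_lfc <- clfc
  networks$circ_padj <- cpadj
  networks$gene_lfc <- glfc
  networks$gene_padj <- gpadj
  networks
}

#' Filter-cascade and type-count report
#'
#' Tallies the classified networks by type and assembles the full filter
#' cascade bookkeeping. The type counts must partition the constructed
#' networks, and every cascade step is checked to be non-increasing
#' where the pipeline guarantees monotonicity.
#'
#' @param networks classified network data.frame (column `type` present,
#'   no `NA`).
#' @param cascade optional named list with the upstream counts
#'   `sites_in`, `sites_kept`, `distinct_mirnas`, `targets_in`,
#'   `targets_kept`, `genes_de_kept` (filled with `NA` when not
#'   supplied).
#' @return `FilterReport` list of counts.
#' @export
summarize_networks <- function(networks, cascade = list()) {
  networks <- as.data.frame(networks)
  if (nrow(networks) && (!"type" %in% names(networks) || anyNA(networks$type)))
    stop("unclassified network present: run classify_sponge first", call. = FALSE)
  n_type <- function(t) if (nrow(networks)) sum(networks$type == t) else 0L
  rep_ <- list(
    sites_in = cascade$sites_in %||% NA_integer_,
    sites_kept = cascade$sites_kept %||% NA_integer_,
    distinct_mirnas = cascade$distinct_mirnas %||% NA_integer_,
    targets_in = cascade$targets_in %||% NA_integer_,
    targets_kept = cascade$targets_kept %||% NA_integer_,
    genes_de_kept = cascade$genes_de_kept %||% NA_integer_,
    networks_built = nrow(networks),
    n_type2 = n_type(2L),
    n_type1 = n_type(1L),
    n_type0 = n_type(0L)
  )
  if (rep_$n_type2 + rep_$n_type1 + rep_$n_type0 != rep_$networks_built)
    stop("type counts do not partition the constructed networks", call. = FALSE)
  if (!is.na(rep_$sites_in) && !is.na(rep_$sites_kept) &&
        rep_$sites_kept > rep_$sites_in)
    stop("cascade not monotone: sites_kept > sites_in", call. = FALSE)
  if (!is.na(rep_$targets_in) && !is.na(rep_$targets_kept) &&
        rep_$targets_kept > rep_$targets_in)
    stop("cascade not monotone: targets_kept > targets_in", call. = FALSE)
  structure(rep_, class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Sponge-network filter cascade:\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
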