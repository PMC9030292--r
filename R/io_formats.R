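#' Read a sample sheet TSV
#'
#' Expected columns: `sample_id`, `stage` (ST1/ST2/ST3), `replicate`.
#'
#' @param path path to a tab-separated file with header.
#' @return validated sample sheet data.frame.
#' @export
read_sample_sheet <- function(path) {
  validate_sample_sheet(read_tsv_strict(path))
}

#' Read a count matrix TSV
#'
#' The file must have a header of sample ids and a first column of feature
#' ids; every cell must be a non-negative integer. Columns are re-aligned
#' to the order of the sample sheet.
#'
#' @param path TSV path.
#' @param samples sample sheet (data.frame) the columns must match.
#' @param feature_class `"circ"`, `"linear"` or `"mrna"`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, samples, feature_class) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) stop("count TSV needs a feature column plus samples", call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated feature_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))),
                 arr.ind = TRUE)
    stop("non-numeric count cell in ", path, call. = FALSE)
  }
  rownames(m) <- ids
  count_matrix(m, samples, feature_class)
}

#' Read a circRNA annotation table
#'
#' Tab-separated, BED-convention coordinates (0-based half-open back-splice
#' junction). Required columns: `circ_id`, `host_gene`, `chrom`,
#' `bsj_start`, `bsj_end`, `strand`, `circ_class`. The annotation is
#' metadata only; it is never used in the statistics.
#'
#' @param path TSV path.
#' @return validated annotation data.frame.
#' @export
read_circ_annotation <- function(path) {
  ann <- read_tsv_strict(path)
  need <- c("circ_id", "host_gene", "chrom", "bsj_start", "bsj_end", "strand", "circ_class")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ann$circ_id)) stop("duplicated circ_id in annotation", call. = FALSE)
  if (any(ann$bsj_start >= ann$bsj_end))
    stop("bsj_start must be < bsj_end (0-based half-open)", call. = FALSE)
  if (any(!ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  ok_class <- c("exonic", "exonic-intronic", "intronic", "intergenic")
  if (any(!ann$circ_class %in% ok_class))
    stop("circ_class must be one of: ", paste(ok_class, collapse = ", "), call. = FALSE)
  ann
}

#' Read circRNA binding-site and miRNA target tables
#'
#' The binding-site table (CircInteractome-style) needs columns `circ_id`,
#' `mirna_id`, `context_score_percentile` (0-100); duplicate
#' (circ, miRNA) rows are retained, since one circRNA can carry several
#' sites for the same miRNA. The target table (TargetScan-style) needs
#' `mirna_id`, `gene_id`, `cumulative_weighted_context` and is
#' deduplicated to the best (minimum, i.e. strongest) score per
#' (miRNA, gene) pair.
#'
#' @param sites_path TSV of binding sites.
#' @param targets_path TSV of miRNA targets.
#' @return list with elements `sites` and `targets`.
#' @export
read_interaction_tables <- function(sites_path, targets_path) {
  sites <- read_tsv_strict(sites_path)
  targets <- read_tsv_strict(targets_path)
  list(sites = validate_binding_sites(sites),
       targets = validate_targets(targets))
}

validate_binding_sites <- function(sites) {
  need <- c("circ_id", "mirna_id", "context_score_percentile")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("binding-site table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  p <- sites$context_score_percentile
  if (nrow(sites) && any(!is.finite(p) | p < 0 | p > 100))
    stop("context_score_percentile outside [0, 100]", call. = FALSE)
  sites
}

validate_targets <- function(targets) {
  need <- c("mirna_id", "gene_id", "cumulative_weighted_context")
  miss <- setdiff(need, names(targets))
  if (length(miss))
    stop("target table lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(targets)) return(targets)
  # best (minimum) score per (miRNA, gene) pair
  key <- paste(targets$mirna_id, targets$gene_id, sep = "\r")
  o <- order(key, targets$cumulative_weighted_context)
  targets <- targets[o, , drop = FALSE]
  targets <- targets[!duplicated(key[o]), , drop = FALSE]
  rownames(targets) <- NULL
  targets
}

#' Write a bundle of result tables to a directory
#'
#' Writes one TSV per table plus a JSON run manifest holding the config
#' hash, seed, package version and the list of files written. Re-reading
#' any written TSV reproduces the table; identical inputs yield
#' byte-identical files.
#'
#' @param bundle named list of data.frames (e.g. DE tables per contrast,
#'   CLP table, cluster assignments, network table).
#' @param out_dir output directory, created if absent.
#' @param seed integer recorded in the manifest.
#' @param config list recorded (hashed) in the manifest.
#' @return invisibly, the manifest list.
#' @export
write_results <- function(bundle, out_dir, seed = NA_integer_, config = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  }
  stopifnot(is.list(bundle), !is.null(names(bundle)), all(nzchar(names(bundle))))
  files <- character(0)
  for (nm in names(bundle)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_strict(as.data.frame(bundle[[nm]]), path)
    files <- c(files, basename(path))
  }
  manifest <- list(
    tool = "circsponge",
    version = as.character(utils::packageVersion("circsponge")),
    seed = seed,
    config_hash = rlang::hash(config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export sponge networks as a graph file
#'
#' Nodes are typed (`circRNA`, `miRNA`, `gene`); each triplet contributes
#' a circRNA->miRNA edge and a miRNA->gene edge, de-duplicated across
#' triplets. The sponge type is carried as an edge attribute. The SIF
#' dialect writes `circ_id sponges mirna_id` and `mirna_id targets
#' gene_id` lines.
#'
#' @param networks classified network data.frame (from
#'   [classify_sponge()]); may have zero rows.
#' @param format `"graphml"` or `"sif"`.
#' @param path output file path.
#' @return invisibly, the igraph object that was exported.
#' @export
export_network_graph <- function(networks, format = c("graphml", "sif"), path) {
  if (!is.character(format) || !all(format %in% c("graphml", "sif")))
    stop("unknown graph format: ", paste(setdiff(format, c("graphml", "sif")), collapse = ", "),
         call. = FALSE)
  format <- match.arg(format)
  g <- networks_to_igraph(networks)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    lines <- character(0)
    if (nrow(networks)) {
      sponge <- unique(paste(networks$circ_id, "sponges", networks$mirna_id))
      target <- unique(paste(networks$mirna_id, "targets", networks$gene_id))
      lines <- c(sponge, target)
    }
    writeLines(lines, path)
  }
  invisible(g)
}

# build the typed igraph from a classified network table (internal)
networks_to_igraph <- function(networks) {
  networks <- as.data.frame(networks)
  if (!nrow(networks)) {
    return(igraph::make_empty_graph(n = 0, directed = TRUE))
  }
  circ <- unique(networks$circ_id)
  mir <- unique(networks$mirna_id)
  gene <- unique(networks$gene_id)
  nodes <- data.frame(
    name = c(circ, mir, gene),
    node_type = rep(c("circRNA", "miRNA", "gene"),
                    c(length(circ), length(mir), length(gene))),
    stringsAsFactors = FALSE
  )
  type_attr <- if ("type" %in% names(networks)) networks$type else rep(NA_integer_, nrow(networks))
  e1 <- data.frame(from = networks$circ_id, to = networks$mirna_id,
                   interaction = "sponges", sponge_type = type_attr)
  e2 <- data.frame(from = networks$mirna_id, to = networks$gene_id,
                   interaction = "targets", sponge_type = type_attr)
  edges <- rbind(e1, e2)
  edges <- edges[!duplicated(edges[, c("from", "to")]), , drop = FALSE]
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

# --- low-level TSV helpers -------------------------------------------------
# All package tables are UTF-8, tab-separated, '.' decimal, mandatory header.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
}

write_tsv_strict <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}
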