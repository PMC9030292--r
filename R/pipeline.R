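#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()] — the pipeline simulates its
#' inputs) or `inputs` (named paths `circ`, `linear`, `mrna`, `samples`,
#' `sites`, `targets` — the pipeline reads TSV files) must be given.
#'
#' @param sim optional [sim_config()].
#' @param inputs optional named list of input file paths.
#' @param lfc_min,alpha,alpha_strict differential-expression thresholds.
#' @param min_percentile strict binding-site percentile cutoff.
#' @param max_cwcs inclusive cumulative-weighted-context cutoff.
#' @param k number of feature clusters, or `"auto"` for silhouette
#'   selection over `k_range`.
#' @param k_range candidate cluster numbers for `k = "auto"`.
#' @param linkage,metric clustering options.
#' @param seed integer; overrides the simulation seed when `sim` is used
#'   and is recorded in the manifest.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, inputs = NULL,
                            lfc_min = 1, alpha = 0.05, alpha_strict = FALSE,
                            min_percentile = 95, max_cwcs = -1,
                            k = "auto", k_range = c(2, 8),
                            linkage = "complete", metric = "euclidean",
                            seed = 1L) {
  if (is.null(sim) == is.null(inputs))
    stop("give exactly one of 'sim' or 'inputs'", call. = FALSE)
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- as.integer(seed)
  } else {
    need <- c("circ", "linear", "mrna", "samples", "sites", "targets")
    miss <- setdiff(need, names(inputs))
    if (length(miss))
      stop("inputs lacks path(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(lfc_min >= 0, alpha >= 0, alpha <= 1,
            min_percentile >= 0, min_percentile <= 100)
  structure(list(sim = sim, inputs = inputs,
                 lfc_min = lfc_min, alpha = alpha, alpha_strict = alpha_strict,
                 min_percentile = min_percentile, max_cwcs = max_cwcs,
                 k = k, k_range = as.integer(k_range),
                 linkage = linkage, metric = metric,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' mapping is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: data (simulate or ingest), size factors and
#' dispersions, pairwise Wald DE for circRNAs and mRNAs, CLP, vst +
#' PCA + sample clustering, z-score pattern clustering of the DE
#' circRNAs, interaction-score filtering, network assembly and Type
#' 0/1/2 classification, cascade report. Deterministic given the seed.
#' When `out_dir` is given every result table is written there along
#' with a JSON manifest; if a stage fails, the manifest carries a
#' `FAILED` marker naming the stage and the error is re-thrown.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param out_dir optional output directory.
#' @param verbose print per-stage row counts.
#' @return result bundle: `de_circ`, `de_mrna`, `clp`, `pca`,
#'   `sample_clusters`, `feature_clusters`, `networks`, `report`,
#'   `manifest`, plus `data` (the count matrices and, when simulated,
#'   the planted `truth`).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  current_stage <- "init"
  stage <- function(name) { current_stage <<- name; say("[stage] %s", name) }

  result <- tryCatch({
    stage("data")
    if (!is.null(config$sim)) {
      sim <- simulate_experiment(config$sim)
      inter <- simulate_interaction_tables(sim$truth, config$sim)
      dat <- c(sim, inter)
    } else {
      samples <- read_sample_sheet(config$inputs$samples)
      inter <- read_interaction_tables(config$inputs$sites, config$inputs$targets)
      dat <- list(circ = read_count_matrix(config$inputs$circ, samples, "circ"),
                  linear = read_count_matrix(config$inputs$linear, samples, "linear"),
                  mrna = read_count_matrix(config$inputs$mrna, samples, "mrna"),
                  samples = samples, truth = NULL,
                  sites = inter$sites, targets = inter$targets)
    }
    say("  circ %d x %d, mrna %d x %d, sites %d, targets %d",
        nrow(dat$circ$counts), ncol(dat$circ$counts),
        nrow(dat$mrna$counts), ncol(dat$mrna$counts),
        nrow(dat$sites), nrow(dat$targets))

    stage("differential_expression")
    de_args <- list(lfc_min = config$lfc_min, alpha = config$alpha,
                    alpha_strict = config$alpha_strict)
    de_circ <- do.call(pairwise_de_all, c(list(dat$circ), de_args))
    de_mrna <- do.call(pairwise_de_all, c(list(dat$mrna), de_args))
    de_circ_ids <- de_feature_ids(de_circ)
    de_gene_ids <- de_feature_ids(de_mrna)
    say("  DE circRNAs: %d; DE genes: %d", length(de_circ_ids), length(de_gene_ids))

    stage("clp")
    clp <- compute_clp(dat$circ, dat$linear)

    stage("exploratory")
    sf_circ <- estimate_size_factors(dat$circ, pseudo_reference = TRUE)
    vst <- vst_transform(dat$circ, sf_circ)
    pca <- run_pca(t(vst))
    sample_clusters <- cluster_features(t(vst), k = 3L,
                                        linkage = config$linkage,
                                        metric = config$metric)

    stage("pattern_clustering")
    feature_clusters <- NULL
    cluster_selection <- NULL
    if (length(de_circ_ids) >= 3L) {
      z <- zscore_profiles(vst[de_circ_ids, , drop = FALSE])
      if (identical(config$k, "auto")) {
        kr <- seq(max(2L, config$k_range[1L]),
                  min(config$k_range[2L], length(de_circ_ids) - 1L))
        cluster_selection <- select_cluster_number(z, kr,
                                                   linkage = config$linkage,
                                                   metric = config$metric)
        k_use <- if (isTRUE(cluster_selection$no_structure)) NA_integer_
                 else cluster_selection$k
      } else k_use <- as.integer(config$k)
      if (!is.na(k_use))
        feature_clusters <- cluster_features(z, k_use,
                                             linkage = config$linkage,
                                             metric = config$metric)
    }

    stage("networks")
    sites_kept <- filter_binding_sites(dat$sites, config$min_percentile)
    targets_kept <- filter_targets(dat$targets, config$max_cwcs)
    trip <- assemble_networks(sites_kept, targets_kept, de_gene_ids)
    networks <- classify_sponge(trip, de_circ, de_mrna,
                                lfc_min = config$lfc_min, fdr_max = config$alpha)
    report <- summarize_networks(networks, cascade = list(
      sites_in = nrow(dat$sites),
      sites_kept = nrow(sites_kept),
      distinct_mirnas = attr(sites_kept, "distinct_mirnas"),
      targets_in = nrow(dat$targets),
      targets_kept = nrow(targets_kept),
      genes_de_kept = length(de_gene_ids)))
    say("  cascade: sites %d -> %d; targets %d -> %d; DE genes %d; networks %d (%d/%d/%d)",
        report$sites_in, report$sites_kept, report$targets_in,
        report$targets_kept, report$genes_de_kept, report$networks_built,
        report$n_type2, report$n_type1, report$n_type0)

    list(data = dat, de_circ = de_circ, de_mrna = de_mrna, clp = clp,
         pca = pca, sample_clusters = sample_clusters,
         feature_clusters = feature_clusters,
         cluster_selection = cluster_selection,
         networks = networks, report = report)
  }, error = function(e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(tool = "circsponge", status = "FAILED", stage = current_stage,
             error = conditionMessage(e)),
        file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
    }
    stop(sprintf("pipeline stage '%s' failed: %s", current_stage,
                 conditionMessage(e)), call. = FALSE)
  })

  stage("report")
  if (!is.null(out_dir)) {
    bundle <- c(
      stats::setNames(lapply(result$de_circ, identity),
                      paste0("de_circ_", names(result$de_circ))),
      stats::setNames(lapply(result$de_mrna, identity),
                      paste0("de_mrna_", names(result$de_mrna))),
      list(clp = result$clp,
           sample_clusters = data.frame(
             sample_id = names(result$sample_clusters$labels),
             cluster = unname(result$sample_clusters$labels)),
           networks = result$networks))
    if (!is.null(result$feature_clusters))
      bundle$feature_clusters <- data.frame(
        feature_id = names(result$feature_clusters$labels),
        cluster = unname(result$feature_clusters$labels))
    manifest <- write_results(bundle, out_dir, seed = config$seed,
                              config = unclass(config))
    jsonlite::write_json(unclass(result$report),
                         file.path(out_dir, "filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    export_network_graph(result$networks, "graphml",
                         file.path(out_dir, "networks.graphml"))
    export_network_graph(result$networks, "sif",
                         file.path(out_dir, "networks.sif"))
    result$manifest <- manifest
  }
  result
}
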