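#' Simulation configuration
#'
#' Parameters of the synthetic three-stage experiment. Counts are
#' negative-binomial with variance `mu + alpha * mu^2`; each circRNA's
#' back-splice and linear host counts arise from a binomial split of a
#' total host count at the planted circular fraction (CLP), so the
#' expected circ/(circ+linear) ratio equals the planted CLP exactly.
#'
#' @param n_circ number of circRNA features.
#' @param n_mrna number of mRNA features.
#' @param n_mirna size of the miRNA id pool (must cover the planted
#'   triplets).
#' @param reps_per_stage replicates per stage (default 3, as in a
#'   three-donor staged design).
#' @param baseline_mean_log_range natural-log range of baseline mean
#'   expression for unreserved features.
#' @param dispersion NB dispersion alpha >= 0 shared across features
#'   (0 = Poisson).
#' @param frac_de fraction of unreserved features given a planted stage
#'   effect.
#' @param planted_lfc_range range of |log2FC| for planted effects; the
#'   lower bound must be >= 1 so that planted effects are callable under
#'   the |log2FC| >= 1 rule.
#' @param clp_range range in (0, 1) for the planted circular fraction.
#' @param n_planted_type2,n_planted_type1,n_planted_type0 numbers of
#'   sponge triplets planted with the respective intended type.
#' @param depth_range sample depth factors are drawn log-uniformly from
#'   this interval, so size-factor estimation is non-trivial.
#' @param seed integer seed determining the entire dataset.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_circ = 120, n_mrna = 300, n_mirna = 40,
                       reps_per_stage = 3,
                       baseline_mean_log_range = c(log(20), log(500)),
                       dispersion = 0.05,
                       frac_de = 0.15,
                       planted_lfc_range = c(1, 2.5),
                       clp_range = c(0.05, 0.6),
                       n_planted_type2 = 5, n_planted_type1 = 3,
                       n_planted_type0 = 4,
                       depth_range = c(0.5, 2),
                       seed = 1L) {
  cfg <- list(n_circ = as.integer(n_circ), n_mrna = as.integer(n_mrna),
              n_mirna = as.integer(n_mirna),
              reps_per_stage = as.integer(reps_per_stage),
              baseline_mean_log_range = as.numeric(baseline_mean_log_range),
              dispersion = as.numeric(dispersion),
              frac_de = as.numeric(frac_de),
              planted_lfc_range = as.numeric(planted_lfc_range),
              clp_range = as.numeric(clp_range),
              n_planted_type2 = as.integer(n_planted_type2),
              n_planted_type1 = as.integer(n_planted_type1),
              n_planted_type0 = as.integer(n_planted_type0),
              depth_range = as.numeric(depth_range),
              seed = as.integer(seed))
  n_trip <- cfg$n_planted_type2 + cfg$n_planted_type1 + cfg$n_planted_type0
  if (cfg$n_circ < 1L || cfg$n_mrna < 1L || cfg$reps_per_stage < 1L)
    stop("degenerate config: features and replicates must be >= 1", call. = FALSE)
  if (cfg$dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (cfg$frac_de < 0 || cfg$frac_de > 1)
    stop("frac_de must lie in [0, 1]", call. = FALSE)
  if (n_trip > 0 && cfg$planted_lfc_range[1L] < 1)
    stop("planted_lfc_range lower bound must be >= 1", call. = FALSE)
  if (cfg$frac_de > 0 && cfg$planted_lfc_range[1L] < 1)
    stop("planted_lfc_range lower bound must be >= 1", call. = FALSE)
  if (any(cfg$clp_range <= 0) || any(cfg$clp_range >= 1) ||
        cfg$clp_range[1L] > cfg$clp_range[2L])
    stop("clp_range must lie within (0, 1)", call. = FALSE)
  if (n_trip > cfg$n_mirna)
    stop("n_mirna too small for the planted triplets", call. = FALSE)
  if (cfg$n_circ < n_trip || cfg$n_mrna < n_trip)
    stop("too few features to host the planted triplets", call. = FALSE)
  structure(cfg, class = "sim_config")
}

contrast_names <- function() c("ST2vsST1", "ST3vsST1", "ST3vsST2")

# planted log2FC per contrast from per-stage log2 offsets
offsets_to_lfc <- function(off) {
  c(ST2vsST1 = off[["ST2"]] - off[["ST1"]],
    ST3vsST1 = off[["ST3"]] - off[["ST1"]],
    ST3vsST2 = off[["ST3"]] - off[["ST2"]])
}

rnb <- function(n, mu, alpha) {
  if (alpha == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Simulate a staged circRNA/mRNA experiment with planted truth
#'
#' Draws NB counts for three stages times `reps_per_stage` replicates.
#' A subset of features carries planted stage effects (one shifted stage
#' per feature, signed log2 shift). Dedicated feature blocks host the
#' planted sponge triplets:
#' * Type 2: strong co-directional circ and gene effects (|log2FC| in
#'   2-2.5) at high expression, detectable at FDR <= 0.05.
#' * Type 1: the gene effect is strong (so the gene passes the DE gate)
#'   but the circRNA effect is small (1.0-1.2) at low expression, so its
#'   fold change keeps |log2FC| >= 1 while its adjusted p typically
#'   misses the FDR cutoff.
#' * Type 0: strong effects of opposite sign in circ and gene, so the
#'   same-sign clause can never hold.
#'
#' Circular and linear host counts come from a binomial split of a total
#' host NB count at the feature's planted CLP.
#'
#' @param config a [sim_config()].
#' @return list with `circ`, `linear`, `mrna` ([count_matrix()]s),
#'   `samples` (sample sheet) and `truth` (planted log2FCs per contrast,
#'   planted CLP per stage, planted triplets, sample depth factors).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stages <- c("ST1", "ST2", "ST3")
  reps <- config$reps_per_stage
  samples <- data.frame(
    sample_id = paste0(rep(stages, each = reps), "_r", rep(seq_len(reps), 3)),
    stage = rep(stages, each = reps),
    replicate = rep(seq_len(reps), 3),
    stringsAsFactors = FALSE
  )
  ns <- nrow(samples)
  depth <- exp(stats::runif(ns, log(config$depth_range[1L]), log(config$depth_range[2L])))
  names(depth) <- samples$sample_id

  n2 <- config$n_planted_type2; n1 <- config$n_planted_type1; n0 <- config$n_planted_type0
  n_trip <- n2 + n1 + n0
  circ_ids <- sprintf("circ_%04d", seq_len(config$n_circ))
  gene_ids <- sprintf("gene_%04d", seq_len(config$n_mrna))
  mirna_ids <- sprintf("miR_%04d", seq_len(config$n_mirna))

  # per-feature planted structure: baseline mean, affected stage, signed shift
  plant_block <- function(n_feat, reserved_lfc, reserved_mean_log, frac_de) {
    base <- exp(stats::runif(n_feat, config$baseline_mean_log_range[1L],
                             config$baseline_mean_log_range[2L]))
    shift <- numeric(n_feat)
    affected <- rep(NA_character_, n_feat)
    n_res <- nrow(reserved_lfc)
    if (n_res) {
      base[seq_len(n_res)] <- exp(stats::runif(n_res, reserved_mean_log[seq_len(n_res), 1L],
                                               reserved_mean_log[seq_len(n_res), 2L]))
      shift[seq_len(n_res)] <- reserved_lfc$shift
      affected[seq_len(n_res)] <- reserved_lfc$stage
    }
    free <- setdiff(seq_len(n_feat), seq_len(n_res))
    de <- free[stats::runif(length(free)) < frac_de]
    if (length(de)) {
      shift[de] <- sample(c(-1, 1), length(de), replace = TRUE) *
        stats::runif(length(de), config$planted_lfc_range[1L], config$planted_lfc_range[2L])
      affected[de] <- sample(stages, length(de), replace = TRUE)
    }
    list(base = base, shift = shift, affected = affected)
  }

  strong <- function(n) stats::runif(n, max(2, config$planted_lfc_range[1L]),
                                     max(2.5, config$planted_lfc_range[2L]))
  sgn <- sample(c(-1, 1), n_trip, replace = TRUE)
  hi_mean <- cbind(rep(log(150), n_trip), rep(log(500), n_trip))
  # circRNA reserved block: type2 strong, type1 weak/low-count, type0 strong
  circ_res <- data.frame(
    shift = c(if (n2) sgn[seq_len(n2)] * strong(n2),
              if (n1) sgn[n2 + seq_len(n1)] * stats::runif(n1, 1.0, 1.2),
              if (n0) sgn[n2 + n1 + seq_len(n0)] * strong(n0)),
    stage = rep("ST3", n_trip)
  )
  circ_mean_log <- hi_mean
  if (n1) circ_mean_log[n2 + seq_len(n1), ] <- cbind(rep(log(8), n1), rep(log(20), n1))
  # gene reserved block: always strong; type0 genes flip the sign
  gene_sgn <- sgn
  if (n0) gene_sgn[n2 + n1 + seq_len(n0)] <- -gene_sgn[n2 + n1 + seq_len(n0)]
  gene_res <- data.frame(shift = gene_sgn * strong(n_trip),
                         stage = rep("ST3", n_trip))
  if (!n_trip) {
    circ_res <- data.frame(shift = numeric(0), stage = character(0))
    gene_res <- circ_res
    circ_mean_log <- hi_mean
  }

  circ_plant <- plant_block(config$n_circ, circ_res, circ_mean_log, config$frac_de)
  mrna_plant <- plant_block(config$n_mrna, gene_res, hi_mean, config$frac_de)

  # planted CLP: one circular fraction per circ feature, shared across stages;
  # reserved features get fractions high enough to keep circ counts powered
  clp <- stats::runif(config$n_circ, config$clp_range[1L], config$clp_range[2L])
  if (n_trip) {
    lo <- max(0.3, config$clp_range[1L])
    hi <- max(config$clp_range[2L], 0.6)
    clp[seq_len(n_trip)] <- stats::runif(n_trip, lo, hi)
  }

  stage_mu <- function(plant) {
    off <- matrix(0, length(plant$base), 3L, dimnames = list(NULL, stages))
    has <- !is.na(plant$affected)
    off[cbind(which(has), match(plant$affected[has], stages))] <- plant$shift[has]
    plant$base * 2^off     # features x stages matrix of means
  }
  circ_mu <- stage_mu(circ_plant)   # mean of the CIRC counts
  mrna_mu <- stage_mu(mrna_plant)

  draw_matrix <- function(mu_stage, ids) {
    m <- matrix(0L, nrow(mu_stage), ns, dimnames = list(ids, samples$sample_id))
    for (j in seq_len(ns)) {
      mu <- mu_stage[, samples$stage[j]] * depth[j]
      m[, j] <- rnb(nrow(mu_stage), mu, config$dispersion)
    }
    m
  }

  # total host expression so that the circular share has the drawn mean;
  # binomial thinning of NB(mu, 1/alpha) keeps the dispersion, so circ
  # counts are NB(clp * mu_total, alpha) as the DE model assumes
  total_mu <- circ_mu / clp
  total <- draw_matrix(total_mu, circ_ids)
  circ_counts <- matrix(stats::rbinom(length(total), as.vector(total),
                                      rep(clp, ns)),
                        nrow(total), ns, dimnames = dimnames(total))
  linear_counts <- total - circ_counts
  mrna_counts <- draw_matrix(mrna_mu, gene_ids)

  lfc_of <- function(plant, ids) {
    out <- matrix(0, length(ids), 3L, dimnames = list(ids, contrast_names()))
    has <- !is.na(plant$affected)
    for (i in which(has)) {
      off <- stats::setNames(numeric(3), stages)
      off[plant$affected[i]] <- plant$shift[i]
      out[i, ] <- offsets_to_lfc(off)
    }
    out
  }

  triplets <- data.frame(
    circ_id = circ_ids[seq_len(n_trip)],
    mirna_id = mirna_ids[seq_len(n_trip)],
    gene_id = gene_ids[seq_len(n_trip)],
    type = rep(c(2L, 1L, 0L), c(n2, n1, n0)),
    stringsAsFactors = FALSE
  )[seq_len(n_trip), , drop = FALSE]

  truth <- structure(list(
    circ_lfc = lfc_of(circ_plant, circ_ids),
    mrna_lfc = lfc_of(mrna_plant, gene_ids),
    clp = matrix(clp, config$n_circ, 3L,
                 dimnames = list(circ_ids, stages)),
    triplets = triplets,
    depth = depth,
    mirna_pool = mirna_ids
  ), class = "synthetic_truth")

  list(circ = count_matrix(circ_counts, samples, "circ"),
       linear = count_matrix(linear_counts, samples, "linear"),
       mrna = count_matrix(mrna_counts, samples, "mrna"),
       samples = samples,
       truth = truth)
}

#' Simulate binding-site and target tables around the planted triplets
#'
#' Every planted triplet receives a binding site with context score
#' percentile above 95 and a target row with cumulative weighted context
#' score at or below -1, so it survives both score filters. Decoy rows
#' are added that fail exactly one step of the cascade:
#' * a site at or below percentile 95 (the first decoy sits exactly at
#'   95, exercising the strict boundary) paired with a passing target,
#' * a target with score above -1 paired with a passing site,
#' * a fully passing site/target pair pointing at a gene with no planted
#'   effect, which the differential-expression gate removes.
#'
#' @param truth `synthetic_truth` from [simulate_experiment()].
#' @param config the same [sim_config()].
#' @return list with `sites` and `targets` data.frames.
#' @export
simulate_interaction_tables <- function(truth, config) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(config, "sim_config"))
  trip <- truth$triplets
  bad <- c(setdiff(trip$circ_id, rownames(truth$circ_lfc)),
           setdiff(trip$gene_id, rownames(truth$mrna_lfc)),
           setdiff(trip$mirna_id, truth$mirna_pool))
  if (length(bad))
    stop("planted triplet references unknown id(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  set.seed(config$seed + 101L)
  n <- nrow(trip)
  sites <- data.frame(circ_id = character(0), mirna_id = character(0),
                      context_score_percentile = numeric(0))
  targets <- data.frame(mirna_id = character(0), gene_id = character(0),
                        cumulative_weighted_context = numeric(0))
  if (n) {
    sites <- data.frame(
      circ_id = trip$circ_id, mirna_id = trip$mirna_id,
      context_score_percentile = stats::runif(n, 95.5, 99.9))
    targets <- data.frame(
      mirna_id = trip$mirna_id, gene_id = trip$gene_id,
      cumulative_weighted_context = stats::runif(n, -2.5, -1))

    # decoy miRNAs failing the percentile filter (first one exactly at 95)
    dec_mir <- sprintf("miR_dec_%03d", seq_len(n))
    perc <- stats::runif(n, 50, 95)
    perc[1L] <- 95
    sites <- rbind(sites, data.frame(
      circ_id = trip$circ_id, mirna_id = dec_mir,
      context_score_percentile = perc))
    targets <- rbind(targets, data.frame(
      mirna_id = dec_mir, gene_id = trip$gene_id,
      cumulative_weighted_context = stats::runif(n, -2.5, -1)))

    # weak-score target decoys on the planted miRNAs
    targets <- rbind(targets, data.frame(
      mirna_id = trip$mirna_id,
      gene_id = sprintf("gene_dec_%03d", seq_len(n)),
      cumulative_weighted_context = stats::runif(n, -0.9, -0.1)))

    # full-pass decoys pointing at unreserved (typically non-DE) genes
    n_trip_genes <- n
    null_pool <- setdiff(rownames(truth$mrna_lfc)[truth$mrna_lfc[, 1L] == 0 &
                                                    truth$mrna_lfc[, 2L] == 0 &
                                                    truth$mrna_lfc[, 3L] == 0],
                         trip$gene_id)
    if (length(null_pool)) {
      null_gene <- sample(null_pool, min(n, length(null_pool)))
      gate_mir <- sprintf("miR_gate_%03d", seq_along(null_gene))
      sites <- rbind(sites, data.frame(
        circ_id = trip$circ_id[seq_along(null_gene)], mirna_id = gate_mir,
        context_score_percentile = stats::runif(length(null_gene), 95.5, 99.9)))
      targets <- rbind(targets, data.frame(
        mirna_id = gate_mir, gene_id = null_gene,
        cumulative_weighted_context = stats::runif(length(null_gene), -2.5, -1)))
    }
  }
  rownames(sites) <- rownames(targets) <- NULL
  list(sites = validate_binding_sites(sites), targets = validate_targets(targets))
}

#' Write a simulated experiment to disk in the pipeline's input formats
#'
#' @param sim result of [simulate_experiment()].
#' @param interactions result of [simulate_interaction_tables()].
#' @param out_dir directory to create/write into.
#' @return invisibly, the vector of written paths.
#' @export
write_simulated_inputs <- function(sim, interactions, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  as_tsv <- function(cm) {
    data.frame(feature_id = rownames(cm$counts), cm$counts,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  paths <- c(
    circ = file.path(out_dir, "circ_counts.tsv"),
    linear = file.path(out_dir, "linear_counts.tsv"),
    mrna = file.path(out_dir, "mrna_counts.tsv"),
    samples = file.path(out_dir, "samples.tsv"),
    sites = file.path(out_dir, "binding_sites.tsv"),
    targets = file.path(out_dir, "targets.tsv")
  )
  write_tsv_strict(as_tsv(sim$circ), paths["circ"])
  write_tsv_strict(as_tsv(sim$linear), paths["linear"])
  write_tsv_strict(as_tsv(sim$mrna), paths["mrna"])
  write_tsv_strict(sim$samples, paths["samples"])
  write_tsv_strict(interactions$sites, paths["sites"])
  write_tsv_strict(interactions$targets, paths["targets"])
  invisible(paths)
}
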