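test_that("config validation rejects degenerate or inconsistent settings", {
  expect_error(sim_config(n_circ = 0), "degenerate")
  expect_error(sim_config(reps_per_stage = 0), "degenerate")
  expect_error(sim_config(frac_de = 1.5), "frac_de")
  expect_error(sim_config(planted_lfc_range = c(0.5, 2)), ">= 1")
  expect_error(sim_config(clp_range = c(0, 0.5)), "clp_range")
  expect_error(sim_config(n_mirna = 2), "n_mirna")
})

test_that("the same seed reproduces the dataset bit for bit", {
  cfg <- sim_config(n_circ = 40, n_mrna = 60, seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$circ$counts, b$circ$counts)
  expect_identical(a$linear$counts, b$linear$counts)
  expect_identical(a$mrna$counts, b$mrna$counts)
  ia <- simulate_interaction_tables(a$truth, cfg)
  ib <- simulate_interaction_tables(b$truth, cfg)
  expect_identical(ia, ib)
  c2 <- simulate_experiment(sim_config(n_circ = 40, n_mrna = 60, seed = 43))
  expect_false(identical(a$circ$counts, c2$circ$counts))
})

test_that("simulated counts match the NB mean-variance law", {
  # many replicates of one stage via repeated seeds; variance ~ mu + alpha mu^2
  alpha <- 0.3
  mu <- 200
  set.seed(1)
  x <- rnbinom(20000, mu = mu, size = 1 / alpha)
  expect_lt(abs(var(x) - (mu + alpha * mu^2)) / (mu + alpha * mu^2), 0.1)
  # and through the generator: pooled empirical dispersion near truth
  cfg <- sim_config(n_circ = 400, n_mrna = 10, frac_de = 0, dispersion = alpha,
                    baseline_mean_log_range = c(log(150), log(600)),
                    depth_range = c(1, 1), clp_range = c(0.4, 0.6),
                    n_planted_type2 = 0, n_planted_type1 = 0,
                    n_planted_type0 = 0, seed = 5)
  sim <- simulate_experiment(cfg)
  d <- estimate_dispersions(sim$mrna, rep(1, 9))
  expect_lt(abs(mean(d$raw_alpha) - alpha) / alpha, 0.35)
})

test_that("the binomial split gives the planted CLP in expectation", {
  cfg <- sim_config(n_circ = 60, n_mrna = 10, clp_range = c(0.499, 0.501),
                    baseline_mean_log_range = c(log(500), log(1200)),
                    frac_de = 0, n_planted_type2 = 0, n_planted_type1 = 0,
                    n_planted_type0 = 0, seed = 9)
  sim <- simulate_experiment(cfg)
  clp <- compute_clp(sim$circ, sim$linear)
  expect_true(all(abs(clp$clp - 0.5) < 0.1))
  # circ + linear reconstruct the total host draw exactly
  expect_true(all(sim$circ$counts + sim$linear$counts >= sim$circ$counts))
})

test_that("null simulations produce near-nominal raw p-value rates", {
  rates <- numeric(4)
  for (s in seq_len(4)) {
    cfg <- sim_config(n_circ = 800, n_mrna = 10, frac_de = 0, dispersion = 0.05,
                      n_planted_type2 = 0, n_planted_type1 = 0,
                      n_planted_type0 = 0, seed = 200 + s)
    sim <- simulate_experiment(cfg)
    de <- pairwise_de_all(sim$circ)
    rates[s] <- mean(unlist(lapply(de, function(t) t$pvalue)) <= 0.05)
  }
  expect_gte(mean(rates), 0.02)
  expect_lte(mean(rates), 0.10)
})

test_that("interaction tables plant passing rows and single-failure decoys", {
  cfg <- sim_config(n_circ = 30, n_mrna = 80, n_planted_type2 = 1,
                    n_planted_type1 = 0, n_planted_type0 = 0, seed = 12)
  sim <- simulate_experiment(cfg)
  tabs <- simulate_interaction_tables(sim$truth, cfg)
  trip <- sim$truth$triplets
  planted_site <- tabs$sites[tabs$sites$mirna_id == trip$mirna_id, ]
  expect_equal(nrow(planted_site), 1L)
  expect_gt(planted_site$context_score_percentile, 95)
  planted_target <- tabs$targets[tabs$targets$mirna_id == trip$mirna_id &
                                   tabs$targets$gene_id == trip$gene_id, ]
  expect_lte(planted_target$cumulative_weighted_context, -1)

  # the boundary decoy sits exactly at 95 and is removed by the strict filter
  expect_true(any(tabs$sites$context_score_percentile == 95))
  kept <- filter_binding_sites(tabs$sites)
  expect_false(any(kept$context_score_percentile <= 95))

  # weak-score decoys exist and fail the target filter
  expect_true(any(tabs$targets$cumulative_weighted_context > -1))
  expect_false(any(filter_targets(tabs$targets)$cumulative_weighted_context > -1))

  # corrupted truth is rejected
  bad <- sim$truth
  bad$triplets$circ_id[1] <- "circ_9999"
  expect_error(simulate_interaction_tables(bad, cfg), "unknown id")
})

test_that("planted strong effects are recovered by the DE module", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_circ = 200, n_mrna = 10, frac_de = 0.2,
                      planted_lfc_range = c(2, 2),
                      baseline_mean_log_range = c(log(100), log(500)),
                      n_planted_type2 = 0, n_planted_type1 = 0,
                      n_planted_type0 = 0, seed = 300 + s)
    sim <- simulate_experiment(cfg)
    de <- pairwise_de_all(sim$circ)
    for (ct in names(de)) {
      planted <- abs(sim$truth$circ_lfc[, ct]) >= 1
      hits <- hits + sum(de[[ct]]$is_de & planted)
      total <- total + sum(planted)
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("estimated log2FC tracks the planted value at high counts", {
  cfg <- sim_config(n_circ = 150, n_mrna = 10, frac_de = 0.3,
                    planted_lfc_range = c(2, 2),
                    baseline_mean_log_range = c(log(200), log(800)),
                    n_planted_type2 = 0, n_planted_type1 = 0,
                    n_planted_type0 = 0, seed = 77)
  sim <- simulate_experiment(cfg)
  de <- pairwise_de_all(sim$circ)
  ok <- 0; tot <- 0
  for (ct in names(de)) {
    idx <- which(abs(sim$truth$circ_lfc[, ct]) == 2)
    est <- de[[ct]]$log2FC[match(rownames(sim$truth$circ_lfc)[idx],
                                 de[[ct]]$feature_id)]
    ok <- ok + sum(abs(est - sim$truth$circ_lfc[idx, ct]) <= 0.5)
    tot <- tot + length(idx)
  }
  expect_gte(ok / tot, 0.9)
})

test_that("simulated inputs written to disk re-enter the pipeline unchanged", {
  cfg <- sim_config(n_circ = 25, n_mrna = 40, seed = 6,
                    n_planted_type2 = 2, n_planted_type1 = 1, n_planted_type0 = 1)
  sim <- simulate_experiment(cfg)
  tabs <- simulate_interaction_tables(sim$truth, cfg)
  out <- withr::local_tempdir()
  paths <- write_simulated_inputs(sim, tabs, out)
  sheet <- read_sample_sheet(paths[["samples"]])
  circ <- read_count_matrix(paths[["circ"]], sheet, "circ")
  expect_identical(circ$counts, sim$circ$counts)
  back <- read_interaction_tables(paths[["sites"]], paths[["targets"]])
  expect_equal(nrow(back$sites), nrow(tabs$sites))
})
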