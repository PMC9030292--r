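test_that("binding-site filter is strictly greater than the percentile cutoff", {
  sites <- data.frame(circ_id = "c1", mirna_id = paste0("m", 1:4),
                      context_score_percentile = c(94, 95, 95.1, 99))
  kept <- filter_binding_sites(sites)
  expect_equal(kept$context_score_percentile, c(95.1, 99))
  expect_equal(attr(kept, "distinct_mirnas"), 2L)
  expect_equal(nrow(filter_binding_sites(sites[0, ])), 0L)
})

test_that("target filter is inclusive at the score cutoff", {
  targets <- data.frame(mirna_id = "m1", gene_id = paste0("g", 1:3),
                        cumulative_weighted_context = c(-1.5, -1.0, -0.99))
  kept <- filter_targets(targets)
  expect_equal(kept$cumulative_weighted_context, c(-1.5, -1.0))
  expect_equal(nrow(filter_targets(targets[0, ])), 0L)
})

test_that("both filters agree with a row-wise predicate oracle on random tables", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    s <- data.frame(circ_id = sample(letters[1:5], n, TRUE),
                    mirna_id = sample(letters[6:10], n, TRUE),
                    context_score_percentile = runif(n, 90, 100))
    expect_equal(nrow(filter_binding_sites(s)),
                 sum(s$context_score_percentile > 95))
    t <- data.frame(mirna_id = sample(letters[6:10], n, TRUE),
                    gene_id = paste0("g", seq_len(n)),
                    cumulative_weighted_context = runif(n, -2, 0))
    expect_equal(nrow(filter_targets(t)),
                 sum(t$cumulative_weighted_context <= -1))
    expect_lte(nrow(filter_binding_sites(s)), nrow(s))   # cascade monotone
    expect_lte(nrow(filter_targets(t)), nrow(t))
  }
})

test_that("network assembly joins filtered pairs and gates on DE genes", {
  sites <- data.frame(circ_id = "C1", mirna_id = "m1",
                      context_score_percentile = 99)
  targets <- data.frame(mirna_id = "m1", gene_id = "G1",
                        cumulative_weighted_context = -1.4)
  got <- assemble_networks(sites, targets, de_gene_ids = "G1")
  expect_equal(nrow(got), 1L)
  expect_equal(got$circ_id, "C1")
  expect_equal(nrow(assemble_networks(sites, targets, de_gene_ids = character(0))), 0L)
})

test_that("assembly equals the brute-force triple loop on random tables", {
  set.seed(17)
  for (i in 1:15) {
    circ <- sprintf("C%d", 1:4); mir <- sprintf("m%d", 1:4); gene <- sprintf("G%d", 1:5)
    sites <- data.frame(circ_id = sample(circ, 12, TRUE),
                        mirna_id = sample(mir, 12, TRUE),
                        context_score_percentile = 99)
    targets <- data.frame(mirna_id = sample(mir, 12, TRUE),
                          gene_id = sample(gene, 12, TRUE),
                          cumulative_weighted_context = -2)
    de <- sample(gene, 2)
    got <- assemble_networks(sites, targets, de)
    want <- character(0)
    for (ci in circ) for (mi in mir) for (gi in gene) {
      if (any(sites$circ_id == ci & sites$mirna_id == mi) &&
            any(targets$mirna_id == mi & targets$gene_id == gi) &&
            gi %in% de)
        want <- c(want, paste(ci, mi, gi))
    }
    expect_setequal(paste(got$circ_id, got$mirna_id, got$gene_id), want)
    expect_equal(anyDuplicated(got), 0L)
  }
})

test_that("classifier reproduces the three worked rule applications", {
  contrasts <- c("ST2vsST1", "ST3vsST1", "ST3vsST2")
  de_of <- function(lfc, padj) {
    setNames(lapply(seq_len(3), function(i)
      make_de_table("x", lfc[i], padj[i])), contrasts)
  }
  net <- data.frame(circ_id = "x", mirna_id = "m", gene_id = "x")

  # co-downregulation significant in ST3vsST1: strongly possible sponge
  got <- classify_sponge(net, de_of(c(0, -1.5, 0), c(1, 0.01, 1)),
                         de_of(c(0, -2.1, 0), c(1, 0.003, 1)))
  expect_equal(got$type, 2L)
  expect_equal(got$supporting_contrasts, "ST3vsST1")

  # magnitude and sign hold but FDR fails everywhere: possible sponge
  got <- classify_sponge(net, de_of(c(1.2, 0, 0), c(0.2, 1, 1)),
                         de_of(c(1.0, 0, 0), c(0.3, 1, 1)))
  expect_equal(got$type, 1L)

  # opposite signs in every contrast: no sponge
  got <- classify_sponge(net, de_of(c(1.2, 1.2, 1.2), c(0.01, 0.01, 0.01)),
                         de_of(c(-1.5, -1.5, -1.5), c(0.01, 0.01, 0.01)))
  expect_equal(got$type, 0L)
  expect_equal(got$supporting_contrasts, "")

  expect_error(
    classify_sponge(data.frame(circ_id = "nope", mirna_id = "m", gene_id = "x"),
                    de_of(c(0, 0, 0), c(1, 1, 1)), de_of(c(0, 0, 0), c(1, 1, 1))),
    "nope")
})

test_that("classifier agrees with the brute-force rule evaluator on a dense grid", {
  contrasts <- c("ST2vsST1", "ST3vsST1", "ST3vsST2")
  lfcs <- c(-2, -1.2, -1, -0.5, 0, 0.5, 1, 1.2, 2)
  padjs <- c(0.01, 0.05, 0.2)
  grid <- expand.grid(cl = lfcs, gl = lfcs, cp = padjs, gp = padjs)
  # one varying contrast (ST3vsST1); the others held null
  nets <- data.frame(circ_id = paste0("c", seq_len(nrow(grid))),
                     mirna_id = "m",
                     gene_id = paste0("g", seq_len(nrow(grid))))
  null_c <- make_de_table(nets$circ_id, 0, 1)
  null_g <- make_de_table(nets$gene_id, 0, 1)
  circ_de <- list(ST2vsST1 = null_c,
                  ST3vsST1 = make_de_table(nets$circ_id, grid$cl, grid$cp),
                  ST3vsST2 = null_c)
  gene_de <- list(ST2vsST1 = null_g,
                  ST3vsST1 = make_de_table(nets$gene_id, grid$gl, grid$gp),
                  ST3vsST2 = null_g)
  got <- classify_sponge(nets, circ_de, gene_de)
  want <- mapply(function(cl, gl, cp, gp)
    classify_brute(c(0, cl, 0), c(1, cp, 1), c(0, gl, 0), c(1, gp, 1)),
    grid$cl, grid$gl, grid$cp, grid$gp)
  expect_gte(nrow(grid), 700)
  expect_equal(got$type, unname(want))
})

test_that("the filter report partitions types and rejects inconsistent cascades", {
  nets <- data.frame(circ_id = c("a", "b", "c"), mirna_id = "m", gene_id = "g",
                     type = c(2L, 1L, 0L))
  rep_ <- summarize_networks(nets)
  expect_equal(c(rep_$n_type2, rep_$n_type1, rep_$n_type0), c(1L, 1L, 1L))
  expect_equal(rep_$networks_built, 3L)

  empty <- summarize_networks(nets[0, ])
  expect_equal(empty$networks_built, 0L)
  expect_equal(empty$n_type2 + empty$n_type1 + empty$n_type0, 0L)

  set.seed(23)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    nn <- data.frame(circ_id = paste0("c", 1:n), mirna_id = "m", gene_id = "g",
                     type = sample(0:2, n, TRUE))
    r <- summarize_networks(nn)
    expect_equal(r$n_type2, sum(nn$type == 2))
    expect_equal(r$n_type1 + r$n_type2 + r$n_type0, n)
  }

  untyped <- data.frame(circ_id = "a", mirna_id = "m", gene_id = "g", type = NA)
  expect_error(summarize_networks(untyped), "unclassified")
  expect_error(summarize_networks(nets, cascade = list(sites_in = 5, sites_kept = 9)),
               "monotone")
})
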