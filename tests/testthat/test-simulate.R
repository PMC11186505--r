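test_that("generators are bit-identical under the same seed", {
  e1 <- simulate_expression(n_genes = 50, n_up = 3, n_down = 3, seed = 9)
  e2 <- simulate_expression(n_genes = 50, n_up = 3, n_down = 3, seed = 9)
  expect_identical(e1, e2)
  q <- signed_gene_set(up = paste0("U", 1:10), down = paste0("D", 1:10))
  uni <- c(q$up, q$down, paste0("B", 1:300))
  c1 <- simulate_compendium(n_drugs = 20, sig_size = 30, universe = uni,
                            query = q, n_reversers = 2, seed = 5)
  c2 <- simulate_compendium(n_drugs = 20, sig_size = 30, universe = uni,
                            query = q, n_reversers = 2, seed = 5)
  expect_identical(c1, c2)
  p1 <- simulate_pk_profile(noise_cv = 0.2, seed = 3)
  p2 <- simulate_pk_profile(noise_cv = 0.2, seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(p1$conc,
                         simulate_pk_profile(noise_cv = 0.2, seed = 4)$conc))
})

test_that("planted expression truth is consistent and recoverable", {
  sim <- simulate_expression(n_genes = 100, n_per_group = 5, n_up = 5,
                             n_down = 5, effect_log2fc = 3,
                             noise_sd = 0.1, seed = 1)
  tr <- sim$truth
  expect_length(intersect(tr$planted_up_genes, tr$planted_down_genes), 0)
  expect_true(all(c(tr$planted_up_genes, tr$planted_down_genes) %in%
                  rownames(sim$matrix)))
  # downstream filter recovers exactly the 10 planted genes
  degs <- filter_degs(compute_deg_stats(sim$matrix, sim$groups), "array")
  expect_setequal(degs$up, tr$planted_up_genes)
  expect_setequal(degs$down, tr$planted_down_genes)
})

test_that("no signal and no noise gives logfc exactly 0", {
  sim <- simulate_expression(n_genes = 30, n_up = 0, n_down = 0,
                             effect_log2fc = 0, noise_sd = 0, seed = 2)
  stats <- suppressMessages(compute_deg_stats(sim$matrix, sim$groups))
  expect_true(all(stats$logfc == 0))
})

test_that("null expression data is calibrated at the 5% level", {
  sim <- simulate_expression(n_genes = 10000, n_per_group = 5,
                             n_up = 0, n_down = 0, effect_log2fc = 0,
                             noise_sd = 0.5, seed = 17)
  stats <- compute_deg_stats(sim$matrix, sim$groups)
  frac <- mean(stats$p < 0.05)
  # binomial 99.9% band around 0.05 at n = 10000 is about +/- 0.0072;
  # Welch small-sample calibration adds a little slack
  expect_gt(frac, 0.035)
  expect_lt(frac, 0.065)
})

test_that("perfect-concordance reverser scores 1, zero background scores 0", {
  q <- signed_gene_set(up = paste0("U", 1:8), down = paste0("D", 1:8))
  uni <- c(q$up, q$down, paste0("B", 1:400))
  sim <- simulate_compendium(n_drugs = 10, sig_size = 40, universe = uni,
                             query = q, n_reversers = 1, concordance = 1,
                             background_concordance = 0, seed = 4)
  planted <- sim$truth$planted_reverser_drugs
  for (id in names(sim$compendium)) {
    s <- overlap_score(q, sim$compendium[[id]], "reverse")
    expect_equal(s, if (id %in% planted) 1 else 0)
  }
})

test_that("drug signatures from the generator keep up/down disjoint", {
  q <- signed_gene_set(up = paste0("U", 1:6), down = paste0("D", 1:6))
  uni <- c(q$up, q$down, paste0("B", 1:200))
  sim <- simulate_compendium(n_drugs = 30, sig_size = 25, universe = uni,
                             query = q, n_reversers = 3, seed = 8)
  for (s in sim$compendium) {
    expect_length(intersect(s$up, s$down), 0)
    expect_length(s$up, 25)
  }
})

test_that("enriched synthetic gene sets pass the 3/3 eligibility rule", {
  sim <- simulate_expression(n_genes = 1000, n_up = 10, n_down = 10,
                             seed = 3)
  gs <- simulate_genesets(n_sets = 30, universe = rownames(sim$matrix),
                          truth = sim$truth, n_enriched = 5, seed = 3)
  for (id in gs$truth$enriched_set_ids) {
    expect_gte(length(intersect(gs$sets[[id]],
                                sim$truth$planted_up_genes)), 3)
    expect_gte(length(intersect(gs$sets[[id]],
                                sim$truth$planted_down_genes)), 3)
  }
})

test_that("noiseless kinome runs are exactly linear with max-multiplier rule", {
  pmap <- list(AKT1 = paste0("p", 1:5), ERK1 = paste0("p", 4:8))
  runs <- simulate_kinome_run(pmap, base_slope = 2,
                              activity = c(AKT1 = 1.5), noise_sd = 0,
                              n_wells = 1, seed = 1)
  act <- fit_peptide_slopes(runs[[1]])
  expect_equal(act$r2, rep(1, nrow(act)))
  # peptides p4, p5 are shared: max(1.5, 1) = 1.5
  expect_equal(act$slope[act$peptide_id %in% paste0("p", 1:5)], rep(3, 5))
  expect_equal(act$slope[act$peptide_id %in% paste0("p", 6:8)], rep(2, 3))
})

test_that("noiseless PK profile matches the closed form and starts at 0", {
  prof <- simulate_pk_profile(noise_cv = 0)
  expect_equal(prof$conc[1], 0)
  p <- default_pk_params()
  tgrid <- seq(0, 6, by = 1e-4)
  dense <- one_compartment_conc(tgrid, p$ka, p$ke, p$v_over_f, p$dose)
  tmax_closed <- log(p$ka / p$ke) / (p$ka - p$ke)
  expect_equal(tgrid[which.max(dense)], tmax_closed, tolerance = 1e-3)
  expect_error(one_compartment_conc(1, 0.5, 0.5, 0.19, 15), "degenerate")
})
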