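#!/usr/bin/env Rscript
# Generate every synthetic input of the screen, with ground-truth
# sidecars, under results/synthetic/. All later analysis steps read
# only these files (or regenerate with the same seed).

library(otoscreen)

seed <- 1
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config()

# Two-condition cochlear expression with 20+20 planted DEGs at
# |logFC| = 3, noise sd 0.1 (the regime the |logFC|>2, P<0.05 filter is
# calibrated to).
sim <- simulate_expression(n_genes = 5000, n_per_group = 5, n_up = 20,
                           n_down = 20, seed = seed)
write_expression_matrix(sim$matrix, file.path(out, "expression.tsv"),
                        config = cfg, seed = seed)

# Pathway annotation: 42 sets, 27 seeded with >= 3 up and >= 3 down
# planted DEGs so they pass query eligibility.
gs <- simulate_genesets(n_sets = 42, universe = rownames(sim$matrix),
                        truth = sim$truth, n_enriched = 27, seed = seed)
write_gmt(gs$sets, file.path(out, "genesets.gmt"))

# Drug compendium of 200 signatures, 5 planted reversers of the pooled
# planted signature (concordance 0.8 vs background 0.05).
pooled <- signed_gene_set(up = sim$truth$planted_up_genes,
                          down = sim$truth$planted_down_genes)
comp <- simulate_compendium(n_drugs = 200, sig_size = 120,
                            universe = rownames(sim$matrix),
                            query = pooled, n_reversers = 5,
                            concordance = 0.8,
                            background_concordance = 0.05, seed = seed)
write_compendium(comp$compendium, file.path(out, "compendium.json"))

# Kinome chips: 12 kinases x 12 peptides, AKT1 planted at 1.3x in the
# noise condition; three chips, one control + one case well each.
pmap <- c(lapply(1:11, function(i) sprintf("p%02d_%d", 1:12, i)),
          list(sprintf("akt%02d", 1:12)))
names(pmap) <- c(paste0("KIN", 1:11), "AKT1")
write_gmt(pmap, file.path(out, "kinase_map.gmt"))
for (chip in 1:3) {
  ctrl <- simulate_kinome_run(pmap, noise_sd = 0.5, condition = "control",
                              seed = seed + 10 * chip)[[1]]
  case <- simulate_kinome_run(pmap, activity = c(AKT1 = 1.3),
                              noise_sd = 0.5, condition = "noise",
                              seed = seed + 10 * chip)[[1]]
  write_chip_run(ctrl, file.path(out, sprintf("chip%d_control.tsv", chip)))
  write_chip_run(case, file.path(out, sprintf("chip%d_noise.tsv", chip)))
}

# Perilymph PK: one-compartment oral curve at the sampling design
# (15 mg/kg, 0-6 h), 20% lognormal assay noise.
prof <- simulate_pk_profile(default_pk_params(), noise_cv = 0.2,
                            seed = seed)
write_pk_profile(prof, file.path(out, "pk_profile.csv"))

write_truth(c(sim$truth, gs$truth, comp$truth,
              list(kinase_activity_map = list(AKT1 = 1.3),
                   pk_params = default_pk_params())),
            file.path(out, "truth.json"))
message("synthetic inputs written to ", out)
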