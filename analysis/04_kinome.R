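#!/usr/bin/env Rscript
# Kinome deconvolution: per-peptide kinetic slopes, QC, fold-change
# calls (FC > 1.15 or < 0.85), random-sampling kinase z-scores averaged
# across chips, kinase-family summaries and quartile harmonization
# against an independent effect-size ranking.

library(otoscreen)

seed <- 1
indir <- "results/synthetic"
out <- "results"
cfg <- default_config()

kmap <- read_gmt(file.path(indir, "kinase_map.gmt"))

chips <- lapply(1:3, function(chip) {
  ctrl <- read_chip_run(file.path(indir,
                                  sprintf("chip%d_control.tsv", chip)))
  case <- read_chip_run(file.path(indir,
                                  sprintf("chip%d_noise.tsv", chip)))
  qc_ctrl <- qc_filter(fit_peptide_slopes(ctrl), cfg$kinome$min_signal,
                       cfg$kinome$min_r2)
  qc_case <- qc_filter(fit_peptide_slopes(case), cfg$kinome$min_signal,
                       cfg$kinome$min_r2)
  fc <- peptide_fold_changes(qc_case, qc_ctrl, cfg$kinome$fc_hi,
                             cfg$kinome$fc_lo)
  write_table(fc, file.path(out, sprintf("kinome_fc_chip%d.tsv", chip)),
              cfg, seed)
  message("chip ", chip, ": ", sum(fc$differential), "/", nrow(fc),
          " peptides differentially phosphorylated")
  fc
})

z <- krsa_mean_zscores(
  lapply(chips, function(fc) {
    list(differential_peptides = fc$peptide_id[fc$differential],
         chip_peptides = fc$peptide_id)
  }),
  kmap, n_iter = cfg$kinome$n_iter, seed = seed)
write_table(z, file.path(out, "kinome_zscores.tsv"), cfg, seed)
message("top kinase by mean z: ", z$kinase_id[1], " (z = ",
        signif(z$z_mean[1], 3), ")")

# family summaries on the first chip's comparison, AKT1 family
fam <- family_aggregate(chips[[1]], kmap["AKT1"],
                        comparison = "noise vs control")
write_table(fam, file.path(out, "kinome_families.tsv"), cfg, seed)

# harmonize the sampling z ranking with a mean-log2FC effect ranking
by_fc <- sapply(names(kmap), function(k) {
  mean(chips[[1]]$log2fc[chips[[1]]$peptide_id %in% kmap[[k]]])
})
quart <- quartile_harmonize(list(
  krsa = z$kinase_id,
  effect_size = names(sort(by_fc, decreasing = TRUE))))
write_table(quart, file.path(out, "kinome_quartiles.tsv"), cfg, seed)
message("consensus quartile table written; best kinase ",
        quart$kinase_id[1])
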