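#!/usr/bin/env Rscript
# The in silico connectivity screen: three dataset arms (27 mimic, 13
# mimic, 25 reverse eligible queries), top-50 retrieval per query,
# overlap-score cutoff 0.1, pathway hit counting, multi-pathway drug
# prioritisation and the cross-arm consensus list.

library(otoscreen)

seed <- 1
out <- "results"
cfg <- default_config()

run_arm <- function(n_enriched, mode, arm_seed) {
  sim <- simulate_expression(n_genes = 5000, n_per_group = 5, n_up = 20,
                             n_down = 20, seed = arm_seed)
  degs <- filter_degs(compute_deg_stats(sim$matrix, sim$groups), "array",
                      cfg)
  gs <- simulate_genesets(n_sets = n_enriched + 15,
                          universe = rownames(sim$matrix),
                          truth = sim$truth, n_enriched = n_enriched,
                          seed = arm_seed)
  rec <- enrich_sets(degs, gs$sets, rownames(sim$matrix))
  queries <- eligible_queries(rec, cfg$query$min_up, cfg$query$min_down)
  # Plant the same 5 "true otoprotectant" drugs in every arm (shared
  # compendium seed). A mimic arm seeks drugs that mimic its planted
  # signature, i.e. reverse its flip - so the compendium is planted
  # against the flipped signature in that case.
  comp_query <- if (mode == "mimic") {
    signed_gene_set(up = sim$truth$planted_down_genes,
                    down = sim$truth$planted_up_genes)
  } else {
    signed_gene_set(up = sim$truth$planted_up_genes,
                    down = sim$truth$planted_down_genes)
  }
  comp <- simulate_compendium(n_drugs = 200, sig_size = 120,
                              universe = rownames(sim$matrix),
                              query = comp_query, n_reversers = 5,
                              concordance = 0.8,
                              background_concordance = 0.05,
                              seed = seed)
  results <- lapply(names(queries), function(id) {
    query_compendium(id, queries[[id]], comp$compendium, mode = mode,
                     top_k = cfg$query$top_k)
  })
  names(results) <- names(queries)
  results
}

arms <- list(arm1 = run_arm(27, "mimic", seed + 1),
             arm2 = run_arm(13, "mimic", seed + 2),
             arm3 = run_arm(25, "reverse", seed + 3))

bk <- tally_bookkeeping(arms)
message("connectivity analyses per arm: ",
        paste(bk$n_queries_per_arm, collapse = "/"),
        " (total ", bk$total_queries, "); perturbations: ",
        paste(bk$n_perturbations_per_arm, collapse = "/"),
        " (total ", bk$total_perturbations, ")")
jsonlite::write_json(bk, file.path(out, "bookkeeping.json"),
                     auto_unbox = FALSE)

filtered <- lapply(arms, function(arm) {
  lapply(arm, filter_by_score, cutoff = cfg$query$score_cutoff)
})

for (arm in names(filtered)) {
  hits <- count_pathway_hits(filtered[[arm]], cfg$consensus$min_pathway_hits)
  write_table(hits, file.path(out, paste0("pathway_hits_", arm, ".tsv")),
              cfg, seed)
  retained <- filtered[[arm]][hits$pathway_id[hits$retained]]
  mp <- multi_pathway_drugs(retained, cfg$consensus$min_pathways_per_drug)
  write_table(mp, file.path(out, paste0("multi_pathway_drugs_", arm,
                                        ".tsv")), cfg, seed)
  message(arm, ": ", sum(hits$retained), " pathways retained, ",
          nrow(mp), " multi-pathway drugs")
}

cons <- consensus_across_arms(filtered)
write_table(cons, file.path(out, "consensus_drugs.tsv"), cfg, seed)
message("consensus: ", sum(cons$n_arms == 3),
        " drugs found in all three arms; top drug ", cons$drug_id[1])
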