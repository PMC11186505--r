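#!/usr/bin/env Rscript
# Differential expression and pathway enrichment: call DEGs of
# interest (|logFC| > 2, P < 0.05), rank pathways by enrichment FDR,
# and emit the queries eligible to seed connectivity analyses.

library(otoscreen)

seed <- 1
indir <- "results/synthetic"
out <- "results"
cfg <- default_config()

mat <- read_expression_matrix(file.path(indir, "expression.tsv"))
groups <- sub("_[0-9]+$", "", colnames(mat))
stats <- compute_deg_stats(mat, groups)
write_table(stats, file.path(out, "deg_table.tsv"), cfg, seed)

degs <- filter_degs(stats, "array", cfg)
message(length(degs$up), " up- and ", length(degs$down),
        " down-regulated DEGs of interest")
writeLines(degs$up, file.path(out, "deg_up.txt"))
writeLines(degs$down, file.path(out, "deg_down.txt"))

sets <- read_gmt(file.path(indir, "genesets.gmt"))
rec <- enrich_sets(degs, sets, rownames(mat))
write_table(rec, file.path(out, "enrichment.tsv"), cfg, seed)
top <- top_sets(rec, 30)
message("top pathway: ", top$set_id[1], " (q = ",
        signif(top$q[1], 3), ")")

queries <- eligible_queries(rec, cfg$query$min_up, cfg$query$min_down)
message(length(queries), " pathways eligible as connectivity queries ",
        "(>= 3 up and >= 3 down member DEGs)")
jsonlite::write_json(lapply(queries, unclass),
                     file.path(out, "eligible_queries.json"),
                     auto_unbox = FALSE)
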