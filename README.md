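# otoscreen

An in silico drug-repurposing workflow for noise-induced hearing loss
(NIHL), for hearing researchers and computational biologists who want
to run — and stress-test — a transcriptome connectivity screen without
depending on external web services.

The screen works on signed differential-expression signatures. For a
two-group cochlear dataset, genes with |log2FC| > 2 and P < 0.05
(Welch t-test; single-cell tables use linear |FC| > 1.2 with FDR
q < 0.05) become DEGs of interest. Gene sets are ranked by the
hypergeometric upper tail — with N universe genes, n DEGs and K set
members, p = P[X ≥ k] — and BH-adjusted; every pathway carrying at
least 3 up- and 3 down-regulated member DEGs seeds a connectivity
query. Each query scores a compendium of drug signatures with the
signed overlap score

    score = (#concordant query genes) / (|query up| + |query down|)

where "concordant" means query-up in the drug's up set and query-down
in its down set (mimic mode) or crossed (reverse mode); a cosine
variant handles signed signature vectors. The top 50 perturbations
per query are retained, hits must exceed score 0.1, pathways need ≥ 3
hit drugs, and drugs hitting multiple pathways across dataset arms
form the consensus list. Two validation-stage analyses are included:
kinome peptide-array deconvolution (kinetic slopes → QC → FC > 1.15 /
FC < 0.85 calls → random-sampling kinase z-scores averaged across
chips) and non-compartmental PK of perilymph drug levels (Cmax, Tmax,
trapezoidal AUC, λz, t½, Cl/F, Vz/F).

A synthetic-data module generates every input with planted ground
truth (DEGs, enriched pathways, reverser drugs, active kinases, PK
parameters), so the whole pipeline is testable offline. See
`vignettes/otoscreen-methods.Rmd` for the models, assumptions and
design decisions.

## Worked example

```r
library(otoscreen)

sim   <- simulate_expression(n_genes = 2000, n_per_group = 5,
                             n_up = 10, n_down = 10, seed = 42)
stats <- compute_deg_stats(sim$matrix, sim$groups)
degs  <- filter_degs(stats, "array")
degs
#> <signed_gene_set> 10 up / 10 down

gs  <- simulate_genesets(n_sets = 20, universe = rownames(sim$matrix),
                         truth = sim$truth, n_enriched = 3, seed = 42)
rec <- enrich_sets(degs, gs$sets, rownames(sim$matrix))
head(rec[, c("set_id", "k", "K", "p", "q")], 4)
#>   set_id k  K            p            q
#> 1 SET004 7 19 1.450902e-10 2.901805e-09
#> 2 SET008 7 24 9.683370e-10 8.914600e-09
#> 3 SET002 7 25 1.337190e-09 8.914600e-09
#> 4 SET014 2 19 1.467575e-02 7.337875e-02

queries <- eligible_queries(rec)           # 3 pathways pass the 3-up/3-down rule
comp <- simulate_compendium(n_drugs = 100, sig_size = 80,
                            universe = rownames(sim$matrix), query = degs,
                            n_reversers = 3, seed = 42)
query_compendium(names(queries)[1], queries[[1]], comp$compendium,
                 "reverse", top_k = 5)
#>   query_id  drug_id    mode     score rank
#> 1   SET004 DRUG0061 reverse 1.0000000    1
#> 2   SET004 DRUG0031 reverse 0.7142857    2
#> 3   SET004 DRUG0091 reverse 0.7142857    3
#> 4   SET004 DRUG0038 reverse 0.4285714    4
#> 5   SET004 DRUG0047 reverse 0.4285714    5
```

The three planted reverser drugs (`DRUG0031`, `DRUG0061`, `DRUG0091`)
occupy the top three ranks: each places ~80% of this 7-gene pathway
query's genes in its opposite direction, while background drugs do so
at ~10% per gene.

```r
nca(lloq_censor(simulate_pk_profile(noise_cv = 0)))
#> <nca_result>
#>   Cmax 66.9 ng/ml at Tmax 0.5 h
#>   AUC0-t 199, AUCinf 233.9 ng/ml*h
#>   lambda_z 0.3301 /h (t1/2 2.1 h; 3-point fit, adjR2 1.0000)
#>   Cl/F 0.0641 (mg/kg)/(ng/ml)/h, Vz/F 0.194 (mg/kg)/(ng/ml)
```

The noise-free perilymph profile (oral 15 mg/kg, sampled 0–6 h, LLOQ
5 ng/ml) returns the generator's parameters: half-life 2.1 h, peak at
30 min, clearance dose/AUCinf ≈ 0.064.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic
data and write their tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`01_simulate.R` writes all inputs (expression TSV, gene-set GMT,
compendium JSON, chip-run TSVs, PK CSV, truth JSON);
`02_deg_enrichment.R` calls DEGs and ranks pathways;
`03_connectivity_consensus.R` runs the three-arm screen (27/13/25
queries), hit counting and the cross-arm consensus;
`04_kinome.R` runs the kinome stage chip by chip; `05_pk_nca.R` the
pharmacokinetics.

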