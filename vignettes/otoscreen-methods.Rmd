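---
title: "Methods: transcriptome connectivity screening, kinome deconvolution and perilymph NCA"
author: "otoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptome connectivity screening, kinome deconvolution and perilymph NCA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otoscreen)
```

# The problem

Noise-induced hearing loss (NIHL) has no approved drug therapy. A
practical route to candidates is in silico drug repurposing: take
transcriptomes of cochleae that resist or succumb to noise trauma,
derive signed differential-expression signatures, and search a
compendium of drug perturbation signatures for compounds that *mimic*
a protective signature or *reverse* a damage signature. `otoscreen`
implements that screen end to end, together with the two downstream
quantitative analyses used to validate a candidate: deconvolution of
kinome peptide-array kinetics into upstream-kinase activity scores,
and non-compartmental pharmacokinetics (NCA) of drug levels measured
in inner-ear perilymph.

Because the source datasets of such screens are typically heterogeneous
public microarray/RNA-seq studies, the package ships a synthetic-data
module that generates every input with known ground truth. All claims
the test suite makes are claims about recovery of planted signal under
the generator's assumptions, not about any particular public dataset.

# Differential expression

For a two-group log2-scale matrix, `compute_deg_stats()` reports per
gene the log2 fold change (case minus control mean), a two-sample
unequal-variance (Welch) t-test p-value, and Benjamini–Hochberg FDR
q-values (`stats::p.adjust`). Genes are ranked by p, ties broken by
|logFC| then gene ID, so reports are reproducible.

A deliberate design choice: the original screens ran GEO2R (limma) on
public series, or took published DEG lists as-is. This package uses a
plain Welch test instead of moderated statistics. Everything downstream
consumes only the thresholded gene sets, and with the effect sizes the
screen targets (|logFC| > 2) the moderation of per-gene variances does
not change set membership in any regime we simulate; replicating
limma's shrinkage is therefore out of scope. Precomputed DEG tables
enter directly at `filter_degs()`.

Two threshold regimes are exposed (`default_config()`):

* **array regime** — |logFC| > 2 and P < 0.05 (strict inequalities),
  for microarray/bulk data. Upstream descriptions sometimes quote
  |logFC| > 1 for the initial download; the DEG-of-interest cutoff here
  defaults to 2 and is configurable (`deg.logfc_cut`).
* **scrna regime** — linear |FC| > 1.2 (i.e. |logFC| > log2 1.2) with
  FDR q < 0.05, for single-cell-derived tables. Records lacking a q are
  rejected rather than imputed: silently treating p as q would loosen
  the filter.

Degenerate genes (zero variance in both groups) take p = 1 when the
means agree and p = 0 when they differ — the limiting values of the t
test — with a logged note.

# Pathway enrichment and query eligibility

`enrich_sets()` scores each gene set by the one-sided hypergeometric
upper tail: with `N` universe genes, `n` DEGs and `K` in-universe set
members, `p = P[X >= k]` for observed overlap `k`, via
`stats::phyper`; FDR across sets by Benjamini–Hochberg. The universe
defaults to all genes in the expression matrix (or the DEG table's
gene column for precomputed input). Sets are trimmed to the universe
first; sets with fewer than two in-universe members are skipped with a
note, and a DEG missing from the universe is an error, because it
means the universe was mis-specified. The GO hierarchy is ignored:
sets are flat lists, which is what a ranked-pathway screen consumes.

A pathway may seed a connectivity query only if it contains at least
3 up- and 3 down-regulated member DEGs (`eligible_queries()`); the
query is exactly those member DEGs. Eligibility counts use *all*
member DEGs of interest, not a significance-flagged subset — the
simplest reading that makes eligibility a property of the pathway's
DEG content alone.

# Connectivity scoring

A drug signature is a pair of disjoint up/down gene sets, optionally
with a signed characteristic vector. Two scores are implemented:

* **overlap score** (`overlap_score()`): the fraction of query genes
  whose direction is concordant with the signature — in mimic mode
  query-up∩sig-up plus query-down∩sig-down, in reverse mode the sides
  crossed — divided by the *full* query size. Genes absent from a
  signature count as discordant. This makes scores comparable across
  drugs with different gene coverage, at the cost of penalising drugs
  assayed on narrow gene spaces; the alternative (normalising by the
  intersection) would inflate small-coverage drugs. The score obeys an
  exact duality, `mimic(sig) = reverse(flip(sig))`, which the test
  suite checks on 10^4 random pairs.
* **cosine score** (`cosine_score()`): cosine similarity between the
  ±1 encoding of the query and the signature vector over their shared
  genes, for compendia that provide signed characteristic vectors
  (ranking by descending similarity equals ranking by ascending
  cosine distance).

`query_compendium()` scores every drug, sorts by score descending with
drug-ID tie-break (so results are invariant to compendium order), and
returns the top 50 by default. `filter_by_score()` applies the strict
`score > 0.1` cutoff, i.e. at least 10% of the query genes concordant.
The scoring engine behind the public L1000-based services additionally
uses characteristic-direction vectors over landmark genes; this module
implements the published set-based score semantics, and concordance
with any live service is explicitly not a goal.

# Hits, pathways of interest, consensus

A *hit* is a drug surviving the score cutoff within one pathway's
ranked list; hit counting happens after the cutoff (a flag can move it
before). Pathways with ≥ 3 distinct hit drugs are retained
(`count_pathway_hits()`), drugs hitting ≥ 2 retained pathways are
prioritised (`multi_pathway_drugs()`), and `consensus_across_arms()`
unions arms, ranking drugs by the number of arms, then pathways, then
ID. Drug identity is the case-folded perturbation name; no chemical
deduplication is attempted. `tally_bookkeeping()` reports the
conservation identities (queries per arm × top-k = perturbations per
arm, summing to the total) that anchor the acceptance checks.

# Kinome deconvolution

Peptide-array kinetics are reduced in four stages:

1. **slopes** — per-peptide OLS slope of intensity vs exposure time
   (`fit_peptide_slopes()`), with R² defined as 0 for a zero-variance
   response; at least three exposures are required.
2. **QC** — peptides with maximum raw signal ≤ 5 (inactive) or
   R² < 0.90 (non-linear post-wash) are excluded with logged reasons.
3. **fold changes** — FC is the ratio of case to control slopes, each
   averaged over replicate wells of peptides passing QC in every well
   of the condition; FC > 1.15 or FC < 0.85 (strict) calls a peptide
   differentially phosphorylated. Calls are invariant to any common
   rescaling of intensities.
4. **KRSA z-scores** — for each kinase, the observed number of
   differential peptides among its mapped peptides is compared to a
   null of `n_iter = 2000` uniform random peptide subsets of the same
   size drawn without replacement from the QC-passed chip peptides;
   z = (obs − mean)/sd, computed per chip and averaged across chips
   (`krsa_mean_zscores()`). A degenerate null (sd < 10⁻¹², e.g. a
   kinase mapping every peptide) reports z = 0 rather than dividing by
   zero. Sampling is exactly the hypergeometric null, which the tests
   exploit: on chips of ≤ 12 peptides the z agrees with the
   closed-form hypergeometric mean/sd within Monte-Carlo error at 10⁵
   iterations.

Peptides mapped to several kinases are generated with the *maximum*
activity multiplier (a peptide is phosphorylated by whichever mapped
kinase is most active); the kinase→peptide map itself is consumed as a
GMT input, not reconstructed from prediction servers.
`family_aggregate()` emits per-family mean ± SD of peptide log2 fold
changes per comparison (e.g. AKT/ERK putative-target families), and
`quartile_harmonize()` integrates rankings from ≥ 2 assignment methods
by reducing each to quartiles 1–4 with `ceiling(4·rank/n)` (quartile 1
= top; kinases absent from a method stay NA). The differential-peptide
definition feeding KRSA is the FC-threshold rule above; the upstream
tools' unpublished advancement criteria are not reproduced.

# Non-compartmental pharmacokinetics

`nca()` computes Cmax and Tmax by argmax (earliest time on ties),
AUC0–t by the linear trapezoid (configurable in principle; the linear
rule is used throughout because the sampled profiles here have few
points and sub-LLOQ tails where log-down interpolation is undefined),
and the terminal slope λz by least squares on log C over the
contiguous window of ≥ 3 quantifiable post-peak points ending at the
last quantifiable point that maximises adjusted R². Then
t½ = ln2/λz, AUCinf = AUC0–t + C_last/λz, Cl/F = dose/AUCinf,
Vz/F = Cl/F/λz. A non-positive fitted λz is an explicit error. LLOQ
censoring (`lloq_censor()`, default 5 ng/ml) zeroes sub-LLOQ values —
pre-peak values enter the AUC as 0, post-peak values are additionally
excluded from the λz fit.

The generator's reference parameters (`default_pk_params()`) are
derived from the published perilymph NCA values for orally dosed
zorifertinib: ke = ln2/2.1 h⁻¹, Vz/F = 0.19 (mg/kg)/(ng/ml), dose
15 mg/kg, and ka = 6.2 h⁻¹ chosen so the model peaks at 0.5 h. Two
published conventions deserve note. First, the printed clearance
(0.06) equals dose/AUCinf (0.19 × 0.33 ≈ 0.063), not dose/AUC0–t
(15/189.9 ≈ 0.079); this package computes both AUCs and defines Cl/F
on AUCinf. Second, the model curve implied by those parameters peaks
near 67 ng/ml, whereas the measured mean Cmax was ~100 ng/ml — the
printed parameter set is not exactly self-consistent with the
measured curve, so the generator reproduces the parameters, not the
Cmax, and no value was tuned to close the gap.

# The synthetic-data module

Each generator emulates one input class with planted ground truth:

* **expression** — Gaussian noise on the log2 scale around uniform
  baselines (4–12 log2 units), planted ±effect shifts. Defaults:
  12,488 genes (the motivating platform's probe count; the workflow
  studies here use 5,000–10,000 to keep runtimes in seconds), 5
  samples per group, 20+20 planted DEGs, effect 3 log2 units, noise
  sd 0.1 — the regime the |logFC| > 2 filter is calibrated to defeat
  or pass by design.
* **compendium** — planted reversers place query genes in their
  opposite set by independent Bernoulli draws at concordance 0.8
  (background 0.05–0.1), padded with off-query genes so padding never
  moves a score; realized concordance therefore varies binomially.
* **gene sets** — enriched sets are seeded with ≥ 3 planted genes per
  direction (guaranteeing query eligibility); background sets draw
  uniformly from the universe, so at the default universe sizes a
  background set passes the 3/3 rule with negligible probability.
* **kinome** — intensities `base_slope · multiplier · exposure` plus
  Gaussian noise at exposures 5/25/100 ms; multi-kinase peptides use
  the maximum multiplier.
* **PK** — the one-compartment oral curve above with multiplicative
  lognormal noise (mean 1) of a chosen CV, the standard bioanalytical
  error model for strictly positive concentrations.

Every generator is bit-reproducible under its seed. Internally each
generator seeds R's RNG with a stream derived from (seed, generator
label): passing the same seed to two different generators yields
*independent* draws. This matters — seeding the expression and
gene-set generators identically with a shared raw seed would make the
"random" background sets retrace the planted-gene sampling sequence
and look spectacularly enriched.

What the generators do *not* model: probe-level microarray artifacts,
count noise and dropout of scRNA-seq, batch effects, correlated genes,
non-linear chip saturation, or assay calibration drift. Passing tests
therefore demonstrate correctness of the screen's logic and
statistics under idealised noise, and say nothing about robustness to
those real-data pathologies.

# Problem sizes and numerical choices

The test suite and the acceptance workflow use: 5,000-gene arms (27,
13 and 25 planted-enriched pathways; 42/28/40 sets total) with a
200-drug compendium and top-50 retrieval; a 10,000-gene null and
recovery matrix; 144-peptide chips (12 kinases × 12 peptides, three
chips); exhaustive hypergeometric enumeration up to N = 12; KRSA
oracle comparison at 10⁵ resamples on a 12-peptide chip; PK grids of
6 (sampling design) to 97 (dense) points. These sizes were chosen so
the whole suite completes in well under a minute of CPU while leaving
every statistical comparison comfortably powered.

Numerical details: BH is delegated to `stats::p.adjust`; the
hypergeometric tail to `stats::phyper` (exact to ~10⁻¹⁵ relative);
ties in every ranking are broken lexicographically; the KRSA sd floor
is 10⁻¹²; λz windows require ≥ 3 points so adjusted R² is defined;
config hashes use a 32-bit FNV-1a implemented in exact double
arithmetic.

# Limitations

* Welch statistics, not moderated; small-n arrays with strong
  variance heterogeneity may call fewer DEGs than limma would.
* The overlap score's full-query denominator penalises drugs assayed
  on narrow gene spaces.
* The consensus stage works at the perturbation-name level; salts,
  stereoisomers and synonyms are distinct drugs.
* KRSA inherits the kinase→peptide map's quality; mapping bias
  propagates directly into z-scores.
* NCA on sparse grids (6 points) estimates λz from 3–4 points; with
  noisy data the half-life carries wide uncertainty, as the noisy
  demonstration profile in `analysis/05_pk_nca.R` shows.
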