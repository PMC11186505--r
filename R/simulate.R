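#' Simulate a two-condition expression matrix with planted DEGs
#'
#' Emulates a two-group cochlear expression study on the log2 scale:
#' background genes share the same mean in both groups; planted up
#' genes have a group-mean difference of `+effect_log2fc`, planted down
#' genes `-effect_log2fc`; i.i.d. Gaussian noise of sd `noise_sd` is
#' added everywhere. Baseline abundances are uniform on \[4, 12\] log2
#' units (a typical microarray intensity range). Identical seeds give
#' bit-identical output.
#'
#' The defaults reflect the calibration of the downstream DEG filter
#' (`|logFC| > 2`, `P < 0.05`): a planted effect of 3 log2 units with
#' sd 0.1 noise at n = 5 per group is recovered exactly.
#'
#' @param n_genes number of genes (default 12488, the probe count of
#'   the motivating microarray platform)
#' @param n_per_group samples per group (>= 3)
#' @param n_up,n_down planted up-/down-regulated gene counts
#' @param effect_log2fc planted group-mean difference (log2 units, > 0)
#' @param noise_sd Gaussian noise sd (log2 units, >= 0)
#' @param seed integer seed
#' @return list with `matrix` (genes x samples), `groups` (column
#'   labels, "control"/"case"), and `truth` (a list with
#'   `planted_up_genes`, `planted_down_genes`)
#' @export
simulate_expression <- function(n_genes = 12488, n_per_group = 5,
                                n_up = 20, n_down = 20,
                                effect_log2fc = 3, noise_sd = 0.1,
                                seed = 1) {
  if (n_genes < 1 || n_up < 0 || n_down < 0) stop("non-positive counts")
  if (n_up + n_down >= n_genes) stop("too many planted genes")
  if (effect_log2fc < 0) stop("effect_log2fc must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_per_group < 3) stop("n_per_group must be >= 3")
  set.seed(derive_seed(seed, "expression"))
  genes <- sprintf("G%05d", seq_len(n_genes))
  planted <- sample(genes, n_up + n_down)
  up <- sort(utils::head(planted, n_up))
  down <- sort(utils::tail(planted, n_down))
  base <- stats::runif(n_genes, 4, 12)
  shift <- numeric(n_genes)
  shift[match(up, genes)] <- effect_log2fc
  shift[match(down, genes)] <- -effect_log2fc
  n_s <- 2 * n_per_group
  groups <- rep(c("control", "case"), each = n_per_group)
  mu <- outer(base, rep(1, n_s)) +
    outer(shift, as.numeric(groups == "case"))
  mat <- mu + matrix(stats::rnorm(n_genes * n_s, 0, noise_sd),
                     n_genes, n_s)
  dimnames(mat) <- list(genes,
                        paste0(groups, "_", rep(seq_len(n_per_group), 2)))
  list(matrix = mat, groups = groups,
       truth = list(planted_up_genes = up, planted_down_genes = down))
}

#' Simulate a drug-signature compendium with planted reversers
#'
#' Emulates a perturbation-signature compendium against a known signed
#' query. Planted "reverser" drugs place each query up-gene in their
#' down set (and vice versa) independently with probability
#' `concordance`; background drugs do so with probability
#' `background_concordance`. Remaining signature slots are filled with
#' genes drawn from the universe outside the query, so they never
#' change the overlap score. Realized concordance therefore varies
#' binomially around the target.
#'
#' @param n_drugs compendium size
#' @param sig_size genes per signature side
#' @param universe character vector of gene IDs
#' @param query a [signed_gene_set()], non-empty
#' @param n_reversers number of planted reverser drugs (<= n_drugs)
#' @param concordance per-gene reversal probability for planted drugs
#' @param background_concordance same for background drugs (strictly
#'   smaller)
#' @param seed integer seed
#' @return list with `compendium` (named list of [drug_signature()])
#'   and `truth` (list with `planted_reverser_drugs`)
#' @export
simulate_compendium <- function(n_drugs = 200, sig_size = 150,
                                universe, query, n_reversers = 5,
                                concordance = 0.8,
                                background_concordance = 0.1,
                                seed = 1) {
  stopifnot(inherits(query, "signed_gene_set"))
  if (query_size(query) == 0) stop("empty query")
  if (!(background_concordance >= 0 && background_concordance < concordance &&
        concordance <= 1)) {
    stop("need 0 <= background_concordance < concordance <= 1")
  }
  if (n_reversers > n_drugs) stop("n_reversers > n_drugs")
  universe <- unique(normalize_gene_ids(universe))
  filler <- setdiff(universe, c(query$up, query$down))
  if (length(filler) < sig_size) {
    stop("universe too small for the requested signature size")
  }
  set.seed(derive_seed(seed, "compendium"))
  ids <- sprintf("DRUG%04d", seq_len(n_drugs))
  planted <- sort(sample(ids, n_reversers))
  sigs <- lapply(ids, function(id) {
    p <- if (id %in% planted) concordance else background_concordance
    rev_up <- query$down[stats::runif(length(query$down)) < p]
    rev_down <- query$up[stats::runif(length(query$up)) < p]
    pad <- sample(filler, 2 * sig_size)
    up <- utils::head(c(rev_up, pad), sig_size)
    down <- utils::head(c(rev_down, setdiff(pad, up)), sig_size)
    drug_signature(id, up = up, down = down)
  })
  names(sigs) <- ids
  list(compendium = sigs,
       truth = list(planted_reverser_drugs = planted))
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' Emulates a flat pathway annotation. `n_enriched` sets are seeded
#' with at least 3 planted up- and 3 planted down-regulated DEGs (so
#' each passes the 3-up/3-down query-eligibility rule) and padded with
#' random universe genes; the remaining sets draw uniformly from the
#' universe.
#'
#' @param n_sets number of gene sets
#' @param set_size_range integer range (min, max) of set sizes; min must
#'   be >= 8 so enriched sets can hold their planted seed
#' @param universe character vector of gene IDs
#' @param truth list with `planted_up_genes` and `planted_down_genes`
#'   (>= 3 each), e.g. from [simulate_expression()]
#' @param n_enriched number of enriched sets (<= n_sets)
#' @param seed integer seed
#' @return list with `sets` (named list of character vectors) and
#'   `truth` (list with `enriched_set_ids`)
#' @export
simulate_genesets <- function(n_sets = 60, set_size_range = c(15, 30),
                              universe, truth, n_enriched = 5,
                              seed = 1) {
  if (n_enriched > n_sets) stop("n_enriched > n_sets")
  universe <- unique(normalize_gene_ids(universe))
  up <- normalize_gene_ids(truth$planted_up_genes)
  down <- normalize_gene_ids(truth$planted_down_genes)
  if (length(up) < 3 || length(down) < 3) {
    stop("need >= 3 planted genes in each direction")
  }
  if (set_size_range[1] < 8) stop("minimum set size must be >= 8")
  if (length(universe) < set_size_range[2]) {
    stop("universe too small for the requested set sizes")
  }
  set.seed(derive_seed(seed, "genesets"))
  ids <- sprintf("SET%03d", seq_len(n_sets))
  enriched <- sort(sample(ids, n_enriched))
  sets <- lapply(ids, function(id) {
    size <- sample(seq(set_size_range[1], set_size_range[2]), 1)
    if (id %in% enriched) {
      seed_genes <- c(sample(up, min(length(up), sample(3:4, 1))),
                      sample(down, min(length(down), sample(3:4, 1))))
      pad <- sample(setdiff(universe, seed_genes), size - length(seed_genes))
      c(seed_genes, pad)
    } else {
      sample(universe, size)
    }
  })
  names(sets) <- ids
  list(sets = sets, truth = list(enriched_set_ids = enriched))
}

#' Simulate kinome chip runs with planted kinase activities
#'
#' Emulates kinetic reads of a peptide kinase array: the intensity of a
#' peptide targeted by kinase `k` at exposure `e` is
#' `base_slope * activity[k] * e` plus Gaussian noise. Peptides mapped
#' to several kinases use the maximum activity multiplier; unmapped
#' peptides use multiplier 1.
#'
#' @param peptide_map named list: kinase ID -> peptide IDs
#' @param exposures exposure lengths (ms), >= 3, strictly increasing
#'   (default 5/25/100 ms)
#' @param base_slope baseline slope (intensity/ms, > 0)
#' @param activity named numeric vector: kinase ID -> positive activity
#'   multiplier; kinases absent default to 1
#' @param noise_sd Gaussian intensity noise sd
#' @param n_wells replicate wells to generate
#' @param condition condition label stored in each run
#' @param seed integer seed
#' @return list of [kinome_chip_run()]s, length `n_wells`
#' @export
simulate_kinome_run <- function(peptide_map,
                                exposures = c(5, 25, 100),
                                base_slope = 1.5,
                                activity = numeric(0),
                                noise_sd = 1, n_wells = 1,
                                condition = "control", seed = 1) {
  if (length(peptide_map) == 0) stop("empty peptide map")
  if (base_slope <= 0) stop("base_slope must be positive")
  if (any(activity <= 0)) stop("activity multipliers must be positive")
  peptides <- sort(unique(unlist(peptide_map)))
  mult <- rep(1, length(peptides))
  names(mult) <- peptides
  for (k in names(peptide_map)) {
    a <- if (k %in% names(activity)) activity[[k]] else 1
    idx <- match(peptide_map[[k]], peptides)
    mult[idx] <- pmax(mult[idx], a)
  }
  set.seed(derive_seed(seed, paste0("kinome:", condition)))
  lapply(seq_len(n_wells), function(w) {
    mu <- outer(base_slope * mult, exposures)
    y <- mu + matrix(stats::rnorm(length(mu), 0, noise_sd),
                     nrow = nrow(mu))
    rownames(y) <- peptides
    kinome_chip_run(well_id = paste0(condition, "_w", w),
                    condition = condition, intensities = y,
                    exposures = exposures)
  })
}

#' One-compartment oral-absorption concentration curve
#'
#' Closed-form concentration at time `t` after an oral dose with
#' first-order absorption `ka` and elimination `ke`:
#' `C(t) = dose*ka / (V_over_F*(ka - ke)) * (exp(-ke*t) - exp(-ka*t))`.
#'
#' @param t time (h)
#' @param ka,ke absorption and elimination rate constants (1/h); must
#'   differ
#' @param v_over_f apparent volume of distribution,
#'   (mg/kg)/(ng/ml) units so `dose/v_over_f` is in ng/ml
#' @param dose dose (mg/kg)
#' @return concentration (ng/ml)
#' @export
one_compartment_conc <- function(t, ka, ke, v_over_f, dose) {
  if (ka == ke) stop("ka = ke: closed form is degenerate")
  dose * ka / (v_over_f * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
}

#' Default perilymph pharmacokinetic parameters
#'
#' The generator's reference parameter set for perilymph zorifertinib
#' after 15 mg/kg oral gavage: elimination `ke = log(2)/2.1` per hour
#' (half-life 2.1 h), apparent volume `Vz/F = 0.19` (mg/kg)/(ng/ml),
#' and absorption `ka = 6.2` per hour, which places the concentration
#' peak at 0.5 h.
#'
#' @return list with `ka`, `ke`, `v_over_f`, `dose`
#' @export
default_pk_params <- function() {
  list(ka = 6.2, ke = log(2) / 2.1, v_over_f = 0.19, dose = 15)
}

#' Simulate a perilymph concentration-time profile
#'
#' Samples the one-compartment oral-absorption curve at the given
#' times and multiplies by lognormal noise of coefficient of variation
#' `noise_cv` (mean 1), the standard multiplicative error model for
#' bioanalytical concentrations. Deterministic under seed.
#'
#' @param params list with `ka`, `ke`, `v_over_f`, `dose` (see
#'   [default_pk_params()])
#' @param times sampling times (h), sorted, non-negative (default the
#'   perilymph design: 0, 0.5, 1, 2, 4, 6 h)
#' @param noise_cv coefficient of variation of the multiplicative
#'   noise (0 = noiseless)
#' @param lloq assay LLOQ stored in the profile (ng/ml)
#' @param seed integer seed
#' @return a [conc_time_profile()]
#' @export
simulate_pk_profile <- function(params = default_pk_params(),
                                times = c(0, 0.5, 1, 2, 4, 6),
                                noise_cv = 0, lloq = 5, seed = 1) {
  if (any(diff(times) <= 0) || times[1] < 0) {
    stop("times must be sorted, non-negative")
  }
  conc <- one_compartment_conc(times, params$ka, params$ke,
                               params$v_over_f, params$dose)
  if (noise_cv > 0) {
    set.seed(derive_seed(seed, "pk"))
    sdlog <- sqrt(log(1 + noise_cv^2))
    conc <- conc * stats::rlnorm(length(conc), -sdlog^2 / 2, sdlog)
  }
  conc_time_profile(times, conc, dose = params$dose, lloq = lloq)
}
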