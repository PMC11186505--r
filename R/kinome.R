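#' Construct a kinome chip run
#'
#' One well of a serine/threonine kinase peptide array read kinetically:
#' reporter-peptide fluorescence captured at increasing camera exposure
#' lengths. The phosphorylation activity of a peptide is the linear
#' slope of signal versus exposure, which extends the dynamic range
#' beyond a single exposure read.
#'
#' @param well_id identifier of the well
#' @param condition condition label (e.g. "control", "noise")
#' @param intensities numeric matrix, peptides in rows (rownames are
#'   peptide IDs), exposures in columns
#' @param exposures numeric vector of exposure lengths (ms), strictly
#'   increasing, length >= 3
#' @return object of class `kinome_chip_run`
#' @export
kinome_chip_run <- function(well_id, condition, intensities, exposures) {
  stopifnot(is.matrix(intensities), is.numeric(intensities))
  if (is.null(rownames(intensities))) stop("peptide IDs required as rownames")
  if (length(exposures) < 3) stop("at least 3 exposure points required")
  if (any(diff(exposures) <= 0)) stop("exposures must be strictly increasing")
  if (ncol(intensities) != length(exposures)) {
    stop("one intensity column per exposure required")
  }
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  structure(list(well_id = as.character(well_id),
                 condition = as.character(condition),
                 intensities = intensities,
                 exposures = as.numeric(exposures)),
            class = "kinome_chip_run")
}

#' Per-peptide kinetic slopes
#'
#' Ordinary least-squares slope and R^2 of signal intensity versus
#' exposure length for every peptide of a chip run, plus the maximum
#' raw signal. R^2 of a zero-variance response is defined as 0.
#'
#' @param run a [kinome_chip_run()]
#' @return data.frame `peptide_id`, `slope` (intensity/ms), `r2`,
#'   `max_signal`
#' @export
fit_peptide_slopes <- function(run) {
  stopifnot(inherits(run, "kinome_chip_run"))
  x <- run$exposures
  y <- run$intensities
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(y %*% xc) / sxx
  ybar <- rowMeans(y)
  sst <- rowSums((y - ybar)^2)
  ssr <- slope^2 * sxx
  r2 <- ifelse(sst == 0, 0, ssr / sst)
  data.frame(peptide_id = rownames(y), slope = slope,
             r2 = pmin(r2, 1), max_signal = apply(y, 1, max),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Peptide quality-control filter
#'
#' Removes peptides that appear inactive (maximum raw signal at or
#' below `min_signal`, default 5) or whose kinetic fit is non-linear
#' (R^2 below `min_r2`, default 0.90); exclusions are reported with a
#' reason.
#'
#' @param activities data.frame from [fit_peptide_slopes()]
#' @param min_signal inactivity threshold (raw signal <= min_signal
#'   removed)
#' @param min_r2 minimum linear-fit R^2 (strictly below removed)
#' @return the retained rows, with a `passed_qc` column set TRUE
#' @export
qc_filter <- function(activities, min_signal = 5, min_r2 = 0.90) {
  stopifnot(is.data.frame(activities))
  inactive <- activities$max_signal <= min_signal
  nonlinear <- activities$r2 < min_r2
  if (any(inactive)) {
    message(sum(inactive), " peptide(s) removed: raw signal <= ", min_signal)
  }
  if (any(nonlinear & !inactive)) {
    message(sum(nonlinear & !inactive), " peptide(s) removed: R2 < ", min_r2)
  }
  keep <- activities[!(inactive | nonlinear), , drop = FALSE]
  keep$passed_qc <- TRUE
  rownames(keep) <- NULL
  keep
}

#' Average peptide slopes over replicate wells
#'
#' Per-condition peptide activity: the mean post-QC slope across
#' replicate wells. A peptide is kept only if it passed QC in every
#' well of the condition.
#'
#' @param activity_list list of QC-filtered data.frames (one per well)
#'   from [qc_filter()]
#' @return data.frame `peptide_id`, `slope`
#' @export
average_peptide_slopes <- function(activity_list) {
  stopifnot(is.list(activity_list), length(activity_list) >= 1)
  common <- Reduce(intersect, lapply(activity_list, `[[`, "peptide_id"))
  slopes <- vapply(common, function(p) {
    mean(vapply(activity_list, function(a) a$slope[a$peptide_id == p],
                numeric(1)))
  }, numeric(1))
  data.frame(peptide_id = common, slope = unname(slopes),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Peptide fold changes between conditions
#'
#' FC is the ratio of case to control peptide slope; peptides with
#' `FC > fc_hi` or `FC < fc_lo` (defaults 1.15 and 0.85, i.e. a 15%
#' change, strict inequalities) are called differentially
#' phosphorylated. Peptides must be present post-QC in both conditions;
#' a non-positive control slope makes the ratio meaningless and the
#' peptide is skipped with a note.
#'
#' @param case,control data.frames with `peptide_id` and `slope`
#'   (e.g. from [average_peptide_slopes()])
#' @param fc_hi,fc_lo differential call bounds
#' @return data.frame `peptide_id`, `fc`, `log2fc`, `differential`
#' @export
peptide_fold_changes <- function(case, control, fc_hi = 1.15,
                                 fc_lo = 0.85) {
  shared <- intersect(case$peptide_id, control$peptide_id)
  cs <- case$slope[match(shared, case$peptide_id)]
  ct <- control$slope[match(shared, control$peptide_id)]
  bad <- ct <= 0
  if (any(bad)) {
    message(sum(bad), " peptide(s) skipped: non-positive control slope")
    shared <- shared[!bad]; cs <- cs[!bad]; ct <- ct[!bad]
  }
  fc <- cs / ct
  data.frame(peptide_id = shared, fc = fc, log2fc = log2(fc),
             differential = fc > fc_hi | fc < fc_lo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kinase random-sampling z-scores for one chip
#'
#' For each candidate upstream kinase, compares the observed number of
#' differential peptides among its mapped peptides to a null built by
#' drawing `n_iter` random peptide subsets of the same size as the
#' differential set from the chip's (QC-passed) peptides. The z-score
#' is (observed - null mean) / null sd; a degenerate null (sd below a
#' tiny floor, e.g. a kinase mapping every chip peptide) reports z = 0.
#' Kinases with no mapped on-chip peptide are skipped with a note.
#'
#' @param differential_peptides character vector of differential peptide
#'   IDs (subset of `chip_peptides`)
#' @param chip_peptides character vector of all QC-passed peptide IDs on
#'   the chip
#' @param kinase_map named list: kinase ID -> character vector of mapped
#'   peptide IDs
#' @param n_iter number of random resamples (>= 100; default 2000)
#' @param seed integer seed (resampling is deterministic under it)
#' @return data.frame `kinase_id`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `n_mapped`
#' @export
krsa_zscores <- function(differential_peptides, chip_peptides,
                         kinase_map, n_iter = 2000, seed = 1) {
  chip_peptides <- unique(chip_peptides)
  differential_peptides <- unique(differential_peptides)
  if (!all(differential_peptides %in% chip_peptides)) {
    stop("differential peptides must be a subset of chip peptides")
  }
  m <- length(differential_peptides)
  if (m == 0) stop("no differential peptides: z-scores are undefined")
  if (n_iter < 100) stop("n_iter must be >= 100")
  mapped <- lapply(kinase_map, function(p) intersect(unique(p), chip_peptides))
  off_chip <- vapply(mapped, length, integer(1)) == 0
  if (any(off_chip)) {
    message(sum(off_chip), " kinase(s) with no on-chip peptide skipped")
    mapped <- mapped[!off_chip]
  }
  if (length(mapped) == 0) stop("no kinase maps onto the chip")

  # membership matrix: chip peptides x kinases
  memb <- vapply(mapped, function(p) chip_peptides %in% p,
                 logical(length(chip_peptides)))
  memb <- matrix(memb, nrow = length(chip_peptides),
                 dimnames = list(chip_peptides, names(mapped)))
  observed <- colSums(memb[differential_peptides, , drop = FALSE])

  set.seed(seed)
  draws <- vapply(seq_len(n_iter), function(i) {
    idx <- sample.int(length(chip_peptides), m)
    colSums(memb[idx, , drop = FALSE])
  }, numeric(ncol(memb)))
  draws <- matrix(draws, nrow = ncol(memb))  # kinases x iterations
  null_mean <- rowMeans(draws)
  null_sd <- apply(draws, 1, stats::sd)
  eps <- 1e-12
  z <- ifelse(null_sd < eps, 0, (observed - null_mean) / null_sd)
  data.frame(kinase_id = names(mapped), observed = as.numeric(observed),
             null_mean = null_mean, null_sd = null_sd, z = z,
             n_mapped = vapply(mapped, length, integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Kinase z-scores averaged across chips
#'
#' Runs [krsa_zscores()] chip by chip and averages the per-chip
#' z-scores per kinase (the per-chip values are retained), following
#' the chip-by-chip-then-average convention of kinome waterfall plots.
#'
#' @param chips list of lists, each with elements
#'   `differential_peptides`, `chip_peptides`
#' @param kinase_map named list: kinase ID -> peptide IDs
#' @param n_iter resamples per chip
#' @param seed master seed; each chip uses a derived stream
#' @return data.frame `kinase_id`, `z_mean`, `n_chips` plus list-column
#'   `z_per_chip`, sorted by z_mean descending
#' @export
krsa_mean_zscores <- function(chips, kinase_map, n_iter = 2000, seed = 1) {
  stopifnot(length(chips) >= 1)
  per_chip <- lapply(seq_along(chips), function(i) {
    krsa_zscores(chips[[i]]$differential_peptides,
                 chips[[i]]$chip_peptides, kinase_map,
                 n_iter = n_iter,
                 seed = derive_seed(seed, paste0("krsa_chip_", i)))
  })
  kin <- sort(unique(unlist(lapply(per_chip, `[[`, "kinase_id"))))
  rows <- lapply(kin, function(k) {
    zs <- unlist(lapply(per_chip, function(d) d$z[d$kinase_id == k]))
    data.frame(kinase_id = k, z_mean = mean(zs), n_chips = length(zs),
               z_per_chip = I(list(zs)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$z_mean, res$kinase_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Kinase-family summaries of peptide fold changes
#'
#' Mean and SD of peptide log2 fold changes per kinase family (e.g. the
#' AKT and ERK putative-target peptide sets) for one case-vs-control
#' comparison.
#'
#' @param fc data.frame from [peptide_fold_changes()]
#' @param family_map named list: family -> peptide IDs
#' @param comparison label for the comparison (e.g. "noise vs control")
#' @return data.frame `family`, `comparison`, `n_peptides`, `mean_log2fc`,
#'   `sd_log2fc`
#' @export
family_aggregate <- function(fc, family_map, comparison = "case vs control") {
  stopifnot(is.data.frame(fc), !is.null(names(family_map)))
  rows <- lapply(names(family_map), function(fam) {
    members <- intersect(family_map[[fam]], fc$peptide_id)
    if (length(members) == 0) {
      stop("family '", fam, "' has no on-chip peptide")
    }
    vals <- fc$log2fc[match(members, fc$peptide_id)]
    data.frame(family = fam, comparison = comparison,
               n_peptides = length(members), mean_log2fc = mean(vals),
               sd_log2fc = if (length(vals) > 1) stats::sd(vals) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Quartile harmonization of kinase rankings across methods
#'
#' Different upstream-kinase assignment methods rank different subsets
#' of kinases. To integrate them, each method's ranking is reduced to
#' quartiles 1-4 (quartile 1 = top of the ranking, via
#' `ceiling(4 * rank / n)`); kinases absent from a method are left NA.
#'
#' @param rankings named list: method ID -> character vector of kinase
#'   IDs in rank order (best first); at least 2 methods, none empty
#' @return data.frame `kinase_id` plus one integer quartile column per
#'   method, rows sorted by mean quartile (best consensus first)
#' @export
quartile_harmonize <- function(rankings) {
  stopifnot(is.list(rankings), !is.null(names(rankings)))
  if (length(rankings) < 2) stop("at least 2 methods are required")
  if (any(vapply(rankings, length, integer(1)) == 0)) {
    stop("empty ranking")
  }
  kin <- sort(unique(unlist(rankings)))
  cols <- lapply(rankings, function(r) {
    q <- ceiling(4 * seq_along(r) / length(r))
    q[match(kin, r)]
  })
  res <- data.frame(kinase_id = kin, stringsAsFactors = FALSE)
  for (m in names(cols)) res[[m]] <- cols[[m]]
  mq <- rowMeans(as.matrix(res[, names(rankings), drop = FALSE]),
                 na.rm = TRUE)
  res <- res[order(mq, res$kinase_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
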