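linear_run <- function(slopes, exposures = c(5, 25, 100), noise = 0,
                       seed = 1, condition = "c", well = "w1") {
  set.seed(seed)
  y <- outer(slopes, exposures) +
    matrix(rnorm(length(slopes) * length(exposures), 0, noise),
           nrow = length(slopes))
  rownames(y) <- names(slopes)
  kinome_chip_run(well, condition, y, exposures)
}

test_that("slope fitting is exact on noiseless linear data", {
  slopes <- c(p1 = 0.5, p2 = 2, p3 = 0)
  act <- fit_peptide_slopes(linear_run(slopes))
  expect_equal(act$slope, unname(slopes), tolerance = 1e-12)
  expect_equal(act$r2, c(1, 1, 0))   # constant response: R2 defined as 0
})

test_that("fitted slopes match the closed-form least-squares formula", {
  x <- c(5, 10, 25, 50, 100)
  y <- c(3, 8, 20, 35, 80)
  run <- kinome_chip_run("w", "c", matrix(y, 1, dimnames = list("pep")), x)
  act <- fit_peptide_slopes(run)
  n <- length(x)
  slope_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  expect_equal(act$slope, slope_oracle, tolerance = 1e-12)
  fit <- lm(y ~ x)
  expect_equal(act$r2, summary(fit)$r.squared, tolerance = 1e-12)
})

test_that("QC removes inactive (<= 5) and non-linear (R2 < 0.90) peptides", {
  act <- data.frame(peptide_id = paste0("p", 1:4),
                    slope = c(1, 1, 1, 1),
                    r2 = c(0.99, 0.89, 0.95, 0.90),
                    max_signal = c(100, 100, 5, 6))
  keep <- suppressMessages(qc_filter(act))
  expect_setequal(keep$peptide_id, c("p1", "p4"))  # p2 fails R2, p3 signal
  # brute-force enumeration of the inequalities
  expect_setequal(keep$peptide_id,
                  act$peptide_id[act$max_signal > 5 & act$r2 >= 0.90])
})

test_that("fold-change calls use strict 1.15/0.85 bounds", {
  case <- data.frame(peptide_id = paste0("p", 1:4),
                     slope = c(1.15, 1.2, 0.85, 1.0))
  ctrl <- data.frame(peptide_id = paste0("p", 1:4),
                     slope = rep(1, 4))
  fc <- peptide_fold_changes(case, ctrl)
  expect_equal(fc$fc, c(1.15, 1.2, 0.85, 1.0))
  expect_equal(fc$differential, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(fc$log2fc[4], 0)
  ctrl$slope[1] <- 0
  expect_message(fc2 <- peptide_fold_changes(case, ctrl), "non-positive")
  expect_false("p1" %in% fc2$peptide_id)
})

test_that("fold-change calls are invariant to common intensity rescaling", {
  slopes <- c(p1 = 1, p2 = 1.5, p3 = 0.7, p4 = 1.05)
  case <- fit_peptide_slopes(linear_run(slopes))
  ctrl <- fit_peptide_slopes(linear_run(rep(1, 4) |> setNames(names(slopes))))
  fc1 <- peptide_fold_changes(case, ctrl)
  scale_run <- function(df, f) {df$slope <- df$slope * f; df}
  fc2 <- peptide_fold_changes(scale_run(case, 37.5), scale_run(ctrl, 37.5))
  expect_equal(fc1$differential, fc2$differential)
  expect_equal(fc1$fc, fc2$fc, tolerance = 1e-12)
})

test_that("noiseless planted multiplier yields exact FC for mapped peptides", {
  pmap <- list(AKT1 = paste0("p", 1:6))
  ctrl <- simulate_kinome_run(pmap, noise_sd = 0, condition = "control")
  case <- simulate_kinome_run(pmap, activity = c(AKT1 = 1.5), noise_sd = 0,
                              condition = "noise")
  fc <- peptide_fold_changes(
    average_peptide_slopes(lapply(case, fit_peptide_slopes)),
    average_peptide_slopes(lapply(ctrl, fit_peptide_slopes)))
  expect_equal(fc$fc, rep(1.5, 6), tolerance = 1e-12)
})

test_that("KRSA z agrees with the exact hypergeometric null", {
  # 10-peptide chip, 3 differential, kinase mapping 4 peptides:
  # null hit count is hypergeometric(N=10, K=4, n=3)
  chip <- paste0("p", 1:10)
  diffp <- paste0("p", 1:3)
  kmap <- list(K1 = paste0("p", c(1, 2, 5, 8)))
  n_iter <- 1e5
  res <- krsa_zscores(diffp, chip, kmap, n_iter = n_iter, seed = 42)
  mu <- 3 * 4 / 10
  sd_exact <- sqrt(3 * (4 / 10) * (6 / 10) * (10 - 3) / (10 - 1))
  z_exact <- (res$observed - mu) / sd_exact
  # Monte-Carlo SE of the estimated z
  se <- 3 / sqrt(n_iter)
  expect_lt(abs(res$z - z_exact), 3 * max(se, 0.02))
  expect_equal(res$observed, 2)
})

test_that("a kinase mapping the whole chip has z = 0 (degenerate null)", {
  chip <- paste0("p", 1:8)
  res <- krsa_zscores(paste0("p", 1:2), chip, list(ALL = chip),
                      n_iter = 500, seed = 1)
  expect_equal(res$z, 0)
})

test_that("KRSA errors and skips are explicit", {
  chip <- paste0("p", 1:5)
  expect_error(krsa_zscores(character(0), chip, list(K = chip[1:2])),
               "undefined")
  expect_error(krsa_zscores("p9", chip, list(K = chip[1:2])), "subset")
  expect_message(
    res <- krsa_zscores("p1", chip, list(K = "p2", OFF = "zz"),
                        n_iter = 200, seed = 1),
    "no on-chip peptide")
  expect_equal(res$kinase_id, "K")
})

test_that("KRSA is deterministic under seed and the planted kinase wins", {
  pmap <- c(lapply(1:9, function(i) sprintf("p%02d_%d", 1:10, i)),
            list(sprintf("q%02d", 1:10)))
  names(pmap) <- c(paste0("KIN", 1:9), "AKT1")
  make_chips <- function() lapply(1:3, function(chip) {
    ctrl <- simulate_kinome_run(pmap, noise_sd = 0.5, condition = "control",
                                seed = 100 + chip)
    case <- simulate_kinome_run(pmap, activity = c(AKT1 = 1.5),
                                noise_sd = 0.5, condition = "noise",
                                seed = 200 + chip)
    qc_case <- qc_filter(fit_peptide_slopes(case[[1]]))
    qc_ctrl <- qc_filter(fit_peptide_slopes(ctrl[[1]]))
    fc <- peptide_fold_changes(qc_case, qc_ctrl)
    list(differential_peptides = fc$peptide_id[fc$differential],
         chip_peptides = fc$peptide_id)
  })
  chips <- make_chips()
  z1 <- krsa_mean_zscores(chips, pmap, n_iter = 2000, seed = 5)
  z2 <- krsa_mean_zscores(chips, pmap, n_iter = 2000, seed = 5)
  expect_identical(z1, z2)
  expect_equal(z1$kinase_id[1], "AKT1")
  expect_gt(z1$z_mean[1], 2)
})

test_that("family aggregation reproduces direct arithmetic", {
  fc <- data.frame(peptide_id = paste0("p", 1:5),
                   fc = c(1.2, 1.4, 0.8, 1, 1.1),
                   log2fc = log2(c(1.2, 1.4, 0.8, 1, 1.1)),
                   differential = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  fam <- list(AKT = paste0("p", 1:3), ERK = "p4")
  agg <- family_aggregate(fc, fam, comparison = "noise vs control")
  akt <- agg[agg$family == "AKT", ]
  expect_equal(akt$mean_log2fc, mean(log2(c(1.2, 1.4, 0.8))))
  expect_equal(akt$sd_log2fc, sd(log2(c(1.2, 1.4, 0.8))))
  erk <- agg[agg$family == "ERK", ]
  expect_equal(erk$n_peptides, 1)
  expect_equal(erk$sd_log2fc, 0)
  expect_error(family_aggregate(fc, list(BAD = "zz")), "no on-chip")
})

test_that("quartile harmonization uses the ceiling rule", {
  r4 <- list(m1 = paste0("k", 1:4), m2 = paste0("k", c(2, 1, 4, 3)))
  q4 <- quartile_harmonize(r4)
  expect_equal(q4$m1[match(paste0("k", 1:4), q4$kinase_id)], 1:4)
  r8 <- list(m1 = paste0("k", 1:8), m2 = paste0("k", 8:1))
  q8 <- quartile_harmonize(r8)
  expect_equal(q8$m1[match(paste0("k", 1:2), q8$kinase_id)], c(1L, 1L))
  # absent kinases are NA; hand-enumerated two-method toy
  rt <- list(a = c("x", "y"), b = c("y", "z", "w", "v"))
  qt <- quartile_harmonize(rt)
  expect_true(is.na(qt$a[qt$kinase_id == "z"]))
  expect_equal(qt$b[qt$kinase_id == "y"], 1L)
  expect_equal(qt$b[qt$kinase_id == "v"], 4L)
  expect_error(quartile_harmonize(list(a = "x")), "at least 2")
  expect_error(quartile_harmonize(list(a = "x", b = character(0))), "empty")
})
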