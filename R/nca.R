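#' Construct a concentration-time profile
#'
#' Drug concentrations in a sampled body fluid (here: inner-ear
#' perilymph) over time after dosing, with the administered dose and
#' the bioanalytical lower limit of quantification (LLOQ).
#'
#' @param times numeric vector of sampling times (h), strictly
#'   increasing, first >= 0
#' @param conc numeric vector of concentrations (ng/ml), non-negative
#' @param dose administered dose (mg/kg), > 0
#' @param lloq lower limit of quantification (ng/ml); default 5
#' @return object of class `conc_time_profile` with a `quantifiable`
#'   logical (conc >= lloq)
#' @export
conc_time_profile <- function(times, conc, dose, lloq = 5) {
  times <- as.numeric(times); conc <- as.numeric(conc)
  if (length(times) != length(conc)) stop("times and conc lengths differ")
  if (length(times) < 2) stop("at least 2 time points required")
  if (times[1] < 0 || any(diff(times) <= 0)) {
    stop("times must be non-negative and strictly increasing")
  }
  if (any(conc < 0) || any(!is.finite(conc))) {
    stop("concentrations must be finite and non-negative")
  }
  if (dose <= 0) stop("dose must be positive")
  structure(list(times = times, conc = conc, dose = dose, lloq = lloq,
                 quantifiable = conc >= lloq),
            class = "conc_time_profile")
}

#' Censor a profile at the limit of quantification
#'
#' Values below the LLOQ cannot be distinguished from zero by the
#' assay. Before the observed peak they are set to 0 (absorption has
#' not delivered measurable drug yet); after the peak they are set to 0
#' for AUC purposes but flagged non-quantifiable so the terminal
#' log-linear fit never sees them. All censoring is reported.
#'
#' @param profile a [conc_time_profile()]
#' @return a censored `conc_time_profile`
#' @export
lloq_censor <- function(profile) {
  stopifnot(inherits(profile, "conc_time_profile"))
  if (all(profile$conc < profile$lloq)) {
    stop("all concentrations are below the LLOQ")
  }
  i_max <- which.max(profile$conc)[1]
  below <- profile$conc < profile$lloq
  conc <- profile$conc
  conc[below] <- 0
  n_pre <- sum(below[seq_len(i_max)])
  n_post <- sum(below) - n_pre
  if (any(below)) {
    message(n_pre, " pre-peak and ", n_post,
            " post-peak value(s) below LLOQ (", profile$lloq,
            " ng/ml) censored to 0")
  }
  out <- profile
  out$conc <- conc
  out$quantifiable <- !below
  out
}

# Linear trapezoid over (t, c)
trapz <- function(t, c) sum(diff(t) * (utils::head(c, -1) + c[-1]) / 2)

#' Trapezoidal AUC over the observed times
#'
#' Linear trapezoid of the concentration-time polygon, the `auc_0t`
#' component of [nca()] exposed on its own (it is exactly additive over
#' any split of the profile at an interior time point).
#'
#' @param profile a [conc_time_profile()]
#' @return area (ng/ml * h)
#' @export
nca_auc_0t <- function(profile) {
  stopifnot(inherits(profile, "conc_time_profile"))
  trapz(profile$times, profile$conc)
}

#' Non-compartmental pharmacokinetic analysis
#'
#' Model-free PK parameters from a concentration-time profile:
#'
#' * `cmax`, `tmax`: maximum concentration and its time (earliest time
#'   on ties);
#' * `auc_0t`: linear trapezoidal area under the curve over the
#'   observed times;
#' * `lambda_z`: terminal elimination rate from a least-squares fit of
#'   `log(C)` vs `t`, over the contiguous window of >= 3 quantifiable
#'   post-peak points ending at the last quantifiable point that
#'   maximizes adjusted R^2;
#' * `t_half = log(2)/lambda_z`;
#' * `auc_inf = auc_0t + C_last/lambda_z` (C_last: last quantifiable
#'   concentration);
#' * `cl_f = dose/auc_inf` (apparent clearance, (mg/kg)/(ng/ml)/h) and
#'   `vz_f = cl_f/lambda_z` (apparent terminal volume, (mg/kg)/(ng/ml)).
#'
#' A non-positive fitted `lambda_z` (no terminal decline) is an error.
#'
#' @param profile a [conc_time_profile()], typically [lloq_censor()]ed
#' @return object of class `nca_result`: list with `cmax`, `tmax`,
#'   `auc_0t`, `auc_inf`, `lambda_z`, `t_half`, `cl_f`, `vz_f`,
#'   `lambda_z_points` (times used), `lambda_z_adj_r2`
#' @export
nca <- function(profile) {
  stopifnot(inherits(profile, "conc_time_profile"))
  t <- profile$times; c <- profile$conc
  i_max <- which.max(c)[1]
  cmax <- c[i_max]; tmax <- t[i_max]
  auc_0t <- trapz(t, c)

  # candidate terminal points: quantifiable, positive, at/after the peak
  cand <- which(profile$quantifiable & c > 0 & seq_along(t) >= i_max)
  last <- if (length(cand)) max(cand) else 0L
  cand <- cand[cand <= last]
  if (length(cand) < 3) {
    stop("lambda_z fit needs >= 3 quantifiable post-peak points")
  }
  best <- NULL
  for (start in cand[seq_len(length(cand) - 2)]) {
    win <- cand[cand >= start]
    k <- length(win)
    fit <- stats::lm.fit(cbind(1, t[win]), log(c[win]))
    res <- fit$residuals
    sst <- sum((log(c[win]) - mean(log(c[win])))^2)
    r2 <- if (sst == 0) 0 else 1 - sum(res^2) / sst
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-12) {
      best <- list(slope = fit$coefficients[2], adj = adj, win = win)
    }
  }
  lambda_z <- -as.numeric(best$slope)
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("terminal fit gives non-positive lambda_z: no terminal decline")
  }
  c_last <- c[max(best$win)]
  auc_inf <- auc_0t + c_last / lambda_z
  cl_f <- profile$dose / auc_inf
  structure(list(cmax = cmax, tmax = tmax, auc_0t = auc_0t,
                 auc_inf = auc_inf, lambda_z = lambda_z,
                 t_half = log(2) / lambda_z, cl_f = cl_f,
                 vz_f = cl_f / lambda_z,
                 lambda_z_points = t[best$win],
                 lambda_z_adj_r2 = best$adj),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf(
    paste0("<nca_result>\n  Cmax %.3g ng/ml at Tmax %.3g h\n",
           "  AUC0-t %.4g, AUCinf %.4g ng/ml*h\n",
           "  lambda_z %.4g /h (t1/2 %.3g h; %d-point fit, adjR2 %.4f)\n",
           "  Cl/F %.3g (mg/kg)/(ng/ml)/h, Vz/F %.3g (mg/kg)/(ng/ml)\n"),
    x$cmax, x$tmax, x$auc_0t, x$auc_inf, x$lambda_z, x$t_half,
    length(x$lambda_z_points), x$lambda_z_adj_r2, x$cl_f, x$vz_f))
  invisible(x)
}
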