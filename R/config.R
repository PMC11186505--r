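#' Default pipeline configuration
#'
#' All thresholds of the screen in one flat list. The defaults are the
#' values the workflow is calibrated to:
#'
#' * `deg`: DEG-of-interest thresholds. The array regime keeps genes
#'   with `|logFC| > logfc_cut` and `P < p_cut`; the single-cell regime
#'   keeps linear `|FC| > fc_cut_linear` with FDR `q < q_cut`. (Some
#'   upstream descriptions of the array filter quote `|logFC| > 1` for
#'   the raw download step; the DEG-of-interest cutoff used here
#'   defaults to 2 and is configurable.)
#' * `query`: connectivity-query rules — a pathway seeds a query only
#'   with at least `min_up` up- and `min_down` down-regulated member
#'   DEGs; each query returns `top_k` ranked perturbations; hits must
#'   exceed `score_cutoff` (strictly).
#' * `consensus`: a pathway is retained with at least `min_pathway_hits`
#'   distinct hit drugs; a drug is promising if it targets at least
#'   `min_pathways_per_drug` retained pathways.
#' * `kinome`: peptide QC (maximum raw signal must exceed `min_signal`,
#'   linear-fit R^2 at least `min_r2`), differential-phosphorylation
#'   fold-change bounds (`fc_hi`, `fc_lo`), and the number of random
#'   resamples `n_iter` for kinase z-scores.
#'
#' @param ... named overrides of the form `deg.logfc_cut = 1`, applied
#'   to the nested list by dotted path
#' @return nested configuration list
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$query$top_k
#' default_config(query.top_k = 25)$query$top_k
default_config <- function(...) {
  cfg <- list(
    deg = list(logfc_cut = 2, p_cut = 0.05, fc_cut_linear = 1.2,
               q_cut = 0.05),
    query = list(min_up = 3, min_down = 3, top_k = 50, score_cutoff = 0.1),
    consensus = list(min_pathway_hits = 3, min_pathways_per_drug = 2),
    kinome = list(min_signal = 5, min_r2 = 0.90, fc_hi = 1.15,
                  fc_lo = 0.85, n_iter = 2000)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(path) != 2 || is.null(cfg[[path[1]]]) ||
        !path[2] %in% names(cfg[[path[1]]])) {
      stop("unknown configuration key: ", nm)
    }
    cfg[[path[1]]][[path[2]]] <- dots[[nm]]
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$deg$p_cut > 0, cfg$deg$p_cut <= 1,
    cfg$deg$q_cut > 0, cfg$deg$q_cut <= 1,
    cfg$deg$logfc_cut >= 0, cfg$deg$fc_cut_linear > 1,
    cfg$query$min_up >= 1, cfg$query$min_down >= 1,
    cfg$query$top_k >= 1,
    cfg$kinome$fc_lo < 1, cfg$kinome$fc_hi > 1,
    cfg$kinome$n_iter >= 100
  )
  invisible(cfg)
}

#' Read a configuration file
#'
#' Flat JSON mapping with dotted keys (for example
#' `{"deg.logfc_cut": 1}`) applied over [default_config()].
#'
#' @param path path to a JSON file
#' @return nested configuration list
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(default_config, as.list(raw))
}
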