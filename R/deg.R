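#' Per-gene differential expression between two groups
#'
#' Computes, for every gene of a log2-scale expression matrix, the log2
#' fold change (case minus control group mean), a two-sample
#' unequal-variance (Welch) t-test p-value, and a Benjamini-Hochberg
#' FDR q-value across all genes.
#'
#' Genes with zero variance in both groups have no defined t statistic:
#' they get p = 1 when the group means are equal and p = 0 when they
#' differ (the limiting value), with a note.
#'
#' @param mat numeric matrix of log2 intensities, genes in rows (rownames
#'   are gene IDs), samples in columns
#' @param groups character/factor vector of length `ncol(mat)` with
#'   exactly two levels
#' @param case,control the group labels contrasted as case - control;
#'   default: the two unique labels in order of appearance, second as
#'   case
#' @return data.frame with columns `gene`, `logfc`, `p`, `q`, ordered by
#'   p ascending, ties by |logfc| descending then gene ID
#' @export
compute_deg_stats <- function(mat, groups,
                              case = NULL, control = NULL) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (is.null(rownames(mat))) stop("matrix must have gene IDs as rownames")
  groups <- as.character(groups)
  if (length(groups) != ncol(mat)) {
    stop("groups must have one label per sample column")
  }
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups are required")
  if (is.null(control)) control <- lev[1]
  if (is.null(case)) case <- setdiff(lev, control)[1]
  a <- mat[, groups == case, drop = FALSE]
  b <- mat[, groups == control, drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 samples")

  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  logfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  tstat <- logfc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)

  degen <- se2 == 0
  if (any(degen)) {
    message(sum(degen), " gene(s) with zero variance in both groups; ",
            "p set to 1 (equal means) or 0 (unequal means)")
    p[degen] <- ifelse(logfc[degen] == 0, 1, 0)
  }
  res <- data.frame(gene = normalize_gene_ids(rownames(mat)),
                    logfc = logfc, p = p, q = bh_fdr(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p, -abs(res$logfc), res$gene), , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (`stats::p.adjust(method = "BH")`), with input
#' validation; preserves input order.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return numeric vector of q-values, same order
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must be finite and in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Threshold a DEG table into signed up/down gene sets
#'
#' Applies one of the two threshold regimes of the screen:
#'
#' * `"array"`: keep genes with `|logFC| > logfc_cut` and `p < p_cut`
#'   (defaults 2 and 0.05) — the regime used for microarray and bulk
#'   RNA-seq DEG tables.
#' * `"scrna"`: keep genes with linear `|FC| > fc_cut_linear`
#'   (equivalently `|logFC| > log2(fc_cut_linear)`, default 1.2) and FDR
#'   `q < q_cut` (default 0.05) — the single-cell regime. Records with
#'   a missing q are rejected, not imputed.
#'
#' Both filters are strict inequalities. Direction is the sign of logFC.
#'
#' @param records data.frame with columns `gene`, `logfc`, `p` and (for
#'   the scrna regime) `q`, e.g. from [compute_deg_stats()] or a
#'   precomputed published DEG table
#' @param regime `"array"` or `"scrna"`
#' @param config configuration list, see [default_config()]
#' @return a [signed_gene_set()]
#' @export
filter_degs <- function(records, regime = c("array", "scrna"),
                        config = default_config()) {
  regime <- match.arg(regime)
  stopifnot(is.data.frame(records),
            all(c("gene", "logfc") %in% names(records)))
  if (regime == "array") {
    if (!"p" %in% names(records)) stop("array regime needs a 'p' column")
    keep <- abs(records$logfc) > config$deg$logfc_cut &
      records$p < config$deg$p_cut
  } else {
    if (!"q" %in% names(records)) stop("scrna regime needs a 'q' column")
    if (anyNA(records$q)) {
      stop("records without a q value cannot enter the scrna regime")
    }
    keep <- abs(records$logfc) > log2(config$deg$fc_cut_linear) &
      records$q < config$deg$q_cut
  }
  keep[is.na(keep)] <- FALSE
  signed_gene_set(up = records$gene[keep & records$logfc > 0],
                  down = records$gene[keep & records$logfc < 0])
}
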