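#' Hypergeometric over-representation of DEGs in gene sets
#'
#' One-sided over-representation test per gene set: with `N` universe
#' genes of which `n` are DEGs, and `K` set members in the universe, the
#' enrichment p-value is the hypergeometric upper tail
#' `P[X >= k]` for the observed overlap `k`. q-values are
#' Benjamini-Hochberg over all tested sets; pathways are ranked by
#' enrichment FDR (then p, then set ID). The up- and down-regulated
#' member DEGs of every set are recorded — they decide which pathways
#' may seed connectivity queries, see [eligible_queries()].
#'
#' Sets are intersected with the universe before testing; sets with
#' fewer than 2 in-universe members are skipped with a note. A DEG not
#' present in the universe is an error (the universe is wrong), not a
#' silent drop.
#'
#' @param degs a [signed_gene_set()] of DEGs of interest
#' @param sets named list of character vectors (gene sets, e.g. from
#'   [read_gmt()])
#' @param universe character vector of all assayed gene IDs
#' @return data.frame with columns `set_id`, `k`, `K`, `n`, `N`, `p`,
#'   `q` and list-columns `member_up`, `member_down`, sorted by q then p
#' @export
enrich_sets <- function(degs, sets, universe) {
  universe <- unique(normalize_gene_ids(universe))
  if (length(universe) == 0) stop("empty universe")
  stopifnot(inherits(degs, "signed_gene_set"))
  deg_all <- c(degs$up, degs$down)
  missing <- setdiff(deg_all, universe)
  if (length(missing) > 0) {
    stop("DEG(s) absent from the universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    stop("sets must be a uniquely named list")
  }
  N <- length(universe)
  n <- length(deg_all)

  rows <- lapply(names(sets), function(id) {
    members <- intersect(unique(normalize_gene_ids(sets[[id]])), universe)
    if (length(members) < 2) return(NULL)
    up <- intersect(members, degs$up)
    down <- intersect(members, degs$down)
    k <- length(up) + length(down)
    K <- length(members)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, k = k, K = K, n = n, N = N, p = p,
               member_up = I(list(up)), member_down = I(list(down)),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0) {
    message(skipped, " set(s) with <2 in-universe members skipped")
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("no testable gene sets after universe trimming")
  }
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$q, res$p, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set_id", "k", "K", "n", "N", "p", "q",
          "member_up", "member_down")]
}

#' Top-ranked enriched gene sets
#'
#' First `limit` records of a ranked enrichment table (default 30, the
#' number of pathways carried forward per experimental group); returns
#' fewer if fewer were tested.
#'
#' @param records enrichment table from [enrich_sets()]
#' @param limit positive count
#' @return the leading rows of `records`
#' @export
top_sets <- function(records, limit = 30) {
  stopifnot(is.data.frame(records))
  if (limit < 1) stop("limit must be >= 1")
  utils::head(records, limit)
}

#' Pathways eligible to seed connectivity queries
#'
#' A pathway seeds a connectivity query only if it carries at least
#' `min_up` up-regulated and `min_down` down-regulated member DEGs
#' (default 3 and 3). The query's signed gene set is exactly those
#' member DEGs.
#'
#' @param records enrichment table from [enrich_sets()]
#' @param min_up,min_down minimum member DEGs per direction
#' @return named list (by set ID) of [signed_gene_set()] queries, in
#'   record order
#' @export
eligible_queries <- function(records, min_up = 3, min_down = 3) {
  stopifnot(is.data.frame(records),
            all(c("member_up", "member_down") %in% names(records)))
  keep <- vapply(records$member_up, length, integer(1)) >= min_up &
    vapply(records$member_down, length, integer(1)) >= min_down
  out <- lapply(which(keep), function(i) {
    signed_gene_set(up = records$member_up[[i]],
                    down = records$member_down[[i]])
  })
  names(out) <- records$set_id[keep]
  out
}
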