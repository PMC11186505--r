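#' Count drug hits per pathway
#'
#' A "hit" is a drug perturbation surviving the overlap-score cutoff
#' within a pathway's ranked query results. Pathways with at least
#' `min_hits` distinct hit drugs (default 3) are retained as pathways
#' of interest.
#'
#' @param results_by_pathway named list (by pathway ID) of
#'   score-filtered result data.frames from [filter_by_score()];
#'   zero-row frames are allowed and count as 0 hits
#' @param min_hits retention threshold
#' @return data.frame `pathway_id`, `n_hits`, `retained` plus a
#'   list-column `hit_drugs`, sorted by n_hits descending then pathway
#'   ID
#' @export
count_pathway_hits <- function(results_by_pathway, min_hits = 3) {
  stopifnot(is.list(results_by_pathway),
            !is.null(names(results_by_pathway)))
  rows <- lapply(names(results_by_pathway), function(pw) {
    drugs <- sort(unique(results_by_pathway[[pw]]$drug_id))
    data.frame(pathway_id = pw, n_hits = length(drugs),
               retained = length(drugs) >= min_hits,
               hit_drugs = I(list(drugs)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$n_hits, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Drugs targeting multiple pathways
#'
#' Drugs that hit at least `min_pathways` distinct pathways are
#' considered more promising. Sorted by pathway count descending, then
#' best score descending, then drug ID.
#'
#' @param results_by_pathway named list of score-filtered result
#'   data.frames (restrict to retained pathways upstream if desired)
#' @param min_pathways minimum number of distinct pathways
#' @return data.frame `drug_id`, `n_pathways`, `best_score` plus a
#'   list-column `pathways`
#' @export
multi_pathway_drugs <- function(results_by_pathway, min_pathways = 2) {
  combined <- do.call(rbind, lapply(names(results_by_pathway), function(pw) {
    r <- results_by_pathway[[pw]]
    if (nrow(r) == 0) return(NULL)
    data.frame(pathway_id = pw, drug_id = r$drug_id, score = r$score,
               stringsAsFactors = FALSE)
  }))
  if (is.null(combined) || nrow(combined) == 0) {
    return(data.frame(drug_id = character(0), n_pathways = integer(0),
                      best_score = numeric(0),
                      pathways = I(list())))
  }
  by_drug <- split(combined, combined$drug_id)
  rows <- lapply(by_drug, function(d) {
    pw <- sort(unique(d$pathway_id))
    data.frame(drug_id = d$drug_id[1], n_pathways = length(pw),
               best_score = max(d$score), pathways = I(list(pw)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$n_pathways >= min_pathways, , drop = FALSE]
  res <- res[order(-res$n_pathways, -res$best_score, res$drug_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Consensus drug list across dataset arms
#'
#' Unions the drugs found in each dataset arm, records the arms and
#' pathways in which each drug appears and its best score anywhere, and
#' ranks drugs appearing in more arms (then more pathways) first —
#' the cross-dataset consensus list.
#'
#' @param arms named list (by arm ID) of named lists (by pathway/query
#'   ID) of score-filtered result data.frames
#' @return data.frame `drug_id`, `n_arms`, `n_pathways`, `best_score`
#'   with list-columns `arms`, `pathways`, sorted by n_arms then
#'   n_pathways descending then drug ID; an empty `annotation` column
#'   is left for manual mechanism-of-action curation
#' @export
consensus_across_arms <- function(arms) {
  stopifnot(is.list(arms), length(arms) >= 1, !is.null(names(arms)))
  combined <- do.call(rbind, lapply(names(arms), function(arm) {
    do.call(rbind, lapply(names(arms[[arm]]), function(pw) {
      r <- arms[[arm]][[pw]]
      if (is.null(r) || nrow(r) == 0) return(NULL)
      data.frame(arm = arm, pathway_id = paste(arm, pw, sep = ":"),
                 drug_id = r$drug_id, score = r$score,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(combined) || nrow(combined) == 0) {
    return(data.frame(drug_id = character(0), n_arms = integer(0),
                      n_pathways = integer(0), best_score = numeric(0),
                      arms = I(list()), pathways = I(list()),
                      annotation = character(0)))
  }
  combined$drug_id <- normalize_gene_ids(combined$drug_id)
  rows <- lapply(split(combined, combined$drug_id), function(d) {
    data.frame(drug_id = d$drug_id[1],
               n_arms = length(unique(d$arm)),
               n_pathways = length(unique(d$pathway_id)),
               best_score = max(d$score),
               arms = I(list(sort(unique(d$arm)))),
               pathways = I(list(sort(unique(d$pathway_id)))),
               annotation = "", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$n_arms, -res$n_pathways, res$drug_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bookkeeping tallies of a multi-arm screen
#'
#' Counts queries (connectivity analyses) and returned perturbations per
#' dataset arm and in total — the screen's conservation check: the sum
#' of per-arm perturbation counts equals the total.
#'
#' @param arms named list (by arm ID) of named lists of per-query result
#'   data.frames (the unfiltered top-K lists from [query_compendium()])
#' @return list with `n_queries_per_arm`, `n_perturbations_per_arm`,
#'   `total_queries`, `total_perturbations`
#' @export
tally_bookkeeping <- function(arms) {
  stopifnot(is.list(arms), !is.null(names(arms)))
  nq <- vapply(arms, length, integer(1))
  np <- vapply(arms, function(queries) {
    sum(vapply(queries, nrow, integer(1)))
  }, integer(1))
  list(n_queries_per_arm = nq,
       n_perturbations_per_arm = np,
       total_queries = sum(nq),
       total_perturbations = sum(np))
}
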