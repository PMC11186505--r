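#' Construct a drug signature
#'
#' A perturbation signature: the genes a drug up- and down-regulates,
#' optionally with a signed characteristic value per gene. If the
#' vector is present, its signs must agree with set membership.
#'
#' @param drug_id identifier
#' @param up,down character vectors of gene IDs (disjoint)
#' @param vector optional named numeric vector of signed characteristic
#'   values
#' @return object of class `drug_signature`
#' @export
drug_signature <- function(drug_id, up, down, vector = NULL) {
  sgs <- signed_gene_set(up, down)
  if (!is.null(vector)) {
    names(vector) <- normalize_gene_ids(names(vector))
    bad_up <- intersect(sgs$up, names(vector))
    bad_up <- bad_up[vector[bad_up] <= 0]
    bad_dn <- intersect(sgs$down, names(vector))
    bad_dn <- bad_dn[vector[bad_dn] >= 0]
    if (length(bad_up) || length(bad_dn)) {
      stop("signature vector signs disagree with up/down membership for ",
           drug_id)
    }
  }
  structure(list(drug_id = as.character(drug_id), up = sgs$up,
                 down = sgs$down, vector = vector),
            class = "drug_signature")
}

#' Signed overlap score between a query and a drug signature
#'
#' The fraction of query genes whose direction is concordant with the
#' signature. In `mimic` mode a query-up gene counts if it is in the
#' signature's up set (and query-down in down); in `reverse` mode the
#' sides are crossed. The denominator is the full query size, so genes
#' absent from the signature count as discordant and scores are
#' comparable across drugs. Bounded in \[0, 1\].
#'
#' @param query a [signed_gene_set()]; must be non-empty
#' @param sig a [drug_signature()]
#' @param mode `"mimic"` or `"reverse"`
#' @return fraction in \[0, 1\]
#' @export
overlap_score <- function(query, sig, mode = c("mimic", "reverse")) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "signed_gene_set"))
  nq <- query_size(query)
  if (nq == 0) stop("overlap score is undefined for an empty query")
  concordant <- if (mode == "mimic") {
    length(intersect(query$up, sig$up)) +
      length(intersect(query$down, sig$down))
  } else {
    length(intersect(query$up, sig$down)) +
      length(intersect(query$down, sig$up))
  }
  concordant / nq
}

#' Cosine similarity between a signed query and a signature vector
#'
#' The query is encoded as +1 on its up genes and -1 on its down genes;
#' the similarity is computed over the genes present in both the query
#' and the signature's characteristic vector. Ranking uses descending
#' similarity (equivalently ascending cosine distance 1 - cos).
#'
#' @param query a [signed_gene_set()]
#' @param sig a [drug_signature()] with a `vector`
#' @return similarity in \[-1, 1\]
#' @export
cosine_score <- function(query, sig) {
  if (is.null(sig$vector)) stop("signature has no characteristic vector")
  shared <- intersect(c(query$up, query$down), names(sig$vector))
  if (length(shared) == 0) stop("no shared genes between query and vector")
  enc <- ifelse(shared %in% query$up, 1, -1)
  v <- sig$vector[shared]
  nv <- sqrt(sum(v^2)); ne <- sqrt(sum(enc^2))
  if (nv == 0 || ne == 0) stop("zero-norm vector in cosine score")
  sum(enc * v) / (nv * ne)
}

#' Query a signature compendium
#'
#' Scores every drug of the compendium against one signed query, sorts
#' by score descending with a deterministic tie-break (drug ID
#' ascending), and returns the top `top_k` with ranks 1..K — the
#' ranked perturbation list of one connectivity analysis.
#'
#' @param query_id label of the query (pathway or dataset arm)
#' @param query a [signed_gene_set()]
#' @param compendium named list of [drug_signature()]s
#' @param mode `"mimic"` or `"reverse"`
#' @param scoring `"overlap"` (signed set overlap) or `"cosine"`
#' @param top_k number of ranked perturbations to return (default 50)
#' @return data.frame `query_id`, `drug_id`, `mode`, `score`, `rank`
#' @export
query_compendium <- function(query_id, query, compendium,
                             mode = c("mimic", "reverse"),
                             scoring = c("overlap", "cosine"),
                             top_k = 50) {
  mode <- match.arg(mode)
  scoring <- match.arg(scoring)
  if (length(compendium) == 0) stop("empty compendium")
  if (top_k < 1) stop("top_k must be >= 1")
  ids <- vapply(compendium, function(s) s$drug_id, character(1))
  scores <- vapply(compendium, function(sig) {
    if (scoring == "overlap") overlap_score(query, sig, mode)
    else {
      s <- cosine_score(query, sig)
      if (mode == "reverse") -s else s
    }
  }, numeric(1))
  ord <- order(-scores, ids)
  k <- min(top_k, length(ids))
  data.frame(query_id = query_id, drug_id = ids[ord][seq_len(k)],
             mode = mode, score = scores[ord][seq_len(k)],
             rank = seq_len(k), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Filter ranked perturbations by overlap score
#'
#' Keeps perturbations whose score strictly exceeds the cutoff (default
#' 0.1, i.e. more than 10% of the query genes concordant); ranks are
#' preserved from the pre-filter ordering.
#'
#' @param results data.frame from [query_compendium()]
#' @param cutoff score cutoff, strict inequality
#' @return filtered data.frame
#' @export
filter_by_score <- function(results, cutoff = 0.1) {
  stopifnot(is.data.frame(results), "score" %in% names(results))
  results[results$score > cutoff, , drop = FALSE]
}
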