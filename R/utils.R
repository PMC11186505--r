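#' Normalize gene identifiers
#'
#' Gene (and peptide/kinase) identifiers coming from mixed mouse/human
#' symbol conventions ("Egfr", "EGFR", " egfr ") are matched
#' case-insensitively after trimming whitespace; the canonical form is
#' upper case.
#'
#' @param x character vector of identifiers
#' @return character vector of canonical identifiers
#' @export
normalize_gene_ids <- function(x) {
  if (length(x) == 0) return(character(0))
  toupper(trimws(as.character(x)))
}

#' Construct a signed gene set
#'
#' A signed gene set is the basic query object of the connectivity
#' screen: a set of up-regulated and a set of down-regulated gene IDs.
#' Members are normalized (see [normalize_gene_ids()]) and de-duplicated;
#' the two sides must be disjoint.
#'
#' @param up,down character vectors of gene IDs
#' @return an object of class `signed_gene_set` with elements `up` and
#'   `down`
#' @export
signed_gene_set <- function(up = character(0), down = character(0)) {
  up <- unique(normalize_gene_ids(up))
  down <- unique(normalize_gene_ids(down))
  both <- intersect(up, down)
  if (length(both) > 0) {
    stop("signed gene set has genes in both directions: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  structure(list(up = up, down = down), class = "signed_gene_set")
}

#' @export
print.signed_gene_set <- function(x, ...) {
  cat(sprintf("<signed_gene_set> %d up / %d down\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' Size of a signed gene set
#' @param query a `signed_gene_set`
#' @return total number of member genes
#' @export
query_size <- function(query) length(query$up) + length(query$down)

# FNV-1a 32-bit hash over a string, in double arithmetic (R has no
# native unsigned 32-bit ints).  Used to stamp output files with a
# configuration fingerprint.
fnv1a32 <- function(s) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(s)) {
    # xor touches only the low byte (b < 256)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply in 16-bit halves (keeps doubles exact)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint of a configuration object
#'
#' Stable short hash of a configuration list, stamped into the metadata
#' header of every table the pipeline writes so that two runs can be
#' compared by their effective configuration.
#'
#' @param config a list (typically from [default_config()])
#' @return an 8-hex-digit string
#' @export
config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

# Derive a child seed from a master seed and a stream label; keeps all
# derived seeds in 32-bit integer range.
derive_seed <- function(seed, label) {
  as.integer(strtoi(substr(fnv1a32(paste0(label, ":", seed)), 1, 7), 16L))
}
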