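# All writers stamp a commented metadata header (pipeline version,
# configuration hash, seed) so any output table can be traced back to
# the run that produced it; readers skip '#' lines.

meta_header <- function(config = NULL, seed = NA) {
  ver <- as.character(utils::packageVersion("otoscreen"))
  c(paste0("# otoscreen ", ver),
    paste0("# config_hash: ",
           if (is.null(config)) "none" else config_hash(config)),
    paste0("# seed: ", seed))
}

#' Read an expression matrix
#'
#' Tab- or comma-delimited, first column gene IDs, header row sample
#' IDs. Duplicate gene rows are collapsed by mean with a warning;
#' duplicate sample IDs and non-numeric cells are errors.
#'
#' @param path input file
#' @return numeric matrix, genes x samples
#' @export
read_expression_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed matrix file")
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample IDs")
  genes <- normalize_gene_ids(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression cells")
  if (anyDuplicated(genes)) {
    warning("duplicate gene rows collapsed by mean")
    vals <- do.call(rbind, lapply(split(seq_along(genes), genes), function(i) {
      colMeans(vals[i, , drop = FALSE])
    }))
    genes <- rownames(vals) <- sort(unique(normalize_gene_ids(df[[1]])))
  } else {
    rownames(vals) <- genes
  }
  vals
}

#' Write an expression matrix
#' @param mat numeric matrix, genes x samples
#' @param path output TSV
#' @param config,seed stamped into the metadata header
#' @export
write_expression_matrix <- function(mat, path, config = NULL, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(config, seed), con)
  writeLines(paste(c("gene", colnames(mat)), collapse = "\t"), con)
  utils::write.table(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: per line a set name, a description, then the member
#' genes, tab-separated. Members are de-duplicated; lines with fewer
#' than 3 fields (i.e. empty sets) are errors.
#'
#' @param path GMT file
#' @return named list of character vectors
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("empty GMT file")
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with <3 fields: ", substr(l, 1, 40))
    unique(normalize_gene_ids(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors
#' @param path output file
#' @param description description field (recycled)
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, description, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a drug-signature compendium from JSON
#'
#' Schema: an object mapping drug IDs to `{"up": [...], "down": [...]}`
#' with an optional `"vector"` mapping gene to signed value. Signatures
#' with intersecting up/down sets or sign-inconsistent vectors are
#' rejected.
#'
#' @param path JSON file
#' @return named list of [drug_signature()]s
#' @export
read_compendium <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (length(raw) == 0) stop("empty compendium")
  sigs <- lapply(names(raw), function(id) {
    entry <- raw[[id]]
    if (!all(c("up", "down") %in% names(entry))) {
      stop("compendium entry '", id, "' missing field: up/down")
    }
    vec <- entry$vector
    if (!is.null(vec)) vec <- unlist(vec)
    drug_signature(id, up = unlist(entry$up), down = unlist(entry$down),
                   vector = vec)
  })
  names(sigs) <- names(raw)
  sigs
}

#' Write a drug-signature compendium to JSON
#' @param compendium named list of [drug_signature()]s
#' @param path output file
#' @export
write_compendium <- function(compendium, path) {
  out <- lapply(compendium, function(s) {
    e <- list(up = s$up, down = s$down)
    if (!is.null(s$vector)) e$vector <- as.list(s$vector)
    e
  })
  jsonlite::write_json(out, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a kinome chip run from TSV
#'
#' Peptide rows, exposure columns named `exp_<ms>`; well and condition
#' come from commented metadata lines `# well_id:` / `# condition:` or
#' arguments. Fewer than 3 exposure columns is an error (slope fitting
#' needs >= 3 points).
#'
#' @param path TSV file
#' @param well_id,condition overrides for the metadata lines
#' @return a [kinome_chip_run()]
#' @export
read_chip_run <- function(path, well_id = NULL, condition = NULL) {
  lines <- readLines(path, n = 20)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (length(m)) trimws(sub(paste0("^# ", key, ":"), "", m[1])) else NULL
  }
  well_id <- well_id %||% get_meta("well_id") %||% "well1"
  condition <- condition %||% get_meta("condition") %||% "unknown"
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE)
  expo_cols <- grep("^exp_", colnames(df), value = TRUE)
  if (length(expo_cols) < 3) stop("chip run needs >= 3 exposure columns")
  mat <- as.matrix(df[, expo_cols, drop = FALSE])
  rownames(mat) <- normalize_gene_ids(df[[1]])
  kinome_chip_run(well_id, condition, mat,
                  as.numeric(sub("^exp_", "", expo_cols)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a kinome chip run to TSV
#' @param run a [kinome_chip_run()]
#' @param path output file
#' @export
write_chip_run <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(meta_header(), paste0("# well_id: ", run$well_id),
               paste0("# condition: ", run$condition)), con)
  cols <- paste0("exp_", run$exposures)
  writeLines(paste(c("peptide", cols), collapse = "\t"), con)
  utils::write.table(data.frame(peptide = rownames(run$intensities),
                                run$intensities, check.names = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a concentration-time profile from CSV
#'
#' Columns `time` (h) and `conc` (ng/ml); dose and LLOQ from arguments
#' or commented metadata lines `# dose:` / `# lloq:`.
#'
#' @param path CSV file
#' @param dose,lloq overrides for the metadata lines
#' @return a [conc_time_profile()]
#' @export
read_pk_profile <- function(path, dose = NULL, lloq = NULL) {
  lines <- readLines(path, n = 20)
  get_meta <- function(key) {
    m <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (length(m)) as.numeric(sub(paste0("^# ", key, ":"), "", m[1])) else NULL
  }
  dose <- dose %||% get_meta("dose")
  lloq <- lloq %||% get_meta("lloq") %||% 5
  if (is.null(dose)) stop("dose not given and not in file metadata")
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "conc") %in% names(df))) {
    stop("PK CSV needs 'time' and 'conc' columns")
  }
  conc_time_profile(df$time, df$conc, dose = dose, lloq = lloq)
}

#' Write a concentration-time profile to CSV
#' @param profile a [conc_time_profile()]
#' @param path output file
#' @export
write_pk_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(meta_header(), paste0("# dose: ", profile$dose),
               paste0("# lloq: ", profile$lloq)), con)
  writeLines("time,conc", con)
  utils::write.table(data.frame(profile$times, profile$conc), con,
                     sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a result table with a metadata header
#'
#' Tab-separated with commented header lines; list-columns are joined
#' with ";". The standard writer for every report table of the
#' pipeline.
#'
#' @param df data.frame
#' @param path output TSV
#' @param config,seed stamped into the metadata header
#' @export
write_table <- function(df, path, config = NULL, seed = NA) {
  flat <- df
  for (nm in names(flat)) {
    if (is.list(flat[[nm]])) {
      flat[[nm]] <- vapply(flat[[nm]], paste, character(1), collapse = ";")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(config, seed), con)
  utils::write.table(flat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a ground-truth sidecar JSON
#' @param truth list of truth fields from a generator
#' @param path output JSON
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
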