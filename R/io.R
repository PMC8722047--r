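#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then one gene symbol per
#' field. Within-set duplicate genes are removed with the first occurrence
#' kept, so downstream enrichment walks never double-count a gene.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one element per gene set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(structure(list(), names = character()))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    nms[i] <- fields[1]
    sets[[i]] <- genes[!duplicated(genes)]
  }
  names(sets) <- nms
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read a per-screen hit table
#'
#' Ingests a MAGeCK-style gene summary reduced to four columns: `gene`,
#' `lfc` (log2 fold change of sgRNA abundance), `adj_p_pos` and `adj_p_neg`
#' (BH-adjusted positive/negative selection p-values). Missing p-values are
#' preserved as `NA`, not imputed.
#'
#' @param path Path to a TSV file with a header row.
#' @param screen_id Identifier attached to the table; defaults to the file
#'   name without extension.
#' @return A data.frame with attribute `screen_id`.
#' @export
read_screen_hits <- function(path, screen_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene", "lfc", "adj_p_pos", "adj_p_neg")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("screen hit table %s is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in c("lfc", "adj_p_pos", "adj_p_neg")) {
    raw <- df[[col]]
    suppressWarnings(num <- as.numeric(raw))
    bad <- which(is.na(num) & !is.na(raw) & !(toupper(trimws(raw)) %in% c("NA", "")))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' in column %s, row %d of %s",
                   raw[bad[1]], col, bad[1], path), call. = FALSE)
    }
    df[[col]] <- num
  }
  assert_prob(df$adj_p_pos, "adj_p_pos", allow_na = TRUE)
  assert_prob(df$adj_p_neg, "adj_p_neg", allow_na = TRUE)
  attr(df, "screen_id") <- screen_id %||% sub("\\.[^.]*$", "", basename(path))
  df
}

#' Read a screen metadata table
#'
#' Expected columns: `screen_id`, `study_id`, `cancer_type`, `setting`
#' (in_vitro/in_vivo), `library_scale` (genome_scale/focused), `organism`
#' (mouse/human), `algorithm`, `icb_treated` (logical).
#'
#' @param path TSV path.
#' @return data.frame of screen descriptors.
#' @export
read_screen_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("screen_id", "study_id", "cancer_type", "setting",
                "library_scale", "organism", "algorithm", "icb_treated")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("screen metadata is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(df$screen_id)) {
    stop("screen_id values must be unique", call. = FALSE)
  }
  df$icb_treated <- as.logical(df$icb_treated)
  stopifnot(all(df$setting %in% c("in_vitro", "in_vivo")),
            all(df$library_scale %in% c("genome_scale", "focused")),
            all(df$organism %in% c("mouse", "human")))
  df
}

#' Summarize screen metadata by a categorical field
#'
#' Counts screens per category and reports percentages of the total,
#' rounded half-up to two decimals, with categories ordered by descending
#' count and then lexicographically.
#'
#' @param screens data.frame as returned by [read_screen_metadata()].
#' @param field One of `cancer_type`, `setting`, `library_scale`,
#'   `organism`, `algorithm`.
#' @return data.frame with columns `category`, `count`, `percentage`.
#' @export
summarize_metadata <- function(screens,
                               field = c("cancer_type", "setting",
                                         "library_scale", "organism",
                                         "algorithm")) {
  field <- match.arg(field)
  if (nrow(screens) == 0) stop("no screens to summarize", call. = FALSE)
  tab <- table(screens[[field]])
  out <- data.frame(category = names(tab),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percentage <- round_half_up(100 * out$count / sum(out$count), 2)
  out <- out[order(-out$count, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genes-by-columns numeric matrix from TSV
#'
#' The repo-wide matrix convention: header row of sample/drug identifiers,
#' first column of gene identifiers, tab separators, `NA` for missing.
#'
#' @param path TSV path.
#' @return Numeric matrix with gene rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a numeric matrix to TSV (genes as rows)
#'
#' @param m Matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column (default "gene").
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read mutation records (MAF-lite)
#'
#' Columns: `sample`, `gene`, `consequence` (frameshift, stopgain,
#' startloss, stoploss, missense, other) and `damage_prob` (damaging
#' probability for missense calls; may be NA).
#'
#' @param path TSV path.
#' @return data.frame of mutation records.
#' @export
read_mutations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample", "gene", "consequence", "damage_prob")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("mutation table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$damage_prob <- suppressWarnings(as.numeric(df$damage_prob))
  assert_prob(df$damage_prob, "damage_prob", allow_na = TRUE)
  df
}

#' Read per-sample annotations
#'
#' Columns: `sample`, `cancer_type`, `immune_subtype` (C1..C6 or NA),
#' `age`, `os_time`, `os_event`, `response` (CR/PR/SD/PD or NA).
#'
#' @param path TSV path.
#' @return data.frame of annotations.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  if (!"sample" %in% names(df)) {
    stop("annotation table must have a 'sample' column", call. = FALSE)
  }
  df
}
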