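#' Single-sample gene-set enrichment (ssGSEA-style) score
#'
#' Genes are ranked by descending expression (ties broken by gene symbol,
#' lexicographic, for determinism). Walking down the ranking, the score is
#' the sum over all positions of the difference between the weighted
#' in-set cumulative fraction and the uniform out-of-set step:
#' \deqn{ES = \sum_{i=1}^{N} [P^w_{in}(i) - P_{out}(i)]}
#' where the weight of the set gene at position i is `(N - i + 1)^alpha`
#' (higher-expressed genes count more). A set covering every gene has
#' `P_out == 0` by convention.
#'
#' @param expr_column Named numeric vector: one sample's expression.
#' @param gene_set Character vector of set genes.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Numeric enrichment score.
#' @export
ssgsea_score <- function(expr_column, gene_set, alpha = 0.25) {
  genes <- names(expr_column)
  if (is.null(genes)) stop("expr_column must be a named vector", call. = FALSE)
  present <- intersect(gene_set, genes)
  if (length(present) == 0) {
    stop(sprintf("gene set has no overlap with the expression vector (%d genes)",
                 length(genes)), call. = FALSE)
  }
  ord <- order(-expr_column, genes)
  ranked <- genes[ord]
  n <- length(ranked)
  in_set <- ranked %in% present
  w <- ifelse(in_set, (n - seq_len(n) + 1)^alpha, 0)
  p_in <- cumsum(w) / sum(w)
  n_out <- n - sum(in_set)
  p_out <- if (n_out == 0) rep(0, n) else cumsum(!in_set) / n_out
  sum(p_in - p_out)
}

#' Cytolytic activity (CYT) score
#'
#' Geometric mean of GZMA and PRF1 expression on a linear scale with a
#' pseudocount: `sqrt((a + c) (b + c))`.
#'
#' @param expr_gzma,expr_prf1 Non-negative linear-scale expression values
#'   (vectorized).
#' @param pseudocount Added to both genes before the product (default 0.01).
#' @return Numeric score(s).
#' @export
cyt_score <- function(expr_gzma, expr_prf1, pseudocount = 0.01) {
  if (any(expr_gzma < 0, na.rm = TRUE) || any(expr_prf1 < 0, na.rm = TRUE)) {
    stop("CYT expects non-negative linear-scale expression", call. = FALSE)
  }
  sqrt((expr_gzma + pseudocount) * (expr_prf1 + pseudocount))
}

#' MHC antigen-presentation score
#'
#' Mean per-gene z-scored expression over an MHC gene set (default
#' members: HLA-A/B/C, B2M, TAP1/2, NLRC5, PSMB8/9 via the packaged GMT).
#'
#' @param z_column Named numeric vector of one sample's z-scored expression.
#' @param mhc_set Character vector of MHC set genes.
#' @return Numeric score.
#' @export
mhc_score <- function(z_column, mhc_set) {
  present <- intersect(mhc_set, names(z_column))
  if (length(present) == 0) stop("MHC set has no overlap with expression",
                                 call. = FALSE)
  mean(z_column[present])
}

#' Compute the three tumor-immunity signature scores for a cohort
#'
#' Returns one row per sample with columns `immune` (ssGSEA over the
#' immune set), `CYT` (cytolytic score reported as the log2 of the
#' geometric mean of GZMA and PRF1 linear expression, i.e. their mean
#' log2 expression after the pseudocount -- the log scale stabilizes the
#' variance of this strictly positive multiplicative score for the
#' downstream linear associations; [cyt_score()] gives the linear-scale
#' value), and `MHC` (mean z over the MHC set). All three are oriented
#' so that higher = stronger anti-tumor immune state.
#'
#' @param cohort An [omics_cohort()].
#' @param gene_sets Named list with elements `immune` and `MHC`
#'   (see [default_signature_sets()]).
#' @param ssgsea_alpha Weight exponent passed to [ssgsea_score()].
#' @return data.frame with rownames = samples and columns
#'   immune, CYT, MHC.
#' @export
signature_scores <- function(cohort, gene_sets = default_signature_sets(),
                             ssgsea_alpha = 0.25) {
  stopifnot(all(c("immune", "MHC") %in% names(gene_sets)))
  expr <- cohort$expr
  z <- cohort$expr_z
  samples <- colnames(expr)
  lin <- pmax(2^expr - 1, 0)
  gzma <- if ("GZMA" %in% rownames(expr)) lin["GZMA", ] else
    stop("GZMA missing from expression; cannot compute CYT", call. = FALSE)
  prf1 <- if ("PRF1" %in% rownames(expr)) lin["PRF1", ] else
    stop("PRF1 missing from expression; cannot compute CYT", call. = FALSE)
  immune <- vapply(samples, function(s)
    ssgsea_score(expr[, s], gene_sets$immune, ssgsea_alpha), numeric(1))
  mhc <- vapply(samples, function(s)
    mhc_score(z[, s], gene_sets$MHC), numeric(1))
  data.frame(immune = immune,
             CYT = unname(log2(cyt_score(gzma, prf1))),
             MHC = mhc, row.names = samples)
}

#' Default immune and MHC signature gene sets
#'
#' Reads the GMT shipped with the package. The member lists are
#' structural stand-ins with the composition of published immune and
#' antigen-presentation signatures; both are replaceable by any GMT.
#'
#' @return Named list of character vectors (`immune`, `CYT`, `MHC`).
#' @export
default_signature_sets <- function() {
  read_gmt(system.file("extdata", "signatures.gmt", package = "iscreen"))
}

#' Read an immune-feature catalog
#'
#' Features (immune cell types, checkpoint genes, cytokines) with their
#' gene sets and anti-/pro-tumor polarity. TSV columns: `feature`,
#' `category` (immune_cell/checkpoint_gene/cytokine), `polarity`
#' (anti_tumor/pro_tumor), `genes` (comma-separated).
#'
#' @param path TSV path; defaults to the packaged synthetic catalog.
#' @return data.frame with list-column `genes`.
#' @export
read_feature_catalog <- function(path = system.file("extdata",
                                                    "feature_catalog_synthetic.tsv",
                                                    package = "iscreen")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("feature", "category", "polarity", "genes") %in% names(df)),
            all(df$polarity %in% c("anti_tumor", "pro_tumor")))
  df$genes <- strsplit(df$genes, ",", fixed = TRUE)
  df
}

#' Per-sample abundance of immune-related features
#'
#' Each feature scores as the mean z-scored expression of its gene set
#' (a single-gene feature is that gene's z). Features with no overlap
#' with the expression matrix are dropped with a warning.
#'
#' @param expr_z Genes-by-samples z-scored expression matrix.
#' @param catalog data.frame from [read_feature_catalog()].
#' @return Samples-by-features numeric matrix; attribute `polarity`
#'   carries each retained feature's polarity.
#' @export
feature_abundance <- function(expr_z, catalog) {
  stopifnot(nrow(catalog) > 0)
  cols <- list()
  polarity <- character()
  for (i in seq_len(nrow(catalog))) {
    present <- intersect(catalog$genes[[i]], rownames(expr_z))
    if (length(present) == 0) {
      warning(sprintf("feature '%s' has no genes in the expression matrix; dropped",
                      catalog$feature[i]))
      next
    }
    cols[[catalog$feature[i]]] <- colMeans(expr_z[present, , drop = FALSE])
    polarity[catalog$feature[i]] <- catalog$polarity[i]
  }
  m <- do.call(cbind, cols)
  structure(m, polarity = polarity)
}
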