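#' Assemble a multi-omics cohort
#'
#' Bundles log-scale expression, mutation records, GISTIC-coded copy
#' number, and per-sample annotations, and precomputes per-gene
#' standardized expression (`expr_z`). Standardization defaults to within
#' cancer type, so tissue-level expression differences do not masquerade
#' as functional events; set `z_stratify = "cohort"` for pan-cohort
#' scaling.
#'
#' @param expr Genes-by-samples numeric matrix of log-scale expression.
#' @param mutations data.frame with columns `sample`, `gene`,
#'   `consequence`, `damage_prob`.
#' @param cnv Genes-by-samples integer matrix of GISTIC codes in -2..2.
#' @param annotations data.frame with at least `sample` and `cancer_type`.
#' @param z_stratify `"cancer_type"` (default) or `"cohort"`.
#' @return An object of class `omics_cohort`.
#' @export
omics_cohort <- function(expr, mutations, cnv, annotations,
                         z_stratify = c("cancer_type", "cohort")) {
  z_stratify <- match.arg(z_stratify)
  stopifnot(is.matrix(expr), is.matrix(cnv))
  samples <- colnames(expr)
  if (!setequal(samples, annotations$sample)) {
    stop("expression samples and annotation samples disagree", call. = FALSE)
  }
  if (!setequal(samples, colnames(cnv))) {
    stop("expression samples and CNV samples disagree", call. = FALSE)
  }
  annotations <- annotations[match(samples, annotations$sample), , drop = FALSE]
  cnv <- cnv[, samples, drop = FALSE]
  bad_cnv <- stats::na.omit(unique(as.vector(cnv)))
  if (!all(bad_cnv %in% -2:2)) {
    stop("CNV matrix must contain GISTIC codes in -2..2", call. = FALSE)
  }
  strata <- if (z_stratify == "cancer_type") annotations$cancer_type
            else rep("cohort", length(samples))
  expr_z <- standardize_expression(expr, strata)
  structure(list(expr = expr, expr_z = expr_z, mutations = mutations,
                 cnv = cnv, annotations = annotations,
                 z_stratify = z_stratify),
            class = "omics_cohort")
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat(sprintf("omics_cohort: %d genes x %d samples (%d cancer types, %d mutation records, z within %s)\n",
              nrow(x$expr), ncol(x$expr),
              length(unique(x$annotations$cancer_type)),
              nrow(x$mutations), x$z_stratify))
  invisible(x)
}

#' Per-gene z-scoring of an expression matrix within strata
#'
#' @param expr Genes-by-samples matrix.
#' @param strata Character vector of per-sample stratum labels.
#' @return Matrix of the same shape; genes constant within a stratum get 0.
#' @export
standardize_expression <- function(expr, strata) {
  stopifnot(length(strata) == ncol(expr))
  z <- expr
  for (s in unique(strata)) {
    cols <- which(strata == s)
    block <- expr[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sdv <- apply(block, 1, stats::sd)
    sdv[sdv == 0 | is.na(sdv)] <- Inf   # constant gene -> z = 0
    z[, cols] <- (block - mu) / sdv
  }
  z
}

#' Is a mutation deleterious?
#'
#' Loss-of-function consequence classes (frameshift, stopgain, startloss,
#' stoploss) are always deleterious; missense calls only when the damaging
#' probability exceeds 0.5 (strict). Missense with missing probability is
#' conservative: not deleterious.
#'
#' @param consequence Character vector of consequence classes.
#' @param damage_prob Numeric vector of damaging probabilities (may be NA).
#' @return Logical vector.
#' @export
is_deleterious <- function(consequence, damage_prob = NA_real_) {
  lof <- c("frameshift", "stopgain", "startloss", "stoploss")
  consequence %in% lof |
    (consequence == "missense" & !is.na(damage_prob) & damage_prob > 0.5)
}

# Internal: per-sample clause evaluation for one gene. Returns a list with
# the logical call vector and a provenance matrix (samples x clauses).
.call_events <- function(cohort, gene, kind, z_cut) {
  samples <- colnames(cohort$expr)
  n <- length(samples)
  in_expr <- gene %in% rownames(cohort$expr)
  in_cnv <- gene %in% rownames(cohort$cnv)
  mut_rows <- cohort$mutations[cohort$mutations$gene == gene, , drop = FALSE]
  if (kind == "inactivation") {
    mut_clause <- rep(FALSE, n)
    if (nrow(mut_rows) > 0) {
      del <- mut_rows[is_deleterious(mut_rows$consequence, mut_rows$damage_prob), ]
      mut_clause <- samples %in% del$sample
    }
    cnv_clause <- if (in_cnv) !is.na(cohort$cnv[gene, ]) & cohort$cnv[gene, ] == -2
                  else rep(FALSE, n)
    expr_clause <- if (in_expr) !is.na(cohort$expr_z[gene, ]) & cohort$expr_z[gene, ] <= z_cut
                   else rep(FALSE, n)
    prov <- cbind(mutation = mut_clause, cnv = cnv_clause,
                  expression = expr_clause)
  } else {
    cnv_clause <- if (in_cnv) !is.na(cohort$cnv[gene, ]) & cohort$cnv[gene, ] == 2
                  else rep(FALSE, n)
    expr_clause <- if (in_expr) !is.na(cohort$expr_z[gene, ]) & cohort$expr_z[gene, ] >= z_cut
                   else rep(FALSE, n)
    prov <- cbind(cnv = cnv_clause, expression = expr_clause)
  }
  rownames(prov) <- samples
  list(call = rowSums(prov) > 0, provenance = prov,
       covered = in_expr || in_cnv || nrow(mut_rows) > 0)
}

#' Call an inactivation event for one gene in one sample
#'
#' A sample carries an inactivation event when any clause holds: a
#' deleterious mutation, a deep deletion (GISTIC code -2), or
#' standardized expression at or below `z_cut` (default -2).
#'
#' @param cohort An [omics_cohort()].
#' @param gene Gene symbol.
#' @param sample Sample identifier.
#' @param z_cut Expression z threshold (default -2, inclusive).
#' @return Logical scalar with attribute `provenance` listing the
#'   satisfied clauses.
#' @export
call_inactivation <- function(cohort, gene, sample, z_cut = -2) {
  res <- .call_events(cohort, gene, "inactivation", z_cut)
  if (!res$covered) stop(sprintf("gene %s absent from all omics layers", gene),
                         call. = FALSE)
  if (!sample %in% rownames(res$provenance)) {
    stop(sprintf("unknown sample %s", sample), call. = FALSE)
  }
  prov <- res$provenance[sample, ]
  structure(unname(res$call[[sample]]), provenance = names(prov)[prov])
}

#' Call an activation event for one gene in one sample
#'
#' A sample carries an activation event when it shows high-level
#' amplification (GISTIC code 2) or standardized expression at or above
#' `z_cut` (default +2). Mutations are never consulted: gain-of-function
#' prediction is unreliable, so the mutation layer is excluded from
#' activation calling.
#'
#' @inheritParams call_inactivation
#' @param z_cut Expression z threshold (default +2, inclusive).
#' @return Logical scalar with attribute `provenance`.
#' @export
call_activation <- function(cohort, gene, sample, z_cut = 2) {
  res <- .call_events(cohort, gene, "activation", z_cut)
  if (!res$covered) stop(sprintf("gene %s absent from all omics layers", gene),
                         call. = FALSE)
  if (!sample %in% rownames(res$provenance)) {
    stop(sprintf("unknown sample %s", sample), call. = FALSE)
  }
  prov <- res$provenance[sample, ]
  structure(unname(res$call[[sample]]), provenance = names(prov)[prov])
}

#' Build a binary functional-status matrix
#'
#' Applies [call_inactivation()] or [call_activation()] gene-by-gene over
#' the whole cohort. Row order follows the input gene list, column order
#' the cohort's sample order. Genes absent from every layer are skipped
#' with a summary count rather than failing the run.
#'
#' @param cohort An [omics_cohort()].
#' @param genes Character vector of genes to call.
#' @param kind `"inactivation"` or `"activation"`.
#' @param z_cut Expression z threshold; defaults to -2 for inactivation
#'   and +2 for activation.
#' @return Binary integer matrix (genes x samples) of class
#'   `status_matrix`, with attributes `kind` and `skipped`.
#' @export
build_status_matrix <- function(cohort, genes,
                                kind = c("inactivation", "activation"),
                                z_cut = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(genes) > 0)
  if (is.null(z_cut)) z_cut <- if (kind == "inactivation") -2 else 2
  samples <- colnames(cohort$expr)
  rows <- list()
  skipped <- character()
  for (g in genes) {
    res <- .call_events(cohort, g, kind, z_cut)
    if (!res$covered) {
      skipped <- c(skipped, g)
      next
    }
    rows[[g]] <- as.integer(res$call)
  }
  if (length(skipped) > 0) {
    iscreen_log("build_status_matrix: skipped %d gene(s) absent from all layers",
                length(skipped))
  }
  m <- do.call(rbind, rows)
  if (is.null(m)) m <- matrix(integer(), nrow = 0, ncol = length(samples))
  colnames(m) <- samples
  structure(m, kind = kind, skipped = skipped, class = c("status_matrix", class(m)))
}
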