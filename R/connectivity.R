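#' Assemble the immunotherapy query signature
#'
#' Positive regulators (up side) = sensitizers, tumor-immunity-related
#' TSGs, and ICB enhancer genes; negative regulators (down side) =
#' resistors, tumor-immunity-related OGs, and ICB suppressor genes.
#' A gene landing on both sides is removed from both and logged.
#'
#' @param sensitizers,resistors Catalog gene lists.
#' @param tsgs,ogs Tumor-immunity-related driver lists.
#' @param icb_enhancers,icb_suppressors ICB-screen gene lists.
#' @return List with elements `up` and `down` (class `query_signature`).
#' @export
build_query_signature <- function(sensitizers = character(),
                                  resistors = character(),
                                  tsgs = character(), ogs = character(),
                                  icb_enhancers = character(),
                                  icb_suppressors = character()) {
  up <- unique(c(sensitizers, tsgs, icb_enhancers))
  down <- unique(c(resistors, ogs, icb_suppressors))
  both <- intersect(up, down)
  if (length(both) > 0) {
    iscreen_log("build_query_signature: %d gene(s) on both sides removed: %s",
                length(both), paste(both, collapse = ","))
    up <- setdiff(up, both)
    down <- setdiff(down, both)
  }
  structure(list(up = up, down = down), class = "query_signature")
}

#' Filter a drug-signature matrix by clinical phase
#'
#' Keeps drugs whose development stage is at or beyond `min_phase` in the
#' ordering preclinical < phase1 < phase2 < phase3 < launched. The
#' default keeps drugs that have passed phase II trials or are approved.
#' Unannotated drugs are excluded and logged.
#'
#' @param matrix Genes-by-drugs numeric matrix.
#' @param annotations data.frame with columns `drug`, `clinical_phase`.
#' @param min_phase Minimum phase to retain (default "phase3").
#' @return The column-filtered matrix.
#' @export
filter_drugs_by_phase <- function(matrix, annotations, min_phase = "phase3") {
  phases <- c(preclinical = 1, phase1 = 2, phase2 = 3, phase3 = 4,
              launched = 5)
  stopifnot(min_phase %in% names(phases))
  drugs <- colnames(matrix)
  ann <- annotations[match(drugs, annotations$drug), , drop = FALSE]
  unknown <- drugs[is.na(ann$clinical_phase)]
  if (length(unknown) > 0) {
    iscreen_log("filter_drugs_by_phase: excluded %d unannotated drug(s)",
                length(unknown))
  }
  keep <- !is.na(ann$clinical_phase) &
    phases[ann$clinical_phase] >= phases[min_phase]
  out <- matrix[, keep, drop = FALSE]
  if (ncol(out) == 0) warning("no drugs pass the clinical-phase filter")
  out
}

#' Signed Kolmogorov-Smirnov enrichment of a tag set in a ranked list
#'
#' Connectivity-map style running statistic. With tag positions
#' `V(1) < ... < V(t)` (1-based) in a list of `n` genes:
#' `a = max_j [j/t - V(j)/n]`, `b = max_j [V(j)/n - (j-1)/t]`, and
#' `ES = a` if `a >= b`, else `-b`. Tags clustered at the top give ES
#' near +1, at the bottom near -1.
#'
#' @param tag_positions Strictly increasing integer positions.
#' @param n Total number of genes in the ranked list.
#' @return Signed enrichment score in [-1, 1].
#' @export
ks_enrichment <- function(tag_positions, n) {
  t <- length(tag_positions)
  if (t == 0) stop("empty tag set", call. = FALSE)
  stopifnot(all(diff(tag_positions) > 0), tag_positions[1] >= 1,
            tag_positions[t] <= n)
  j <- seq_len(t)
  a <- max(j / t - tag_positions / n)
  b <- max(tag_positions / n - (j - 1) / t)
  if (a >= b) a else -b
}

#' KS connectivity score of a query signature against one drug ranking
#'
#' Computes KS enrichment of the up and down sets in the drug's
#' descending expression-change ranking; when the two enrichments have
#' opposite signs the score is `ES_up - ES_down`, otherwise 0 (the
#' classic connectivity-map zeroing rule). Negative scores mark reversal.
#'
#' @param up,down Query gene sets.
#' @param drug_ranking Character vector of genes ordered by descending
#'   drug-induced expression change.
#' @return Raw (unscaled) connectivity score.
#' @export
ks_connectivity <- function(up, down, drug_ranking) {
  n <- length(drug_ranking)
  pos_up <- sort(match(intersect(up, drug_ranking), drug_ranking))
  pos_down <- sort(match(intersect(down, drug_ranking), drug_ranking))
  if (length(pos_up) == 0 || length(pos_down) == 0) {
    stop("query up/down sets must both overlap the drug ranking", call. = FALSE)
  }
  es_up <- ks_enrichment(pos_up, n)
  es_down <- ks_enrichment(pos_down, n)
  if (sign(es_up) == sign(es_down)) 0 else es_up - es_down
}

#' Cohort-level scaling of KS connectivity scores
#'
#' Divides positive scores by the cohort maximum and negative scores by
#' the absolute cohort minimum so that scores span [-1, 1]. The scaling
#' is rank-preserving within sign.
#'
#' @param scores Numeric vector of raw connectivity scores.
#' @return Scaled scores.
#' @export
scale_connectivity <- function(scores) {
  out <- scores
  pos <- which(scores > 0)
  neg <- which(scores < 0)
  if (length(pos) > 0) out[pos] <- scores[pos] / max(scores[pos])
  if (length(neg) > 0) out[neg] <- scores[neg] / abs(min(scores[neg]))
  out
}

#' eXtreme Sum (XSum) score
#'
#' Restricts attention to the drug's `n_extreme` most up- and
#' down-regulated genes; the score is the summed change of query up
#' genes inside that extreme set minus the summed change of query down
#' genes. Strongly negative = reversal.
#'
#' @param up,down Query gene sets.
#' @param drug_profile Named numeric vector of expression changes.
#' @param n_extreme Genes kept at each extreme (default 500; truncated
#'   to the available genes).
#' @return Numeric score.
#' @export
xsum_score <- function(up, down, drug_profile, n_extreme = 500) {
  stopifnot(n_extreme >= 1)
  genes <- names(drug_profile)
  n <- length(genes)
  k <- min(n_extreme, floor(n / 2))
  ord <- order(-drug_profile, genes)
  extreme <- c(genes[ord][seq_len(k)], genes[rev(ord)][seq_len(k)])
  sum(drug_profile[intersect(up, extreme)]) -
    sum(drug_profile[intersect(down, extreme)])
}

#' Reverse gene expression score (RGES)
#'
#' `ES_up - ES_down` on the drug's descending-change ranking, without
#' the connectivity-map same-sign zeroing; more negative = stronger
#' reversal of the query signature.
#'
#' @inheritParams ks_connectivity
#' @return Numeric score.
#' @export
rges_score <- function(up, down, drug_ranking) {
  n <- length(drug_ranking)
  pos_up <- sort(match(intersect(up, drug_ranking), drug_ranking))
  pos_down <- sort(match(intersect(down, drug_ranking), drug_ranking))
  if (length(pos_up) == 0 || length(pos_down) == 0) {
    stop("query up/down sets must both overlap the drug ranking", call. = FALSE)
  }
  ks_enrichment(pos_up, n) - ks_enrichment(pos_down, n)
}

#' Stuart order-statistic Q value
#'
#' Joint probability that N iid uniforms, sorted, fall below the
#' observed rank ratios: with `r(1) <= ... <= r(N)`, `V_0 = 1`,
#' `V_k = sum_{i=1}^{k} (-1)^{i-1} V_{k-i} r(N-k+1)^i / i!` and
#' `Q = N! V_N`. Small Q marks a drug consistently near the top across
#' scoring methods.
#'
#' @param rank_ratios Numeric vector in (0, 1].
#' @return Q in (0, 1].
#' @export
stuart_q <- function(rank_ratios) {
  n <- length(rank_ratios)
  stopifnot(n >= 1)
  if (any(rank_ratios <= 0 | rank_ratios > 1)) {
    stop("rank ratios must lie in (0, 1]", call. = FALSE)
  }
  r <- sort(rank_ratios)
  v <- numeric(n + 1)
  v[1] <- 1
  for (k in seq_len(n)) {
    i <- seq_len(k)
    v[k + 1] <- sum((-1)^(i - 1) * v[k - i + 1] * r[n - k + 1]^i / factorial(i))
  }
  factorial(n) * v[n + 1]
}

#' Ensemble drug ranking by Stuart order-statistic aggregation
#'
#' Scores every drug with XSum, KS connectivity, and RGES against a
#' query signature; all three place stronger reversal at the negative
#' end, so each method's ascending rank (average ranks on ties) yields a
#' rank ratio r = rank / n_drugs, and the per-drug Stuart Q fuses the
#' three. Final ordering is ascending Q, ties broken by mean rank ratio
#' then drug id. Drugs whose ranking the query does not overlap are
#' excluded with a logged reason.
#'
#' @param query A [build_query_signature()] result.
#' @param drug_matrix Genes-by-drugs matrix of expression changes.
#' @param n_extreme Passed to [xsum_score()].
#' @param methods Methods to fuse (default all three).
#' @return data.frame: drug, xsum, ks, rges (scaled ks in `ks`), per-
#'   method rank ratios, `q`, `final_rank`.
#' @export
rank_aggregate <- function(query, drug_matrix, n_extreme = 500,
                           methods = c("xsum", "ks", "rges")) {
  stopifnot(length(methods) >= 2)
  drugs <- colnames(drug_matrix)
  genes <- rownames(drug_matrix)
  usable <- vapply(drugs, function(d) {
    length(intersect(query$up, genes)) > 0 &&
      length(intersect(query$down, genes)) > 0 &&
      all(is.finite(drug_matrix[, d]))
  }, logical(1))
  if (any(!usable)) {
    iscreen_log("rank_aggregate: excluded %d drug(s) without query overlap or with non-finite values",
                sum(!usable))
  }
  drugs <- drugs[usable]
  score_mat <- matrix(NA_real_, nrow = length(drugs), ncol = length(methods),
                      dimnames = list(drugs, methods))
  raw <- list()
  for (d in drugs) {
    profile <- drug_matrix[, d]
    ranking <- genes[order(-profile, genes)]
    if ("xsum" %in% methods) {
      score_mat[d, "xsum"] <- xsum_score(query$up, query$down, profile,
                                         n_extreme)
    }
    if ("ks" %in% methods) {
      score_mat[d, "ks"] <- ks_connectivity(query$up, query$down, ranking)
    }
    if ("rges" %in% methods) {
      score_mat[d, "rges"] <- rges_score(query$up, query$down, ranking)
    }
  }
  if ("ks" %in% methods) {
    score_mat[, "ks"] <- scale_connectivity(score_mat[, "ks"])
  }
  n_d <- length(drugs)
  rr <- apply(score_mat, 2, function(s) rank(s, ties.method = "average") / n_d)
  q <- apply(rr, 1, stuart_q)
  mean_rr <- rowMeans(rr)
  out <- data.frame(drug = drugs, score_mat, rr_mean = mean_rr, q = q,
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out)[seq_along(methods) + 1] <- methods
  for (m in methods) out[[paste0("rr_", m)]] <- rr[, m]
  ord <- order(out$q, out$rr_mean, out$drug)
  out <- out[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
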