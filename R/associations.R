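#' Covariate-adjusted linear association of a score with an event status
#'
#' Ordinary least squares of a continuous score on a binary functional
#' status plus categorical covariates (cancer type, optionally age). The
#' covariate reference level is the most frequent category. Returns the
#' status slope and its two-sided t-test p-value.
#'
#' @param y Numeric response (signature score or feature abundance).
#' @param status Binary 0/1 vector.
#' @param cancer_type Character/factor covariate (optional).
#' @param age Numeric covariate (optional).
#' @param min_events Minimum members required in each status class
#'   (default 5).
#' @return List with `coefficient`, `p`, `n`, and `flag`
#'   (`"ok"`/`"insufficient_events"`/`"constant_response"`).
#' @export
fit_linear_association <- function(y, status, cancer_type = NULL, age = NULL,
                                   min_events = 5) {
  keep <- !is.na(y) & !is.na(status)
  if (!is.null(cancer_type)) keep <- keep & !is.na(cancer_type)
  if (!is.null(age)) keep <- keep & !is.na(age)
  y <- y[keep]; status <- status[keep]
  n <- length(y)
  tab <- table(factor(status, levels = c(0, 1)))
  if (any(tab < min_events)) {
    return(list(coefficient = NA_real_, p = NA_real_, n = n,
                flag = "insufficient_events"))
  }
  if (stats::sd(y) == 0) {
    return(list(coefficient = 0, p = 1, n = n, flag = "constant_response"))
  }
  dat <- data.frame(y = y, status = status)
  form <- y ~ status
  if (!is.null(cancer_type)) {
    ct <- factor(cancer_type[keep])
    ct <- stats::relevel(ct, ref = names(which.max(table(ct))))
    dat$cancer_type <- ct
    if (nlevels(droplevels(ct)) > 1) form <- stats::update(form, . ~ . + cancer_type)
  }
  if (!is.null(age)) {
    dat$age <- age[keep]
    form <- stats::update(form, . ~ . + age)
  }
  fit <- stats::lm(form, data = dat)
  cf <- summary(fit)$coefficients
  list(coefficient = unname(cf["status", "Estimate"]),
       p = unname(cf["status", "Pr(>|t|)"]), n = n, flag = "ok")
}

#' Benjamini-Hochberg adjustment with missing-value passthrough
#'
#' Step-up FDR adjustment within one declared test family. `NA` entries
#' are ignored for ranking and returned as `NA` in place.
#'
#' @param pvals Numeric vector of p-values in [0, 1] (NA allowed).
#' @return Adjusted p-values, same order and length as the input.
#' @export
bh_adjust <- function(pvals) {
  assert_prob(pvals, "p-values", allow_na = TRUE)
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Association screen of catalog genes against signature scores
#'
#' For every catalog gene and every signature column, fits
#' [fit_linear_association()] of the score on the gene's inactivation
#' status, adjusting for cancer type; BH adjustment is applied across the
#' full gene-by-signature family.
#'
#' @param scores data.frame from [signature_scores()] (samples x signatures).
#' @param status A `status_matrix` (genes x samples).
#' @param cancer_type Per-sample covariate vector aligned with the score rows.
#' @param min_events Passed through to the per-test fit.
#' @return data.frame: gene, target, target_class, coefficient, p, adj_p,
#'   n_samples, flag.
#' @export
associate_signatures <- function(scores, status, cancer_type,
                                 min_events = 5) {
  stopifnot(nrow(scores) == ncol(status))
  rows <- list()
  for (g in rownames(status)) {
    for (sig in colnames(scores)) {
      fit <- fit_linear_association(scores[[sig]], status[g, ],
                                    cancer_type = cancer_type,
                                    min_events = min_events)
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, target = sig, target_class = "signature",
        coefficient = fit$coefficient, p = fit$p,
        n_samples = fit$n, flag = fit$flag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[, c("gene", "target", "target_class", "coefficient", "p", "adj_p",
          "n_samples", "flag")]
}

#' Filter the regulator catalog down to functional genes
#'
#' A sensitizer is retained when its inactivation is significantly
#' negatively associated (adj_p < alpha and coefficient < 0) with all
#' three tumor-immunity signatures; a resistor when all three
#' associations are significantly positive. Genes missing any signature
#' record are excluded and logged.
#'
#' @param assoc data.frame from [associate_signatures()].
#' @param catalog Regulator catalog from [build_catalog()].
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @param signatures Required signature names (default immune, CYT, MHC).
#' @return The catalog subset of functional regulators.
#' @export
filter_functional_regulators <- function(assoc, catalog, alpha = 0.05,
                                         signatures = c("immune", "CYT", "MHC")) {
  keep <- vapply(seq_len(nrow(catalog)), function(i) {
    g <- catalog$gene[i]
    sub <- assoc[assoc$gene == g & assoc$target %in% signatures, , drop = FALSE]
    if (nrow(sub) < length(signatures) || anyNA(sub$adj_p) || anyNA(sub$coefficient)) {
      if (nrow(sub) < length(signatures)) {
        iscreen_log("filter_functional_regulators: %s lacks signature records, excluded", g)
      }
      return(FALSE)
    }
    sig <- sub$adj_p < alpha
    if (catalog$role[i] == "sensitizer") all(sig & sub$coefficient < 0)
    else all(sig & sub$coefficient > 0)
  }, logical(1))
  out <- catalog[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Immune-subtype-specific event detection by logistic regression
#'
#' For each gene and subtype, a one-vs-rest logistic regression of the
#' gene's event status on subtype membership. Genes are flagged
#' subtype-specific when the BH-adjusted p (family = all gene x subtype
#' tests) is below `alpha` and the log2 odds ratio exceeds `lor_cut`.
#' Perfect separation yields a flagged record with missing p rather than
#' an infinite estimate.
#'
#' @param status Binary status matrix (genes x samples).
#' @param subtypes Per-sample subtype labels (C1..C6; NA samples dropped).
#' @param alpha Significance threshold (default 0.05).
#' @param lor_cut log2 odds-ratio threshold (default 1.5).
#' @param min_events Minimum events per gene overall (default 5).
#' @return data.frame: gene, subtype, log2_or, p, adj_p, specific, flag.
#' @export
subtype_specific_genes <- function(status, subtypes, alpha = 0.05,
                                   lor_cut = 1.5, min_events = 5) {
  keep <- !is.na(subtypes)
  status <- status[, keep, drop = FALSE]
  subtypes <- subtypes[keep]
  rows <- list()
  for (g in rownames(status)) {
    ev <- status[g, ]
    if (sum(ev) < min_events) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, subtype = NA_character_, log2_or = NA_real_, p = NA_real_,
        flag = "insufficient_events", stringsAsFactors = FALSE)
      next
    }
    for (st in sort(unique(subtypes))) {
      member <- as.integer(subtypes == st)
      fit <- suppressWarnings(
        stats::glm(ev ~ member, family = stats::binomial()))
      cf <- summary(fit)$coefficients
      sep <- !fit$converged || any(abs(stats::coef(fit)) > 15) ||
        cf["member", "Std. Error"] > 100
      if (sep) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, subtype = st, log2_or = NA_real_, p = NA_real_,
          flag = "separation", stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, subtype = st,
          log2_or = unname(cf["member", "Estimate"]) / log(2),
          p = unname(cf["member", "Pr(>|z|)"]),
          flag = "ok", stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$specific <- !is.na(out$adj_p) & out$adj_p < alpha &
    !is.na(out$log2_or) & out$log2_or > lor_cut
  out[, c("gene", "subtype", "log2_or", "p", "adj_p", "specific", "flag")]
}

#' Association screen of catalog genes against immune features per cancer type
#'
#' Within each cancer type separately, fits the linear association of
#' each feature's abundance on each gene's event status. BH adjustment
#' spans the whole gene x feature x cancer-type family.
#'
#' @param abundance Samples-by-features matrix from [feature_abundance()]
#'   (carries feature polarity).
#' @param status Binary status matrix (genes x samples).
#' @param cancer_type Per-sample labels.
#' @param min_events Per-stratum minimum class size (default 5).
#' @return data.frame: gene, target (feature), polarity, cancer_type,
#'   coefficient, p, adj_p, flag.
#' @export
associate_features <- function(abundance, status, cancer_type,
                               min_events = 5) {
  polarity <- attr(abundance, "polarity")
  rows <- list()
  for (ct in unique(cancer_type)) {
    idx <- which(cancer_type == ct)
    for (g in rownames(status)) {
      ev <- status[g, idx]
      for (f in colnames(abundance)) {
        fit <- fit_linear_association(abundance[idx, f], ev,
                                      min_events = min_events)
        rows[[length(rows) + 1]] <- data.frame(
          gene = g, target = f, polarity = unname(polarity[f]),
          cancer_type = ct, coefficient = fit$coefficient, p = fit$p,
          flag = fit$flag, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out
}

#' Count sensitizer-/resistor-related features per gene
#'
#' An S-related feature of a sensitizer is an anti-tumor feature whose
#' abundance drops upon the gene's inactivation (significant negative
#' coefficient) or a pro-tumor feature that rises (significant positive
#' coefficient); R-related features mirror the signs. Counts are taken
#' within each cancer type and summed.
#'
#' @param assoc data.frame from [associate_features()].
#' @param catalog Regulator catalog (gene + role).
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @return data.frame: gene, role, n_related.
#' @export
count_related_features <- function(assoc, catalog, alpha = 0.05) {
  counts <- vapply(seq_len(nrow(catalog)), function(i) {
    g <- catalog$gene[i]
    role <- catalog$role[i]
    sub <- assoc[assoc$gene == g & !is.na(assoc$adj_p) &
                   assoc$adj_p < alpha, , drop = FALSE]
    if (nrow(sub) == 0) return(0L)
    if (role == "sensitizer") {
      hit <- (sub$polarity == "anti_tumor" & sub$coefficient < 0) |
             (sub$polarity == "pro_tumor" & sub$coefficient > 0)
    } else {
      hit <- (sub$polarity == "anti_tumor" & sub$coefficient > 0) |
             (sub$polarity == "pro_tumor" & sub$coefficient < 0)
    }
    sum(hit)
  }, integer(1))
  data.frame(gene = catalog$gene, role = catalog$role, n_related = counts,
             stringsAsFactors = FALSE)
}

#' Oncogene/TSG regulatory network over the regulator catalog
#'
#' For every (regulator, driver) pair, compares the regulator's log
#' expression between samples with and without the driver event
#' (OG activation or TSG inactivation): lfc = mean(event) -
#' mean(non-event); two-sided Wilcoxon rank-sum p, BH across all pairs.
#' A sensitizer-driver edge requires significant down-regulation
#' (adj_p < alpha, lfc < -lfc_cut); a resistor-driver edge significant
#' up-regulation (lfc > +lfc_cut).
#'
#' @param expr Log-scale expression matrix containing the regulators.
#' @param driver_status Binary status matrix for drivers (rows = drivers);
#'   build OGs with kind "activation" and TSGs with "inactivation" and
#'   rbind them.
#' @param driver_class Named character vector ("OG"/"TSG") per driver row.
#' @param catalog Regulator catalog (gene + role).
#' @param alpha Adjusted-significance threshold (default 0.05).
#' @param lfc_cut Absolute log-fold-change threshold (default 0.25).
#' @param min_events Minimum event/non-event group size (default 5).
#' @return data.frame of edges: regulator, role, driver, driver_class,
#'   lfc, p, adj_p, edge (logical).
#' @export
og_tsg_network <- function(expr, driver_status, driver_class, catalog,
                           alpha = 0.05, lfc_cut = 0.25, min_events = 5) {
  samples <- colnames(expr)
  stopifnot(identical(samples, colnames(driver_status)))
  rows <- list()
  for (i in seq_len(nrow(catalog))) {
    reg <- catalog$gene[i]
    if (!reg %in% rownames(expr)) next
    x <- expr[reg, ]
    for (d in rownames(driver_status)) {
      ev <- driver_status[d, ] == 1
      if (sum(ev) < min_events || sum(!ev) < min_events) next
      lfc <- mean(x[ev]) - mean(x[!ev])
      p <- suppressWarnings(
        stats::wilcox.test(x[ev], x[!ev], exact = FALSE)$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        regulator = reg, role = catalog$role[i], driver = d,
        driver_class = unname(driver_class[d]), lfc = lfc, p = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(regulator = character(), role = character(),
                      driver = character(), driver_class = character(),
                      lfc = numeric(), p = numeric(), adj_p = numeric(),
                      edge = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out$edge <- !is.na(out$adj_p) & out$adj_p < alpha &
    ifelse(out$role == "sensitizer", out$lfc < -lfc_cut, out$lfc > lfc_cut)
  out
}

#' Select proliferation-independent genes from dependency scores
#'
#' Averages each gene's essentiality (CERES-like) score across cell
#' lines and keeps genes whose mean lies inside `[low, high]`
#' (inclusive); near-zero essentiality means knocking the gene out does
#' not by itself change proliferation.
#'
#' @param dep Genes-by-cell-lines numeric matrix.
#' @param low,high Interval bounds (defaults -0.25, 0.25).
#' @return Character vector of retained genes.
#' @export
proliferation_independent <- function(dep, low = -0.25, high = 0.25) {
  stopifnot(low < high)
  mu <- rowMeans(dep, na.rm = TRUE)
  names(mu)[mu >= low & mu <= high]
}
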