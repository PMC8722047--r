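#' Construct a CTIS gene panel
#'
#' The tumor-intrinsic immune score panel: sensitizer genes whose mean
#' expression enters positively and resistor genes entering negatively.
#' The default panel is the published six-gene set.
#'
#' @param sensitizers Character vector (default JAK1, NFKB2, PPP6C,
#'   TNFRSF1B).
#' @param resistors Character vector (default PIGM, TPR).
#' @return List of class `ctis_panel`.
#' @export
ctis_panel <- function(sensitizers = c("JAK1", "NFKB2", "PPP6C", "TNFRSF1B"),
                       resistors = c("PIGM", "TPR")) {
  stopifnot(length(sensitizers) > 0, length(resistors) > 0)
  if (length(intersect(sensitizers, resistors)) > 0) {
    stop("panel halves must be disjoint", call. = FALSE)
  }
  structure(list(sensitizers = sensitizers, resistors = resistors),
            class = "ctis_panel")
}

#' CRISPR screening-based tumor-intrinsic immune score (CTIS)
#'
#' Mean expression of the sensitizer panel minus mean expression of the
#' resistor panel; higher CTIS indicates a stronger anti-tumor immune
#' state. By default each panel gene is z-scored across the cohort first
#' so the difference is comparable across cohorts; set `scale = "raw"`
#' to use the expression values as given.
#'
#' @param expr Genes-by-samples expression matrix (log scale).
#' @param panel A [ctis_panel()].
#' @param scale `"z"` (default) or `"raw"`.
#' @return Named numeric vector of per-sample scores.
#' @export
ctis_score <- function(expr, panel = ctis_panel(), scale = c("z", "raw")) {
  scale <- match.arg(scale)
  genes <- c(panel$sensitizers, panel$resistors)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    stop(sprintf("panel gene(s) missing from expression: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  m <- expr[genes, , drop = FALSE]
  if (scale == "z") {
    m <- standardize_expression(m, rep("cohort", ncol(m)))
  }
  colMeans(m[panel$sensitizers, , drop = FALSE]) -
    colMeans(m[panel$resistors, , drop = FALSE])
}

#' Cox proportional-hazards screen of one predictor
#'
#' Partial-likelihood fit (Efron tie handling) of survival on a
#' per-sample predictor (binary status or continuous score), adjusting
#' for cancer type and age when supplied. Non-convergence and monotone
#' likelihood are reported as flags, never as silent infinities.
#'
#' @param predictor Numeric per-sample vector.
#' @param survival_df data.frame with columns `time`, `event`, and
#'   optionally `age`, `cancer_type`.
#' @param covariates Character subset of c("age", "cancer_type") to adjust
#'   for (default: those present in `survival_df`).
#' @param min_events Minimum number of observed events (default 5).
#' @param ties Tie method for the partial likelihood (default "efron").
#' @return List: `hr`, `log_hr`, `ci_lower`, `ci_upper`, `p`, `n`,
#'   `n_events`, `flag`.
#' @export
cox_screen <- function(predictor, survival_df,
                       covariates = intersect(c("age", "cancer_type"),
                                              names(survival_df)),
                       min_events = 5, ties = "efron") {
  stopifnot(all(c("time", "event") %in% names(survival_df)),
            length(predictor) == nrow(survival_df))
  keep <- !is.na(predictor) & !is.na(survival_df$time) &
    !is.na(survival_df$event)
  dat <- survival_df[keep, , drop = FALSE]
  dat$predictor <- predictor[keep]
  if (sum(dat$event) < min_events) {
    return(list(hr = NA_real_, log_hr = NA_real_, ci_lower = NA_real_,
                ci_upper = NA_real_, p = NA_real_, n = nrow(dat),
                n_events = sum(dat$event), flag = "insufficient_events"))
  }
  if (stats::sd(dat$predictor) == 0) {
    stop("predictor is constant; Cox screen undefined", call. = FALSE)
  }
  form <- survival::Surv(time, event) ~ predictor
  for (cv in covariates) {
    if (cv == "cancer_type" && length(unique(dat$cancer_type)) < 2) next
    form <- stats::update(form, stats::as.formula(paste(". ~ . +", cv)))
  }
  fit <- tryCatch(
    survival::coxph(form, data = dat, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) structure(list(msg = conditionMessage(w)),
                                    class = "cox_flagged"))
  if (inherits(fit, "cox_flagged")) {
    flag <- if (grepl("infinite|converge", fit$msg, ignore.case = TRUE))
      "non_convergence" else "warned"
    refit <- suppressWarnings(
      survival::coxph(form, data = dat, ties = ties,
                      control = survival::coxph.control(iter.max = 100)))
    cf <- summary(refit)$coefficients
    ci <- suppressMessages(stats::confint(refit))
    return(list(hr = unname(exp(cf["predictor", "coef"])),
                log_hr = unname(cf["predictor", "coef"]),
                ci_lower = exp(ci["predictor", 1]),
                ci_upper = exp(ci["predictor", 2]),
                p = unname(cf["predictor", "Pr(>|z|)"]),
                n = nrow(dat), n_events = sum(dat$event), flag = flag))
  }
  cf <- summary(fit)$coefficients
  ci <- suppressMessages(stats::confint(fit))
  list(hr = unname(exp(cf["predictor", "coef"])),
       log_hr = unname(cf["predictor", "coef"]),
       ci_lower = unname(exp(ci["predictor", 1])),
       ci_upper = unname(exp(ci["predictor", 2])),
       p = unname(cf["predictor", "Pr(>|z|)"]),
       n = nrow(dat), n_events = sum(dat$event), flag = "ok")
}

#' Log-rank (Mantel-Cox) test across groups
#'
#' @param time,event Survival time and event indicator vectors.
#' @param group Group labels (>= 2 non-empty groups required).
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("log-rank test requires at least two non-empty groups", call. = FALSE)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Harrell concordance index
#'
#' Fraction of comparable subject pairs whose score ordering matches
#' their survival ordering; higher score is taken to predict longer
#' survival. A pair is comparable when the earlier time carries an event
#' and the times differ. Score ties count 0.5.
#'
#' @param score Numeric per-sample score.
#' @param time,event Survival data.
#' @return C-index in [0, 1].
#' @export
concordance_index <- function(score, time, event) {
  keep <- !is.na(score) & !is.na(time) & !is.na(event)
  score <- score[keep]; time <- time[keep]; event <- event[keep]
  n <- length(score)
  conc <- 0; comp <- 0
  for (i in seq_len(n)) {
    if (!event[i]) next
    j <- which(time > time[i])
    if (length(j) == 0) next
    comp <- comp + length(j)
    conc <- conc + sum(score[i] < score[j]) + 0.5 * sum(score[i] == score[j])
  }
  if (comp == 0) stop("no comparable pairs", call. = FALSE)
  conc / comp
}

#' ROC AUC by the Mann-Whitney formulation
#'
#' P(score of a positive exceeds score of a negative) + 0.5 P(tie).
#'
#' @param score Numeric vector.
#' @param label Binary responder labels (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(score, label) {
  label <- as.integer(as.logical(label))
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  n_pos <- sum(label == 1); n_neg <- sum(label == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("roc_auc requires both classes", call. = FALSE)
  }
  r <- rank(score)
  (sum(r[label == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Greedy cross-validated C-index panel selection
#'
#' A documented substitute for minimal-depth random-survival-forest gene
#' selection: forward selection over candidate genes, at each step adding
#' the gene (with its catalog role fixing its CTIS sign) that maximizes
#' the k-fold cross-validated C-index of the resulting score. The
#' published six-gene panel remains the package default, so downstream
#' stages do not depend on this selector.
#'
#' @param candidates data.frame with columns `gene`, `role`.
#' @param expr Genes-by-samples expression matrix.
#' @param survival_df data.frame with `time` and `event`, rows aligned to
#'   the expression columns.
#' @param k Panel size to select.
#' @param n_folds Cross-validation folds (default 5).
#' @param seed Fold-assignment seed (default 1).
#' @return A [ctis_panel()] plus attribute `cv_cindex` (the selection
#'   path of CV C-index values).
#' @export
select_panel_greedy <- function(candidates, expr, survival_df, k,
                                n_folds = 5, seed = 1) {
  stopifnot(nrow(candidates) >= k)
  candidates <- candidates[candidates$gene %in% rownames(expr), , drop = FALSE]
  if (nrow(candidates) < k) {
    stop("fewer candidates present in expression than the requested panel size",
         call. = FALSE)
  }
  n <- ncol(expr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "panel_folds"))
  folds <- sample(rep(seq_len(n_folds), length.out = n))
  z <- standardize_expression(expr[candidates$gene, , drop = FALSE],
                              rep("cohort", n))
  signs <- ifelse(candidates$role == "sensitizer", 1, -1)
  names(signs) <- candidates$gene
  cv_cindex_of <- function(genes) {
    sc <- colSums(z[genes, , drop = FALSE] * signs[genes]) / length(genes)
    vals <- vapply(seq_len(n_folds), function(f) {
      idx <- folds == f
      tryCatch(concordance_index(sc[idx], survival_df$time[idx],
                                 survival_df$event[idx]),
               error = function(e) NA_real_)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  chosen <- character()
  path <- numeric()
  pool <- candidates$gene
  while (length(chosen) < k) {
    scores <- vapply(pool, function(g) cv_cindex_of(c(chosen, g)), numeric(1))
    best <- pool[order(-scores, pool)][1]
    chosen <- c(chosen, best)
    path <- c(path, max(scores, na.rm = TRUE))
    pool <- setdiff(pool, best)
  }
  roles <- candidates$role[match(chosen, candidates$gene)]
  sens <- chosen[roles == "sensitizer"]
  res <- chosen[roles == "resistor"]
  if (length(sens) == 0 || length(res) == 0) {
    # CTIS needs both halves; backfill the empty half with the best
    # remaining candidate of that role.
    missing_role <- if (length(sens) == 0) "sensitizer" else "resistor"
    fill_pool <- candidates$gene[candidates$role == missing_role]
    if (length(fill_pool) == 0) {
      stop("candidate pool lacks genes of role ", missing_role, call. = FALSE)
    }
    fill <- fill_pool[order(-vapply(fill_pool, function(g)
      cv_cindex_of(c(chosen, g)), numeric(1)), fill_pool)][1]
    if (missing_role == "sensitizer") sens <- fill else res <- fill
  }
  structure(ctis_panel(sens, res), cv_cindex = path)
}

# Save/restore the global RNG state so selectors do not perturb user code.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
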