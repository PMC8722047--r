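# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition by direct enumeration, never
# calling the implementation under test.

# BH step-up: p * n / rank with enforced monotonicity from the largest p.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- pmin(1, rev(cummin(rev(adj))))
  out <- numeric(n)
  out[o] <- adj
  out
}

# KS enrichment by scanning every prefix of the ranked list.
oracle_ks <- function(tag_positions, n) {
  t <- length(tag_positions)
  best_a <- -Inf
  best_b <- -Inf
  for (j in seq_len(t)) {
    best_a <- max(best_a, j / t - tag_positions[j] / n)
    best_b <- max(best_b, tag_positions[j] / n - (j - 1) / t)
  }
  if (best_a >= best_b) best_a else -best_b
}

# ssGSEA walk re-derived step by step with explicit loops.
oracle_ssgsea <- function(expr, gene_set, alpha) {
  genes <- names(expr)
  ord <- order(-expr, genes)
  ranked <- genes[ord]
  n <- length(ranked)
  in_set <- ranked %in% gene_set
  w_total <- 0
  for (i in seq_len(n)) if (in_set[i]) w_total <- w_total + (n - i + 1)^alpha
  n_out <- sum(!in_set)
  score <- 0
  p_in <- 0
  p_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + (n - i + 1)^alpha / w_total
    else if (n_out > 0) p_out <- p_out + 1 / n_out
    score <- score + (p_in - p_out)
  }
  score
}

# Concordance by exhaustive pair enumeration (higher score = longer life).
oracle_cindex <- function(score, time, event) {
  conc <- 0
  comp <- 0
  n <- length(score)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (event[i] == 1 && time[i] < time[j]) {
        comp <- comp + 1
        if (score[i] < score[j]) conc <- conc + 1
        else if (score[i] == score[j]) conc <- conc + 0.5
      }
    }
  }
  conc / comp
}

# AUC by exhaustive positive-negative pair count.
oracle_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  s <- 0
  for (a in pos) for (b in neg) {
    s <- s + (a > b) + 0.5 * (a == b)
  }
  s / (length(pos) * length(neg))
}

# Monte-Carlo joint probability that sorted uniforms fall below r.
# Rows are sorted with a vectorized compare-exchange network (N <= 5).
oracle_stuart_mc <- function(r, n_draws = 1e6) {
  n <- length(r)
  u <- matrix(stats::runif(n_draws * n), ncol = n)
  for (pass in seq_len(n)) {
    for (k in seq_len(n - 1)) {
      lo <- pmin(u[, k], u[, k + 1])
      hi <- pmax(u[, k], u[, k + 1])
      u[, k] <- lo
      u[, k + 1] <- hi
    }
  }
  ok <- rep(TRUE, n_draws)
  for (k in seq_len(n)) ok <- ok & (u[, k] <= sort(r)[k])
  mean(ok)
}

# Clause-by-clause functional-status evaluator (mirrors the printed rules,
# written independently of the package's vectorized path).
oracle_status <- function(kind, has_deleterious, gistic, z) {
  if (kind == "inactivation") {
    has_deleterious || gistic == -2 || z <= -2
  } else {
    gistic == 2 || z >= 2
  }
}

# Tiny deterministic cohort used by several status/scoring tests.
toy_cohort <- function() {
  expr <- rbind(
    GZMA = c(3, 4, 5, 6),
    PRF1 = c(2, 3, 4, 5),
    TP53 = c(5, 5, 1, 5),
    MYC  = c(2, 2, 2, 9))
  colnames(expr) <- paste0("s", 1:4)
  muts <- data.frame(
    sample = c("s1", "s2"), gene = c("TP53", "TP53"),
    consequence = c("frameshift", "missense"),
    damage_prob = c(NA, 0.3), stringsAsFactors = FALSE)
  cnv <- matrix(0L, nrow = 4, ncol = 4, dimnames = dimnames(expr))
  cnv["MYC", "s4"] <- 2L
  cnv["TP53", "s3"] <- -2L
  ann <- data.frame(sample = paste0("s", 1:4), cancer_type = "skin",
                    stringsAsFactors = FALSE)
  omics_cohort(expr, muts, cnv, ann, z_stratify = "cohort")
}
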