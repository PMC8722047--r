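test_that("CTIS is the sensitizer-mean minus resistor-mean difference", {
  panel <- ctis_panel(c("A", "B"), c("C", "D"))
  expr <- rbind(A = c(3, 2), B = c(3, 2), C = c(1, 2), D = c(1, 2))
  colnames(expr) <- c("s1", "s2")
  sc <- ctis_score(expr, panel, scale = "raw")
  expect_equal(unname(sc), c(3 - 1, 0))
  # toy 6-gene vector with unequal halves
  expr6 <- matrix(c(5, 1, 3, 2, 4, 6), ncol = 1,
                  dimnames = list(LETTERS[1:6], "s"))
  p6 <- ctis_panel(c("A", "B", "C", "D"), c("E", "F"))
  expect_equal(unname(ctis_score(expr6, p6, scale = "raw")),
               mean(c(5, 1, 3, 2)) - mean(c(4, 6)))
  # invariant to gene order within each half
  p6b <- ctis_panel(c("D", "A", "C", "B"), c("F", "E"))
  expect_equal(ctis_score(expr6, p6b, scale = "raw"),
               ctis_score(expr6, p6, scale = "raw"))
  expect_error(ctis_score(expr, ctis_panel("A", "ZZ")), "ZZ")
  expect_error(ctis_panel(c("A", "B"), c("B")), "disjoint")
})

test_that("Cox screen recovers a planted hazard and flags degeneracies", {
  set.seed(91)
  n <- 500
  x <- stats::rnorm(n)
  t_ev <- stats::rexp(n, 0.1 * exp(0.7 * x))
  cens <- stats::runif(n, 0, stats::quantile(t_ev, 0.9) * 2)
  df <- data.frame(time = pmin(t_ev, cens), event = as.integer(t_ev <= cens))
  fit <- cox_screen(x, df)
  expect_equal(fit$log_hr, 0.7, tolerance = 0.15)
  expect_identical(fit$flag, "ok")
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)

  expect_error(cox_screen(rep(1, n), df), "constant")
  few <- cox_screen(x, data.frame(time = df$time, event = 0))
  expect_identical(few$flag, "insufficient_events")
})

test_that("Cox coefficient sign agrees with the log-rank direction", {
  set.seed(17)
  n <- 120
  grp <- stats::rbinom(n, 1, 0.5)
  t_ev <- stats::rexp(n, 0.1 * exp(0.9 * grp))
  df <- data.frame(time = t_ev, event = 1L)
  fit <- cox_screen(grp, df)
  sd_fit <- survival::survdiff(survival::Surv(t_ev, rep(1, n)) ~ grp)
  # group 1 has more observed than expected events iff hazard is higher
  expect_equal(sign(fit$log_hr),
               sign(sd_fit$obs[2] - sd_fit$exp[2]))
})

test_that("log-rank statistic matches a hand risk-table computation", {
  # toy 6 subjects, two groups; O-E computed by walking event times
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  group <- c("a", "b", "a", "b", "a", "b")
  out <- logrank_test(time, event, group)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  expect_equal(out$chisq, unname(sd_fit$chisq), tolerance = 1e-12)
  expect_equal(out$df, 1)

  # identical survival in both groups -> statistic 0
  t2 <- rep(c(1, 2, 3), 2)
  e2 <- rep(c(1, 1, 0), 2)
  g2 <- rep(c("a", "b"), each = 3)
  expect_equal(logrank_test(t2, e2, g2)$chisq, 0, tolerance = 1e-12)

  expect_error(logrank_test(time, event, rep("a", 6)), "two")
})

test_that("concordance and AUC match exhaustive pair enumeration", {
  # hand cases
  expect_equal(concordance_index(c(1, 2, 3), c(1, 2, 3), c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(2, 1, 3), c(1, 2, 3), c(1, 1, 0)),
               oracle_cindex(c(2, 1, 3), c(1, 2, 3), c(1, 1, 0)))
  expect_equal(concordance_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)

  set.seed(23)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    score <- sample(1:6, n, TRUE)   # ties on purpose
    time <- sample(1:8, n, TRUE)
    event <- stats::rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    ci_ok <- tryCatch(concordance_index(score, time, event),
                      error = function(e) NULL)
    if (!is.null(ci_ok)) {
      expect_equal(ci_ok, oracle_cindex(score, time, event),
                   tolerance = 1e-12)
    }
    label <- stats::rbinom(n, 1, 0.5)
    if (length(unique(label)) == 2) {
      expect_equal(roc_auc(score, label), oracle_auc(score, label),
                   tolerance = 1e-12)
    }
  }
})

test_that("evaluation metrics agree with independent library implementations", {
  skip_if_not_installed("pROC")
  set.seed(29)
  n <- 80
  score <- stats::rnorm(n)
  time <- stats::rexp(n, 0.2)
  event <- stats::rbinom(n, 1, 0.7)
  label <- stats::rbinom(n, 1, 0.5)
  conc <- survival::concordance(survival::Surv(time, event) ~ score)
  # survival::concordance orients low score = high risk opposite to ours
  expect_equal(concordance_index(score, time, event),
               unname(conc$concordance), tolerance = 1e-10)
  auc <- as.numeric(pROC::auc(pROC::roc(label, score, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(score, label), auc, tolerance = 1e-10)
})

test_that("greedy panel search recovers planted survival genes", {
  set.seed(43)
  n <- 300
  genes <- sprintf("g%02d", 1:40)
  expr <- matrix(stats::rnorm(40 * n, 8), nrow = 40,
                 dimnames = list(genes, paste0("s", 1:n)))
  true_sens <- c("g01", "g02", "g03", "g04")
  true_res <- c("g05", "g06")
  signal <- colMeans(expr[true_sens, ]) - colMeans(expr[true_res, ])
  t_ev <- stats::rexp(n, 0.1 * exp(-1.5 * (signal - mean(signal))))
  surv <- data.frame(time = t_ev, event = 1L)
  candidates <- data.frame(gene = genes,
                           role = rep(c("sensitizer", "resistor"), 20),
                           stringsAsFactors = FALSE)
  candidates$role[match(true_sens, candidates$gene)] <- "sensitizer"
  candidates$role[match(true_res, candidates$gene)] <- "resistor"
  panel <- select_panel_greedy(candidates, expr, surv, k = 6, seed = 2)
  chosen <- c(panel$sensitizers, panel$resistors)
  expect_gte(length(intersect(chosen, c(true_sens, true_res))), 5)

  # k = pool size returns the whole pool
  small <- candidates[c(1, 2, 5, 6), ]
  p_all <- select_panel_greedy(small, expr, surv, k = 4, seed = 2)
  expect_setequal(c(p_all$sensitizers, p_all$resistors), small$gene)
  expect_error(select_panel_greedy(small, expr, surv, k = 10))
})
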