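test_that("BH adjustment matches the hand rule and the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.1, NA, 0.01)), c(0.1, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(77)
  for (i in 1:1000) {
    p <- stats::runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("linear association recovers a planted effect and matches OLS algebra", {
  set.seed(21)
  n <- 300
  ct <- sample(c("skin", "breast", "colon"), n, TRUE)
  offs <- c(skin = 0, breast = 1.5, colon = -1)
  status <- stats::rbinom(n, 1, 0.3)
  y <- -0.8 * status + offs[ct] + stats::rnorm(n, 0, 0.1)
  fit <- fit_linear_association(y, status, cancer_type = ct)
  expect_equal(fit$coefficient, -0.8, tolerance = 0.1)
  expect_lt(fit$p, 1e-10)

  # closed-form normal equations on the same design
  X <- stats::model.matrix(~ status + relevel(factor(ct),
                                              names(which.max(table(ct)))))
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$coefficient, as.numeric(beta["status", 1]),
               tolerance = 1e-8)

  # degenerate contracts
  expect_equal(fit_linear_association(rep(2, 50), stats::rbinom(50, 1, 0.5))[
    c("coefficient", "p")], list(coefficient = 0, p = 1))
  few <- fit_linear_association(stats::rnorm(50), rep(0, 50))
  expect_identical(few$flag, "insufficient_events")
})

test_that("null linear associations stay calibrated", {
  set.seed(31)
  ok <- 0
  for (s in 1:40) {
    n <- 300
    status <- stats::rbinom(n, 1, 0.3)
    y <- stats::rnorm(n)
    fit <- fit_linear_association(y, status)
    se <- abs(fit$coefficient) /
      abs(stats::qt(fit$p / 2, df = n - 2))
    ok <- ok + (abs(fit$coefficient) < 3 * se ||
                  fit$p > 0.0027)
  }
  expect_gte(ok / 40, 0.95)
})

test_that("the three-signature filter keeps only consistently signed genes", {
  catalog <- data.frame(gene = c("S1", "S2", "R1", "R2", "S3"),
                        role = c("sensitizer", "sensitizer", "resistor",
                                 "resistor", "sensitizer"),
                        stringsAsFactors = FALSE)
  assoc <- rbind(
    data.frame(gene = "S1", target = c("immune", "CYT", "MHC"),
               coefficient = c(-0.3, -0.2, -0.4), adj_p = 0.01),
    data.frame(gene = "S2", target = c("immune", "CYT", "MHC"),
               coefficient = c(-0.3, +0.2, -0.4), adj_p = 0.01),
    data.frame(gene = "R1", target = c("immune", "CYT", "MHC"),
               coefficient = c(0.5, 0.2, 0.1), adj_p = c(0.01, 0.01, 0.06)),
    data.frame(gene = "R2", target = c("immune", "CYT", "MHC"),
               coefficient = c(0.5, 0.2, 0.1), adj_p = 0.001),
    data.frame(gene = "S3", target = c("immune", "CYT"),
               coefficient = c(-0.5, -0.2), adj_p = 0.001))
  out <- suppressMessages(filter_functional_regulators(assoc, catalog))
  expect_setequal(out$gene, c("S1", "R2"))   # S2 sign flip, R1 one ns, S3 incomplete
})

test_that("subtype-specific detection flags a planted enrichment only", {
  set.seed(55)
  n <- 600
  subtypes <- sample(paste0("C", 1:6), n, TRUE)
  planted <- stats::rbinom(n, 1, ifelse(subtypes == "C5", 0.4, 0.05))
  uniform <- stats::rbinom(n, 1, 0.15)
  none <- rep(0L, n)
  status <- rbind(planted = planted, uniform = uniform, none = none)
  out <- subtype_specific_genes(status, subtypes)
  hit <- out[out$gene == "planted" & out$subtype == "C5", ]
  expect_true(hit$specific)
  # true log2 OR = log2((0.4/0.6)/(0.05/0.95)) ~= 3.66
  expect_equal(hit$log2_or, 3.66, tolerance = 0.8)
  expect_false(any(out$specific[out$gene == "uniform"]))
  expect_identical(out$flag[out$gene == "none"], "insufficient_events")
})

test_that("related-feature counts follow the polarity/sign rules and add up", {
  catalog <- data.frame(gene = c("S1", "R1"), role = c("sensitizer", "resistor"),
                        stringsAsFactors = FALSE)
  assoc <- data.frame(
    gene = c("S1", "S1", "S1", "R1", "R1"),
    target = c("ctl", "tgfb", "nk", "ctl", "tgfb"),
    polarity = c("anti_tumor", "pro_tumor", "anti_tumor",
                 "anti_tumor", "pro_tumor"),
    cancer_type = c("skin", "skin", "skin", "skin", "skin"),
    coefficient = c(-0.5, +0.3, +0.5, +0.4, -0.2),
    adj_p = c(0.01, 0.01, 0.01, 0.01, 0.2))
  out <- count_related_features(assoc, catalog)
  expect_equal(out$n_related[out$gene == "S1"], 2)  # anti&neg + pro&pos
  expect_equal(out$n_related[out$gene == "R1"], 1)  # anti&pos; pro ns

  # additivity over disjoint cancer strata
  assoc2 <- assoc
  assoc2$cancer_type <- "breast"
  both <- rbind(assoc, assoc2)
  out2 <- count_related_features(both, catalog)
  expect_equal(out2$n_related, 2L * out$n_related)
})

test_that("driver network edges need sign, magnitude and significance", {
  set.seed(66)
  n <- 400
  samples <- paste0("s", seq_len(n))
  tsg_ev <- stats::rbinom(n, 1, 0.3)
  og_ev <- stats::rbinom(n, 1, 0.3)
  expr <- rbind(
    SENS = 8 - 0.6 * tsg_ev + stats::rnorm(n, 0, 0.4),
    SENSWEAK = 8 - 0.2 * tsg_ev + stats::rnorm(n, 0, 0.05),
    RES = 8 + 0.6 * og_ev + stats::rnorm(n, 0, 0.4))
  colnames(expr) <- samples
  drivers <- rbind(TSG1 = tsg_ev, OG1 = og_ev)
  colnames(drivers) <- samples
  catalog <- data.frame(gene = c("SENS", "SENSWEAK", "RES"),
                        role = c("sensitizer", "sensitizer", "resistor"),
                        stringsAsFactors = FALSE)
  net <- og_tsg_network(expr, drivers, c(TSG1 = "TSG", OG1 = "OG"), catalog)
  expect_true(net$edge[net$regulator == "SENS" & net$driver == "TSG1"])
  # |lfc| ~ 0.2 < 0.25: significant but below magnitude cut -> no edge
  weak <- net[net$regulator == "SENSWEAK" & net$driver == "TSG1", ]
  expect_lt(weak$adj_p, 0.05)
  expect_false(weak$edge)
  expect_true(net$edge[net$regulator == "RES" & net$driver == "OG1"])
  # a resistor down-regulated edge direction never qualifies
  expect_false(net$edge[net$regulator == "SENS" & net$driver == "OG1"])
})

test_that("proliferation-independence keeps inclusive interval means", {
  dep <- rbind(A = c(-0.1, 0.1, 0), B = c(-0.4, -0.3, -0.2),
               C = c(0.25, 0.25, 0.25), D = c(0.3, 0.2, 0.4))
  kept <- proliferation_independent(dep)
  expect_setequal(kept, c("A", "C"))   # mean 0 kept; 0.25 boundary kept
  expect_false("B" %in% kept)          # mean -0.3 excluded
  expect_false("D" %in% kept)
})
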