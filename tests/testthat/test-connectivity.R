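test_that("KS enrichment matches direct evaluation of both maxima", {
  expect_equal(ks_enrichment(1, 10), 0.9)    # lone tag on top
  expect_equal(ks_enrichment(10, 10), -1)    # lone tag at the bottom
  n <- 7
  expect_equal(ks_enrichment(seq_len(n), n), -1 / n)  # all genes tagged
  expect_error(ks_enrichment(integer(), 10), "empty")
})

test_that("KS enrichment equals brute-force prefix maximization", {
  set.seed(13)
  for (i in 1:1000) {
    n <- sample(2:50, 1)
    t <- sample(1:n, 1)
    pos <- sort(sample(n, t))
    expect_equal(ks_enrichment(pos, n), oracle_ks(pos, n),
                 tolerance = 1e-12)
  }
})

test_that("KS connectivity applies the opposite-sign rule and cohort scaling", {
  ranking <- letters[1:10]
  # up genes on top, down at bottom -> mimicry, strongly positive
  mimic <- ks_connectivity(c("a", "b"), c("i", "j"), ranking)
  expect_gt(mimic, 0)
  # reversal: up at the bottom, down on top -> strongly negative
  reversal <- ks_connectivity(c("i", "j"), c("a", "b"), ranking)
  expect_lt(reversal, 0)
  expect_equal(reversal, -mimic)   # symmetric toy construction
  # same-sign enrichments are zeroed
  both_top <- ks_connectivity(c("a", "b"), c("c", "d"), ranking)
  expect_equal(both_top, 0)
  expect_error(ks_connectivity(c("zz"), c("a"), ranking), "overlap")

  expect_equal(scale_connectivity(c(2, 1, -4, -1, 0)),
               c(1, 0.5, -1, -0.25, 0))

  # an exact reverser attains the cohort minimum in a 3-drug toy
  profiles <- cbind(rev_drug = c(-3, -2, 3, 2, 0),
                    null1 = c(0.1, -0.2, 0.3, -0.1, 0),
                    mim = c(3, 2, -3, -2, 0))
  rownames(profiles) <- c("u1", "u2", "d1", "d2", "x")
  scores <- vapply(colnames(profiles), function(d) {
    rk <- rownames(profiles)[order(-profiles[, d], rownames(profiles))]
    ks_connectivity(c("u1", "u2"), c("d1", "d2"), rk)
  }, numeric(1))
  expect_equal(names(which.min(scores)), "rev_drug")
})

test_that("XSum counts only query genes inside the extreme set", {
  profile <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2, g6 = -3)
  expect_equal(xsum_score("g1", "g6", profile, n_extreme = 2), 6)
  # query genes outside the extremes contribute nothing
  expect_equal(xsum_score("g3", "g4", profile, n_extreme = 1), 0)
  expect_equal(xsum_score(character(), character(), profile), 0)
  # perturbing a non-extreme gene leaves the score unchanged
  p2 <- profile
  p2["g3"] <- 1.4
  expect_equal(xsum_score(c("g1", "g3"), "g6", p2, n_extreme = 1),
               xsum_score(c("g1", "g3"), "g6", profile, n_extreme = 1))
})

test_that("RGES subtracts signed enrichments without zeroing", {
  ranking <- letters[1:10]
  # up at bottom (ES_up < 0), down at top (ES_down > 0): strongly negative
  expect_lt(rges_score(c("i", "j"), c("a", "b"), ranking), 0)
  # symmetric query halves cancel
  expect_equal(rges_score(c("a", "j"), c("a", "j"), ranking), 0)
  # same-sign case is NOT zeroed (contrast with ks_connectivity)
  up <- c("a", "b"); down <- c("c", "d")
  expect_false(rges_score(up, down, ranking) == 0)
})

test_that("Stuart Q follows the order-statistic recursion", {
  expect_equal(stuart_q(0.3), 0.3)
  expect_equal(stuart_q(c(1, 1, 1)), 1)
  expect_equal(stuart_q(c(0.5, 0.5)), 0.25)   # P(both uniforms <= 0.5)
  expect_error(stuart_q(c(0.5, 0)), "\\(0, 1\\]")

  # monotone: decreasing any ratio never increases Q
  set.seed(3)
  for (i in 1:50) {
    r <- stats::runif(sample(2:5, 1), 0.05, 1)
    j <- sample(length(r), 1)
    r2 <- r
    r2[j] <- r2[j] * stats::runif(1)
    expect_lte(stuart_q(r2), stuart_q(r) + 1e-12)
  }
})

test_that("Stuart Q matches Monte-Carlo joint probabilities", {
  set.seed(19)
  for (i in 1:10) {
    n <- sample(2:5, 1)
    r <- stats::runif(n, 0.1, 0.9)
    mc_n <- 2e5
    est <- oracle_stuart_mc(r, mc_n)
    q <- stuart_q(r)
    se <- sqrt(max(est * (1 - est), 1e-12) / mc_n)
    expect_lt(abs(q - est), 3 * se + 1e-6)
  }
})

test_that("phase filtering respects the development-stage ordering", {
  m <- matrix(stats::rnorm(12), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("d", 1:4)))
  ann <- data.frame(drug = paste0("d", 1:4),
                    clinical_phase = c("launched", "phase1", "preclinical",
                                       "phase3"))
  kept <- suppressMessages(filter_drugs_by_phase(m, ann))
  expect_identical(colnames(kept), c("d1", "d4"))
  all_launched <- filter_drugs_by_phase(
    m, data.frame(drug = paste0("d", 1:4), clinical_phase = "launched"))
  expect_identical(all_launched, m)
  expect_warning(
    suppressMessages(filter_drugs_by_phase(
      m, data.frame(drug = paste0("d", 1:4), clinical_phase = "preclinical"))),
    "no drugs")
})

test_that("query assembly removes genes claimed by both sides", {
  q <- build_query_signature(sensitizers = c("A", "B"),
                             resistors = c("C"),
                             tsgs = c("D"), ogs = c("E"),
                             icb_enhancers = c("F"), icb_suppressors = c("G"))
  expect_setequal(q$up, c("A", "B", "D", "F"))
  expect_setequal(q$down, c("C", "E", "G"))
  q2 <- suppressMessages(build_query_signature(sensitizers = c("A", "B"),
                                               icb_suppressors = c("B", "C")))
  expect_setequal(q2$up, "A")
  expect_setequal(q2$down, "C")
  q3 <- build_query_signature(sensitizers = "A", resistors = "B")
  expect_setequal(q3$up, "A")
})

test_that("rank aggregation fuses methods and finds planted reversers", {
  set.seed(37)
  spec <- synth_spec(n_drugs = 60, n_reversers = 2)
  query <- build_query_signature(sensitizers = sprintf("U%02d", 1:15),
                                 resistors = sprintf("D%02d", 1:15))
  dm <- make_drug_matrix(spec, query, seed = 8, n_profile_genes = 300)
  res <- suppressMessages(rank_aggregate(query, dm$matrix, n_extreme = 50))
  expect_setequal(res$drug[1:2], dm$truth$reversers)
  # Q of the consensus top drug is the cohort minimum and ranks ascend
  expect_equal(res$q, sort(res$q))
  expect_true(all(res$rr_xsum > 0 & res$rr_xsum <= 1))

  # a drug ranked first by every method has the smallest possible Q
  rr <- c(0.01, 0.01, 0.01)
  expect_lt(stuart_q(rr), stuart_q(c(0.02, 0.5, 0.7)))

  # aggregation is invariant under method order permutation
  res2 <- suppressMessages(rank_aggregate(query, dm$matrix, n_extreme = 50,
                                          methods = c("rges", "xsum", "ks")))
  expect_identical(res$drug, res2$drug)
  expect_equal(res$q, res2$q)
})
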