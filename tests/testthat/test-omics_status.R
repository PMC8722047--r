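test_that("deleterious-mutation rule matches the printed definition", {
  expect_true(is_deleterious("missense", 0.7))
  expect_true(is_deleterious("frameshift", NA))
  expect_false(is_deleterious("missense", 0.5))   # strictly > 0.5
  expect_false(is_deleterious("missense", NA))
  expect_false(is_deleterious("other", 0.99))
  expect_equal(is_deleterious(c("stopgain", "startloss", "stoploss"), NA),
               c(TRUE, TRUE, TRUE))
})

test_that("event callers fire on the right clauses with provenance", {
  co <- toy_cohort()
  # TP53 s3: deep deletion and induced low expression
  call <- call_inactivation(co, "TP53", "s3")
  expect_true(call)
  expect_true("cnv" %in% attr(call, "provenance"))
  # TP53 s1: frameshift only
  call1 <- call_inactivation(co, "TP53", "s1")
  expect_true(call1)
  expect_identical(attr(call1, "provenance"), "mutation")
  # TP53 s2: benign missense (0.3) -> no event
  expect_false(call_inactivation(co, "TP53", "s2"))
  # MYC s4: amplification + high expression, mutation never consulted
  act <- call_activation(co, "MYC", "s4")
  expect_true(act)
  expect_true(all(attr(act, "provenance") %in% c("cnv", "expression")))
  expect_false(call_activation(co, "TP53", "s1")) # frameshift is not activation
  expect_error(call_inactivation(co, "ABSENT", "s1"), "absent")
})

test_that("status callers match a clause-by-clause oracle over all combinations", {
  # one gene x one sample per combination of (mutation class, GISTIC code,
  # z position), forced z via a 3-sample stratum: low/mid/high
  consequences <- c("none", "frameshift", "stopgain", "startloss", "stoploss",
                    "missense_damaging", "missense_benign", "other")
  gistic <- -2:2
  z_levels <- c(low = -10, mid = 0, high = 10)
  samples <- c("sA", paste0("c", 1:10))
  companions <- rep(c(-1, 1), 5)
  for (cons in consequences) {
    for (gi in gistic) {
      for (zl in names(z_levels)) {
        expr <- matrix(8 + c(z_levels[[zl]], companions), nrow = 1,
                       dimnames = list("G", samples))
        muts <- if (cons == "none") {
          data.frame(sample = character(), gene = character(),
                     consequence = character(), damage_prob = numeric())
        } else {
          data.frame(sample = "sA", gene = "G",
                     consequence = sub("_.*", "", cons),
                     damage_prob = switch(cons, missense_damaging = 0.9,
                                          missense_benign = 0.4, NA_real_))
        }
        cnv <- matrix(c(gi, rep(0L, 10)), nrow = 1,
                      dimnames = list("G", samples))
        ann <- data.frame(sample = samples, cancer_type = "x")
        co <- omics_cohort(expr, muts, cnv, ann, z_stratify = "cohort")
        z_val <- co$expr_z["G", "sA"]
        has_del <- cons %in% c("frameshift", "stopgain", "startloss",
                               "stoploss", "missense_damaging")
        expect_equal(as.logical(call_inactivation(co, "G", "sA")),
                     oracle_status("inactivation", has_del, gi, z_val),
                     info = paste(cons, gi, zl))
        expect_equal(as.logical(call_activation(co, "G", "sA")),
                     oracle_status("activation", has_del, gi, z_val),
                     info = paste(cons, gi, zl))
      }
    }
  }
})

test_that("adding a deleterious mutation can only switch calls 0 -> 1", {
  set.seed(11)
  for (rep in 1:20) {
    n <- 6
    expr <- matrix(rnorm(2 * n, 8), nrow = 2,
                   dimnames = list(c("G1", "G2"), paste0("s", 1:n)))
    cnv <- matrix(sample(-2:2, 2 * n, TRUE), nrow = 2,
                  dimnames = dimnames(expr))
    ann <- data.frame(sample = paste0("s", 1:n), cancer_type = "x")
    empty <- data.frame(sample = character(), gene = character(),
                        consequence = character(), damage_prob = numeric())
    co0 <- omics_cohort(expr, empty, cnv, ann, z_stratify = "cohort")
    s0 <- build_status_matrix(co0, c("G1", "G2"), "inactivation")
    extra <- data.frame(sample = sample(paste0("s", 1:n), 1), gene = "G1",
                        consequence = "stopgain", damage_prob = NA_real_)
    co1 <- omics_cohort(expr, extra, cnv, ann, z_stratify = "cohort")
    s1 <- build_status_matrix(co1, c("G1", "G2"), "inactivation")
    expect_true(all(s1 >= s0))
  }
})

test_that("status matrices keep deterministic ordering and handle quiet layers", {
  co <- toy_cohort()
  m <- build_status_matrix(co, c("MYC", "TP53"), "inactivation")
  expect_identical(rownames(m), c("MYC", "TP53"))
  expect_identical(colnames(m), paste0("s", 1:4))
  expect_true(all(m %in% 0:1))

  # activation with no high-level amplification and |z| < 2 is all-false
  expr <- matrix(c(8, 8.1, 7.9, 8), nrow = 1,
                 dimnames = list("G", paste0("s", 1:4)))
  cnv <- matrix(0L, 1, 4, dimnames = dimnames(expr))
  ann <- data.frame(sample = paste0("s", 1:4), cancer_type = "x")
  empty <- data.frame(sample = character(), gene = character(),
                      consequence = character(), damage_prob = numeric())
  co2 <- omics_cohort(expr, empty, cnv, ann, z_stratify = "cohort")
  act <- build_status_matrix(co2, "G", "activation")
  expect_true(all(act == 0))
})
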