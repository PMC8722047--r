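# iscreen — integrative analysis of tumor-immunity CRISPR screens

Pooled CRISPR knockout screens in tumor/immune co-culture systems identify
genes whose loss changes how well immune cells kill tumor cells:
**sensitizer** genes (knockout confers resistance to immune killing, sgRNAs
enriched) and **resistor** genes (knockout sensitizes, sgRNAs depleted).
`iscreen` is an R package plus a numbered analysis workflow that turns a
collection of such screens, together with multi-omics cohort data, into

1. a recurrent **sensitizer/resistor catalog** (significant in ≥ 2 screens,
   with directional rules: enriched ⇔ positive adj. *P* < 0.05 ∧ lfc > 0,
   depleted ⇔ negative adj. *P* < 0.05 ∧ lfc < 0);
2. per-sample binary **functional-status calls** from mutation, copy-number
   and expression data (inactivation ⇔ deleterious mutation ∨ GISTIC −2 ∨
   expression *z* ≤ −2; activation ⇔ GISTIC 2 ∨ *z* ≥ 2, mutations excluded);
3. single-sample **tumor-immunity scores** — an ssGSEA-style immune score,
   the cytolytic (CYT) score √((GZMA+c)(PRF1+c)), and an MHC
   antigen-presentation score — with a covariate-adjusted **association
   filter**: a functional sensitizer must associate negatively with all
   three signatures (adj. *P* < 0.05), a functional resistor positively;
4. the **CTIS** score (mean expression of a sensitizer panel minus a
   resistor panel; default panel JAK1, NFKB2, PPP6C, TNFRSF1B vs PIGM, TPR)
   with Cox, log-rank, C-index and ROC-AUC evaluation; and
5. ensemble **drug-reversal prioritization**: each drug profile is scored
   with XSum, KS connectivity and RGES against an up/down query signature,
   the ascending rank ratios r = rank/n are fused into the Stuart
   order-statistic Q = N!·V\_N (the joint probability that N iid uniforms
   fall below the observed rank ratios), and drugs are ranked by ascending Q.

Every stage is exercised on synthetic cohorts with planted ground truth
(module `synth_spec()` / `make_cohort()` / `make_screens()` /
`make_drug_matrix()` / `make_survival()`), so the whole pipeline is testable
without external downloads. Intended users: computational biologists working
on immuno-oncology target discovery and drug repurposing.

## Worked example

```r
library(iscreen)
spec <- synth_spec()                       # 600 samples, 2000 genes, planted truth
res  <- run_pipeline(pipeline_config(seed = 1), spec = spec)

nrow(res$functional)                       # functional regulators kept
res$ctis_eval$cox$hr                       # CTIS hazard ratio
head(res$drug_ranking[, c("drug", "q")], 3)
```

Running the numbered workflow reproduces the full narrative
(`Rscript analysis/01_simulate.R` … `06_subtype_drivers_dependency.R`); with the
default seed it prints, among others:

```
Functional regulators: 31 of 40 catalog genes (16 sensitizers, 15 resistors)
Recovery vs planted truth: recall 1.00, precision 0.97
CTIS Cox: HR 0.460 (95% CI 0.394-0.536), p = 6.1e-23  [true log-HR -0.7]
Median-split log-rank: chi-square 62.7, p = 2.4e-15
C-index 0.643, responder AUC 0.702
Reversers in top 3: 3 / 3
```

i.e. the association filter recovers the planted regulators essentially
perfectly, the CTIS hazard ratio matches the planted protective effect
(exp(−0.7) ≈ 0.50), and the three planted reversal drugs occupy the top
three aggregated ranks. Stage outputs land as TSV tables under `results/`.

## Layout

- `R/` — the package: IO (`read_gmt`, `read_screen_hits`, …), screen
  integration, status calling, immune scoring, association engine,
  survival/CTIS, connectivity scoring, synthetic-data generators, pipeline.
- `analysis/` — numbered narrative drivers over the package.
- `vignettes/methods.Rmd` — the model, parameter and design documentation.
- `inst/extdata/` — gene-set GMT and synthetic stand-in tables (the screen
  metadata fixture encodes the collection composition of the screen corpus;
  see the vignette).
- `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles.
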