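---
title: "Methods: integrating tumor-immunity CRISPR screens with multi-omics cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrating tumor-immunity CRISPR screens with multi-omics cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iscreen)
```

## The problem

Pooled CRISPR knockout screens in tumor/immune co-culture systems read out
which tumor-intrinsic genes regulate immune-mediated killing. Because each
screen is small, noisy, and run in a particular model system, single-screen
hits are unreliable; the analysis this package implements integrates many
screens into a recurrent catalog, grounds the catalog in patient multi-omics
data, and pushes the result through to two translational outputs: a
prognostic expression score (CTIS) and a ranked list of candidate drugs
whose induced expression changes *reverse* the immune-evasive state.

## Screen integration

A knockout that protects tumor cells from immune killing leaves its sgRNAs
enriched in survivors; such genes normally *sensitize* tumors to immunity.
Conversely, depleted knockouts mark *resistor* genes that normally promote
escape. `classify_hits()` applies the directional rules with strict
inequalities exactly as printed: enriched ⇔ positive adj. *P* < 0.05 ∧
lfc > 0; depleted ⇔ negative adj. *P* < 0.05 ∧ lfc < 0. `build_catalog()`
keeps genes recurring in ≥ 2 screens (`min_screens`, default 2). The
handling of a gene qualifying for both roles is not dictated by the rules
above; we assign the role with more supporting screens and drop exact ties
with a logged message — a conservative choice that never invents a
direction. Mouse screens are lifted to human symbols through a user-supplied
two-column table (`map_orthologs()`); unmapped genes are dropped and
counted, one-to-many mappings expand to all targets.

## Functional-status calling

Patient-level grounding requires knowing, per gene and sample, whether the
gene is functionally knocked out. `call_inactivation()` is the union of
three clauses: a deleterious mutation (loss-of-function consequence, or
missense with damaging probability strictly > 0.5), a deep deletion
(GISTIC −2), or standardized expression z ≤ −2 (inclusive).
`call_activation()` — used for oncogene events in the driver network —
consults only copy number (GISTIC 2) and expression (z ≥ +2): computational
prediction of gain-of-function point mutations is unreliable, so the
mutation layer is deliberately excluded. Every call carries provenance (the
set of satisfied clauses).

Expression is z-scored per gene **within cancer type** by default
(`omics_cohort(..., z_stratify = "cancer_type")`): tissue-of-origin effects
on expression are typically larger than inactivation effects, and pan-cohort
scaling would mark entire low-expressing tissues as "inactivated". Cohort-
wide scaling remains available (`"cohort"`) for single-tissue cohorts.
Genes missing from one omics layer contribute `FALSE` for that clause
rather than aborting a run; genes missing from *all* layers are skipped
with a summary count.

## Tumor-immunity signatures and the association filter

Three orthogonal single-sample scores (all oriented higher = stronger
anti-tumor immune state) anchor the functional filter:

* **immune** — an ssGSEA-style enrichment over an immune-infiltration gene
  set: genes ranked by descending expression (ties broken by symbol for
  determinism), score $\sum_i [P^w_{in}(i) - P_{out}(i)]$ with in-set
  weight $(N-i+1)^\alpha$, $\alpha = 0.25$;
* **CYT** — cytolytic activity, the geometric mean
  $\sqrt{(\mathrm{GZMA}+c)(\mathrm{PRF1}+c)}$ with pseudocount $c = 0.01$ on
  linear-scale expression;
* **MHC** — mean z-scored expression of antigen-presentation genes
  (HLA-A/B/C, B2M, TAP1/2, NLRC5, PSMB8/9 by default).

The member lists ship as a replaceable GMT (`inst/extdata/signatures.gmt`);
they are structural stand-ins with the composition of published signatures,
not a claim about the exact published member lists.

`associate_signatures()` regresses each score on each catalog gene's
inactivation status by OLS with cancer-type dummies (reference = most
frequent type), and `filter_functional_regulators()` keeps sensitizers whose
three associations are all significantly negative and resistors all
significantly positive (BH-adjusted *P* < 0.05 within the full
gene-by-signature family). One scale decision matters here: `cyt_score()`
itself is the linear-scale geometric mean, but `signature_scores()` reports
CYT as its log2 — equivalently the mean log2 expression of the two genes —
because a strictly positive multiplicative score is strongly
heteroscedastic on the linear scale and OLS t-tests against it lose power;
the log transform is the standard variance-stabilizing choice and preserves
the coefficient-sign contract the filter uses.

The same engine drives the secondary screens: one-vs-rest logistic
regressions flag immune-subtype-specific genes (adj. *P* < 0.05 and log2
odds ratio > 1.5; perfect separation yields a flagged record with missing
*p*, never a silent infinity), per-cancer-type feature associations are
counted into S-/R-related feature totals (an S-related feature of a
sensitizer is an anti-tumor feature falling or a pro-tumor feature rising
upon inactivation), and the oncogene/TSG network emits an edge when a
regulator's expression moves beyond |lfc| 0.25 with BH-adjusted Wilcoxon
significance in the role-appropriate direction. Dependency screening
(`proliferation_independent()`) keeps genes with mean CERES-like
essentiality inside the inclusive window [−0.25, 0.25].

## CTIS and survival evaluation

CTIS is the mean expression of a sensitizer panel minus a resistor panel;
higher CTIS = stronger anti-tumor immune state. The shipped default panel
(JAK1, NFKB2, PPP6C, TNFRSF1B vs PIGM, TPR) is used by all downstream
stages. Because the original panel-selection procedure (minimal-depth
random survival forests) is out of scope here, `select_panel_greedy()`
provides a *documented, non-equivalent substitute*: forward selection
maximizing k-fold cross-validated C-index of the CTIS-form score,
deterministic given a seed. Each panel gene is z-scored across the cohort
before averaging (`scale = "z"`), so the two panel halves contribute on
comparable scales across cohorts; raw-scale scoring is available.

Survival machinery: Cox partial likelihood via `survival::coxph` with Efron
tie handling (Breslow configurable), log-rank via `survival::survdiff`,
Harrell C-index and Mann-Whitney AUC implemented by their pair-counting
definitions (ties in score count 0.5; a pair is comparable when the earlier
time carries an event) and cross-checked in the tests against
`survival::concordance`, `pROC`, and exhaustive pair enumeration. KM
dichotomization of CTIS uses the cohort median.

## Connectivity scoring and rank aggregation

The query signature sets positive regulators (sensitizers ∪
immunity-related TSGs ∪ ICB enhancers) as the up side and negative
regulators as the down side; genes claimed by both sides are removed from
both with a log entry. Drugs are prefiltered by development stage
(default: phase 3 or launched, i.e. past phase I/II trials).

Three scores are computed per drug against its descending expression-change
ranking:

* `ks_enrichment()` — signed Kolmogorov–Smirnov statistic
  $a = \max_j [j/t - V_j/n]$, $b = \max_j [V_j/n - (j-1)/t]$, ES = $a$ if
  $a \ge b$ else $-b$;
* `ks_connectivity()` — ES(up) − ES(down) when signs differ, else 0, with
  cohort-level scaling (positives by the max, negatives by |min|);
* `xsum_score()` — sum of up-gene changes minus down-gene changes inside
  the 500 most extreme genes per tail (truncated for small matrices);
* `rges_score()` — ES(up) − ES(down) without the zeroing rule.

Under these definitions all three scores place reversal at the *negative*
end (a reverser pushes query-up genes to the bottom of its ranking, making
ES(up) < 0 and ES(down) > 0, and contributes negative XSum terms), so
ascending per-method ranks already agree in orientation and no per-method
negation is applied before aggregation; the orientation is recorded in the
output columns. Ascending ranks (average on ties) over the post-filter drug
set give rank ratios r = rank/n, and `stuart_q()` computes
$Q = N! \, V_N$ with $V_0 = 1$,
$V_k = \sum_{i=1}^{k} (-1)^{i-1} V_{k-i} \, r_{(N-k+1)}^i / i!$ — the joint
probability that N sorted uniforms fall below the observed rank ratios.
Final ranking is ascending Q with ties broken by mean rank ratio then drug
id. Drugs whose profiles the query does not overlap are excluded with a
logged reason rather than silently ranked.

## The synthetic study and what it does (not) show

All tests run against generated data with planted truth
(`synth_spec()` defaults): 600 samples over 2,000 genes in four cancer
types (skin 0.35, breast 0.25, colon 0.25, lung 0.15); 15 sensitizers,
15 resistors and 10 *null regulators* — recurrent screen hits whose events
do not move the immune signatures, i.e. deliberate screen false positives
that make the filter's precision a real measurement; per-gene event rate
π = 0.15; immune-signature shift δ = 1.0 log2 units per event (down for
sensitizer events, up for resistor events, additive); exponential survival
with baseline rate 0.1 and log-hazard −0.7 per CTIS unit, 30% uniform
censoring; 200 drugs with 3 planted reversers at full strength ρ = 1.
These sizes run the whole suite in minutes on one core while leaving
comfortable statistical headroom for the recovery properties.

Event injection is constructed so the status callers reproduce the planted
event matrix *exactly*: every event carries at least one of a deleterious
mutation (60%), a deep deletion (50%), or an extreme-low expression value
(25%, at least one forced); background mutations are always benign and
background CNV never reaches ±2 on planted genes. Two numerical details
make the expression clause safe: regulator genes use bounded two-point
noise (±0.3 plus jitter), whose sample z can never stray past ≈ ±1.2 on a
non-event sample, and expression-borne events are kept sparse because a
binary low/high pattern mathematically cannot reach |z| ≥ 2 once the low
group exceeds about a fifth of a stratum.

The generator emulates the *statistical structure* the analysis assumes —
cancer-type expression offsets, consistent multi-omics event injection,
signature shifts, hazard coupling, reversal anti-correlation — and none of
the distributional quirks of real tumor data: no mutation signatures, no
copy-number segments, no expression correlation structure beyond the
planted shifts, one profile per drug. Passing recovery tests therefore
demonstrates that the pipeline's inference is correct *under its own model
assumptions*, not that real cohorts meet those assumptions.

One global seed drives a named substream per generator
(`substream_seed()`), so adding a generator never perturbs another's draws
and every generator is a pure function of (spec, seed).

## Numerical choices and degenerate inputs

* Strict vs inclusive boundaries follow the printed rules: adj. *P* < 0.05
  and damage probability > 0.5 strict; z cuts, the CERES window and the
  development-stage minimum inclusive.
* Percentages in metadata summaries are rounded half-up to two decimals.
* Expression-rank ties in enrichment walks break by gene symbol; rank ties
  in drug scoring use average ranks.
* Constant response in OLS returns coefficient 0, *p* = 1 by contract;
  single-class status yields an `insufficient_events` flag (default
  minimum 5 per class) instead of a fit.
* Logistic separation, Cox non-convergence and monotone likelihood are
  flagged records, never ±∞ estimates.
* BH adjustment passes missing p-values through untouched and is applied
  once per declared test family (all gene × target tests of one run).
* The screen metadata table under `inst/extdata/` is a synthetic stand-in
  (so labelled) whose category counts match the published collection
  composition; the gene sets and feature catalog are likewise structural
  stand-ins, replaceable via GMT/TSV.

## Known limitations

MAGeCK/DrugZ-style sgRNA statistics, variant-effect prediction, CNV
segmentation, GO similarity analysis and deconvolution are out of scope;
hit tables, damage probabilities and GISTIC codes are inputs. The greedy
panel selector is not the original forest-based procedure and is labelled
as such. The normalized resistor-sensitizer ratio statistic has no
recoverable definition and is not computed. Drug profiles are taken one
per compound; collapsing replicate instances is the caller's concern.
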