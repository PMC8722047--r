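#' Specification of a synthetic study
#'
#' Collects every generator parameter in one validated list. Defaults
#' define the study conditions the test-suite cohorts use: a 600-sample
#' pan-cancer cohort over 2,000 genes with 15 planted sensitizers,
#' 15 planted resistors and 10 null regulators (recurrent screen hits
#' whose events do not move the immune signatures — screen false
#' positives that the association filter should remove), event rate 0.15,
#' immune-signature shift 1.0 (log2 units per event), exponential
#' survival with log-hazard -0.7 per CTIS unit, and 3 planted reversal
#' drugs among 200.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param cancer_types Named numeric vector of mixing proportions
#'   (must sum to 1).
#' @param n_sensitizers,n_resistors,n_null_regulators Planted gene counts.
#' @param event_rate Per-gene, per-sample functional-event probability.
#' @param signature_effect Log2 expression shift of immune-signature
#'   genes per event (sensitizer events shift down, resistor events up).
#' @param mutation_background_rate Per-sample rate of benign background
#'   mutation records.
#' @param cnv_background_rate Probability of a background single-copy
#'   gain/loss per gene-sample.
#' @param surv_lambda Baseline exponential hazard rate.
#' @param surv_beta Log-hazard decrease per CTIS unit (protective).
#' @param censoring Target censoring fraction.
#' @param n_drugs,n_reversers Drug-matrix dimensions.
#' @param reversal_strength rho in [0, 1]; scales the planted reversers'
#'   anti-correlation with the query signature.
#' @param n_screens Number of synthetic screens.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 600, n_genes = 2000,
                       cancer_types = c(skin = 0.35, breast = 0.25,
                                        colon = 0.25, lung = 0.15),
                       n_sensitizers = 15, n_resistors = 15,
                       n_null_regulators = 10,
                       event_rate = 0.15, signature_effect = 1.0,
                       mutation_background_rate = 0.02,
                       cnv_background_rate = 0.05,
                       surv_lambda = 0.1, surv_beta = 0.7,
                       censoring = 0.3,
                       n_drugs = 200, n_reversers = 3,
                       reversal_strength = 1,
                       n_screens = 4) {
  stopifnot(abs(sum(cancer_types) - 1) < 1e-8,
            event_rate >= 0, event_rate <= 1,
            reversal_strength >= 0, reversal_strength <= 1,
            censoring >= 0, censoring < 1)
  if ((n_sensitizers + n_resistors + n_null_regulators) > 0 && event_rate == 0) {
    stop("event_rate = 0 is infeasible with planted regulator genes",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_spec")
}

# Gene universe shared by the generators. Signature genes use field-standard
# symbols so the packaged GMT applies unchanged; planted and background genes
# use synthetic identifiers.
.synth_genes <- function(spec) {
  sets <- default_signature_sets()
  sens <- sprintf("SENS%02d", seq_len(spec$n_sensitizers))
  res <- sprintf("RES%02d", seq_len(spec$n_resistors))
  nul <- if (spec$n_null_regulators > 0)
    sprintf("NULLREG%02d", seq_len(spec$n_null_regulators)) else character()
  panel <- c("JAK1", "NFKB2", "PPP6C", "TNFRSF1B", "PIGM", "TPR")
  feature_genes <- unique(unlist(read_feature_catalog()$genes,
                                 use.names = FALSE))
  named <- unique(c(unlist(sets, use.names = FALSE), panel, feature_genes))
  n_bg <- spec$n_genes - length(named) - length(sens) - length(res) - length(nul)
  if (n_bg < 0) stop("n_genes too small for the planted and signature genes",
                     call. = FALSE)
  bg <- sprintf("BG%04d", seq_len(n_bg))
  list(sensitizers = sens, resistors = res, null_regulators = nul,
       signature = unlist(sets, use.names = FALSE), panel = panel,
       background = bg,
       all = c(named, sens, res, nul, bg), sets = sets)
}

#' Generate a synthetic multi-omics cohort with planted ground truth
#'
#' Log2-scale expression with per-cancer-type offsets; planted regulator
#' events at the configured event rate, injected so that the functional-
#' status callers reproduce the intended event matrix exactly: every
#' event carries at least one of a deleterious mutation, a deep deletion
#' (GISTIC -2), or extreme-low expression, and expression-borne events
#' are kept sparse enough that the within-stratum z <= -2 rule can fire
#' (a binary low/high pattern cannot reach |z| >= 2 once the low group
#' exceeds about a fifth of a stratum). Sensitizer events shift every
#' immune-signature gene down by the signature effect, resistor events
#' shift them up; null-regulator events shift nothing.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed; every generator stream derives from it.
#' @return List: `cohort` (an [omics_cohort()]) and `truth` (planted
#'   gene lists and the genes-by-samples event matrix).
#' @export
make_cohort <- function(spec, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "cohort"))
  g <- .synth_genes(spec)
  genes <- g$all
  n <- spec$n_samples
  samples <- sprintf("S%04d", seq_len(n))
  ct <- sample(names(spec$cancer_types), n, replace = TRUE,
               prob = spec$cancer_types)

  mu <- stats::runif(length(genes), 4, 10)
  names(mu) <- genes
  offsets <- matrix(stats::rnorm(length(genes) * length(spec$cancer_types),
                                 0, 0.5),
                    nrow = length(genes),
                    dimnames = list(genes, names(spec$cancer_types)))
  noise_sd <- ifelse(genes %in% c(g$signature, g$panel), 0.5, 1)
  expr <- matrix(stats::rnorm(length(genes) * n, 0, 1), nrow = length(genes),
                 dimnames = list(genes, samples)) * noise_sd
  expr <- expr + mu + offsets[, ct]

  planted <- c(g$sensitizers, g$resistors, g$null_regulators)
  # Regulator genes get two-point bounded noise (+/-0.3 with a small
  # jitter): the sample z of such a pattern stays near +/-1, so chance
  # excursions can never trip the |z| >= 2 clauses on non-event samples.
  reg_noise <- matrix(sample(c(-0.3, 0.3), length(planted) * n, TRUE) +
                        stats::runif(length(planted) * n, -0.05, 0.05),
                      nrow = length(planted))
  expr[planted, ] <- mu[planted] + offsets[planted, ct] + reg_noise

  events <- matrix(0L, nrow = length(planted), ncol = n,
                   dimnames = list(planted, samples))
  mut_rows <- list()
  cnv <- matrix(0L, nrow = length(genes), ncol = n,
                dimnames = list(genes, samples))
  bg_cnv <- matrix(sample(c(-1L, 0L, 1L), length(genes) * n, replace = TRUE,
                          prob = c(spec$cnv_background_rate / 2,
                                   1 - spec$cnv_background_rate,
                                   spec$cnv_background_rate / 2)),
                   nrow = length(genes))
  cnv[, ] <- bg_cnv

  lof <- c("frameshift", "stopgain", "startloss", "stoploss")
  for (gene in planted) {
    ev <- which(stats::runif(n) < spec$event_rate)
    events[gene, ev] <- 1L
    cnv[gene, ] <- pmax(pmin(cnv[gene, ], 1L), -1L)  # no stray +/-2 codes
    for (s in ev) {
      via_mut <- stats::runif(1) < 0.6
      via_cnv <- stats::runif(1) < 0.5
      via_expr <- stats::runif(1) < 0.25
      if (!via_mut && !via_cnv && !via_expr) via_mut <- TRUE
      if (via_mut) {
        if (stats::runif(1) < 0.7) {
          mut_rows[[length(mut_rows) + 1]] <- data.frame(
            sample = samples[s], gene = gene,
            consequence = sample(lof, 1), damage_prob = NA_real_,
            stringsAsFactors = FALSE)
        } else {
          mut_rows[[length(mut_rows) + 1]] <- data.frame(
            sample = samples[s], gene = gene, consequence = "missense",
            damage_prob = stats::runif(1, 0.6, 1), stringsAsFactors = FALSE)
        }
      }
      if (via_cnv) cnv[gene, s] <- -2L
      if (via_expr) expr[gene, s] <- mu[gene] + offsets[gene, ct[s]] - 10
    }
  }

  # Benign background mutation records (never deleterious, any gene).
  n_bg_mut <- stats::rpois(1, spec$mutation_background_rate * n * 10)
  if (n_bg_mut > 0) {
    mut_rows[[length(mut_rows) + 1]] <- data.frame(
      sample = sample(samples, n_bg_mut, replace = TRUE),
      gene = sample(g$background, n_bg_mut, replace = TRUE),
      consequence = sample(c("other", "missense"), n_bg_mut, replace = TRUE),
      damage_prob = stats::runif(n_bg_mut, 0, 0.5), stringsAsFactors = FALSE)
  }
  mutations <- if (length(mut_rows) > 0) do.call(rbind, mut_rows) else
    data.frame(sample = character(), gene = character(),
               consequence = character(), damage_prob = numeric(),
               stringsAsFactors = FALSE)

  # Immune-signature shift: -delta per sensitizer event, +delta per
  # resistor event, additive over a sample's events.
  shift <- spec$signature_effect *
    (colSums(events[g$resistors, , drop = FALSE]) -
     colSums(events[g$sensitizers, , drop = FALSE]))
  sig_genes <- intersect(g$signature, genes)
  expr[sig_genes, ] <- expr[sig_genes, ] +
    matrix(shift, nrow = length(sig_genes), ncol = n, byrow = TRUE)

  annotations <- data.frame(
    sample = samples, cancer_type = ct,
    immune_subtype = sample(paste0("C", 1:6), n, replace = TRUE,
                            prob = c(0.25, 0.30, 0.10, 0.15, 0.10, 0.10)),
    age = round(stats::rnorm(n, 60, 10)),
    stringsAsFactors = FALSE)

  cohort <- omics_cohort(expr, mutations, cnv, annotations)
  truth <- list(sensitizers = g$sensitizers, resistors = g$resistors,
                null_regulators = g$null_regulators, events = events,
                gene_sets = g$sets)
  list(cohort = cohort, truth = truth)
}

#' Generate synthetic per-screen hit tables and metadata
#'
#' Planted regulators (including null regulators) are significant in at
#' least two screens with the role-appropriate direction; decoy genes are
#' significant in exactly one screen; the remaining genes are neutral.
#'
#' @param spec A [synth_spec()].
#' @param seed Integer seed.
#' @param n_decoys Decoy genes per role (default 10).
#' @param n_noise Neutral filler genes (default 200).
#' @return List: `hits` (named list of hit tables), `metadata`
#'   (data.frame), `truth` (planted gene lists).
#' @export
make_screens <- function(spec, seed = 1, n_decoys = 10, n_noise = 200) {
  stopifnot(spec$n_screens >= 2)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "screens"))
  g <- .synth_genes(spec)
  screen_ids <- sprintf("SCR%02d", seq_len(spec$n_screens))
  decoy_sens <- sprintf("DECS%02d", seq_len(n_decoys))
  decoy_res <- sprintf("DECR%02d", seq_len(n_decoys))
  noise <- sprintf("NOISE%03d", seq_len(n_noise))
  universe <- c(g$sensitizers, g$resistors, g$null_regulators,
                decoy_sens, decoy_res, noise)

  assign_screens <- function(k) sample(screen_ids, k)
  plan <- list()
  for (gene in c(g$sensitizers, g$null_regulators)) {
    plan[[gene]] <- list(role = "enriched",
                         screens = assign_screens(sample(2:spec$n_screens, 1)))
  }
  for (gene in g$resistors) {
    plan[[gene]] <- list(role = "depleted",
                         screens = assign_screens(sample(2:spec$n_screens, 1)))
  }
  for (gene in decoy_sens) {
    plan[[gene]] <- list(role = "enriched", screens = assign_screens(1))
  }
  for (gene in decoy_res) {
    plan[[gene]] <- list(role = "depleted", screens = assign_screens(1))
  }

  hits <- lapply(screen_ids, function(sid) {
    df <- data.frame(gene = universe,
                     lfc = stats::rnorm(length(universe), 0, 0.3),
                     adj_p_pos = stats::runif(length(universe), 0.2, 1),
                     adj_p_neg = stats::runif(length(universe), 0.2, 1),
                     stringsAsFactors = FALSE)
    for (gene in names(plan)) {
      if (!sid %in% plan[[gene]]$screens) next
      i <- match(gene, df$gene)
      if (plan[[gene]]$role == "enriched") {
        df$lfc[i] <- stats::runif(1, 0.5, 2.5)
        df$adj_p_pos[i] <- stats::runif(1, 1e-5, 0.04)
      } else {
        df$lfc[i] <- -stats::runif(1, 0.5, 2.5)
        df$adj_p_neg[i] <- stats::runif(1, 1e-5, 0.04)
      }
    }
    attr(df, "screen_id") <- sid
    df
  })
  names(hits) <- screen_ids

  metadata <- data.frame(
    screen_id = screen_ids,
    study_id = paste0("STUDY", ceiling(seq_along(screen_ids) / 2)),
    cancer_type = sample(names(spec$cancer_types), spec$n_screens,
                         replace = TRUE),
    setting = sample(c("in_vitro", "in_vivo"), spec$n_screens, TRUE,
                     prob = c(0.75, 0.25)),
    library_scale = "genome_scale", organism = "human",
    algorithm = sample(c("MAGeCK", "DrugZ"), spec$n_screens, TRUE),
    icb_treated = FALSE, stringsAsFactors = FALSE)

  list(hits = hits, metadata = metadata,
       truth = list(sensitizers = c(g$sensitizers, g$null_regulators),
                    resistors = g$resistors,
                    decoys = c(decoy_sens, decoy_res)))
}

#' Generate a synthetic drug-signature matrix with planted reversers
#'
#' Background drugs carry iid standard-normal expression-change profiles;
#' planted reversers push the query's up genes down and down genes up
#' with magnitude proportional to the reversal strength.
#'
#' @param spec A [synth_spec()].
#' @param query A [build_query_signature()] result.
#' @param seed Integer seed.
#' @param n_profile_genes Background genes in the profiles (default 1000).
#' @return List: `matrix`, `annotations` (all "launched"), `truth`
#'   (reverser drug ids).
#' @export
make_drug_matrix <- function(spec, query, seed = 1, n_profile_genes = 1000) {
  stopifnot(length(query$up) + length(query$down) > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "drugs"))
  genes <- unique(c(query$up, query$down,
                    sprintf("DG%04d", seq_len(n_profile_genes))))
  drugs <- sprintf("drug_%03d", seq_len(spec$n_drugs))
  m <- matrix(stats::rnorm(length(genes) * spec$n_drugs), nrow = length(genes),
              dimnames = list(genes, drugs))
  reversers <- sample(drugs, spec$n_reversers)
  rho <- spec$reversal_strength
  for (d in reversers) {
    m[query$up, d] <- stats::rnorm(length(query$up), -3 * rho, 1)
    m[query$down, d] <- stats::rnorm(length(query$down), 3 * rho, 1)
  }
  annotations <- data.frame(drug = drugs, clinical_phase = "launched",
                            stringsAsFactors = FALSE)
  list(matrix = m, annotations = annotations,
       truth = list(reversers = sort(reversers)))
}

#' Generate survival and response records whose hazard tracks a score
#'
#' Event times are exponential with rate `lambda * exp(-beta * score)`
#' (higher score, lower hazard, longer survival); censoring is uniform
#' on (0, c) with c solved so the expected censoring fraction meets the
#' spec target. Response (CR/PR vs SD/PD) is drawn from a logistic model
#' on the same score.
#'
#' @param spec A [synth_spec()].
#' @param score Named per-sample score vector (e.g. CTIS).
#' @param seed Integer seed.
#' @param response_beta Log-odds of response per score unit (default 1).
#' @return data.frame: sample, time, event, response.
#' @export
make_survival <- function(spec, score, seed = 1, response_beta = 1) {
  stopifnot(spec$surv_lambda > 0)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "survival"))
  n <- length(score)
  rate <- spec$surv_lambda * exp(-spec$surv_beta * score)
  t_event <- stats::rexp(n, rate)
  if (spec$censoring > 0) {
    f <- function(cc) mean(pmin(t_event / cc, 1)) - spec$censoring
    cmax <- max(t_event) * 100
    c_sol <- stats::uniroot(f, c(min(t_event) / 100, cmax))$root
    t_cens <- stats::runif(n, 0, c_sol)
  } else {
    t_cens <- rep(Inf, n)
  }
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  p_resp <- stats::plogis(response_beta * (score - stats::median(score)))
  responder <- stats::runif(n) < p_resp
  response <- ifelse(responder,
                     sample(c("CR", "PR"), n, TRUE, prob = c(0.3, 0.7)),
                     sample(c("SD", "PD"), n, TRUE, prob = c(0.4, 0.6)))
  data.frame(sample = names(score) %||% seq_len(n), time = time,
             event = event, response = response, stringsAsFactors = FALSE)
}
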