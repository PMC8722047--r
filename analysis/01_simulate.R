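#!/usr/bin/env Rscript
# Stage 1: define the synthetic study and summarize its inputs.
#
# The packaged screen-metadata table describes the screen collection the
# integration stage draws on (17 immune-killing screens + 5 ICB-treated);
# the synthetic cohort generator defines the multi-omics study population
# with planted sensitizers/resistors. Later stages regenerate the same
# objects from the shared seed, so no large matrices are written to disk.

suppressMessages(library(iscreen))
dir.create("results", showWarnings = FALSE)
seed <- 1
spec <- synth_spec()

meta <- read_screen_metadata(
  system.file("extdata", "screen_metadata_synthetic.tsv", package = "iscreen"))
killing <- meta[!meta$icb_treated, ]
cat(sprintf("Screen collection: %d screens (%d immune-killing, %d ICB-treated)\n",
            nrow(meta), nrow(killing), sum(meta$icb_treated)))

summaries <- do.call(rbind, lapply(
  c("cancer_type", "setting", "library_scale", "organism", "algorithm"),
  function(f) cbind(field = f, summarize_metadata(killing, f))))
print(summaries, row.names = FALSE)
write.table(summaries, "results/01_screen_metadata_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sim <- make_cohort(spec, seed = seed)
ann <- sim$cohort$annotations
cohort_summary <- data.frame(
  quantity = c("samples", "genes", "cancer_types", "planted_sensitizers",
               "planted_resistors", "null_regulators", "total_events"),
  value = c(ncol(sim$cohort$expr), nrow(sim$cohort$expr),
            length(unique(ann$cancer_type)),
            length(sim$truth$sensitizers), length(sim$truth$resistors),
            length(sim$truth$null_regulators), sum(sim$truth$events)))
print(cohort_summary, row.names = FALSE)
write.table(cohort_summary, "results/01_cohort_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("Mean events per planted gene:",
    round(mean(rowSums(sim$truth$events)), 1), "\n")
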