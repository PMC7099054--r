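#!/usr/bin/env Rscript
# Run the full pipeline (trim, merge, annotate, collapse) on simulated
# cohorts and compute the per-donor repertoire statistics: hypomutated
# fraction, mean mutation count, skewness, Gini index, IGHV4-34 usage and
# motif intactness.
#
# Output: results/02_repertoire_summaries.csv

library(ighvrep)

dir.create("results", showWarnings = FALSE)
ref <- load_reference()

groups <- c("HC", "ERA", "ESRA", "SJOGREN")
n_donors <- 6L
n_reads <- 3000L

summaries <- list()
for (g in groups) {
  preset <- donor_preset(g, n_reads = n_reads)
  for (s in seq_len(n_donors)) {
    sim <- simulate_donor(preset, seed = s, reference = ref)
    rep <- run_donor_pipeline(sim, ref)
    sm <- repertoire_summary(rep)
    sm$group <- g
    sm$seed <- s
    summaries[[length(summaries) + 1L]] <- sm
    cat(sprintf("%s seed %d: %5.2f%% hypomutated, mean %5.2f, gini %.3f\n",
                g, s, sm$pct_hypomutated, sm$mean_mutations, sm$gini))
  }
}
res <- do.call(rbind, summaries)
write.csv(res, "results/02_repertoire_summaries.csv", row.names = FALSE)

cat("\nGroup means:\n")
print(aggregate(res[, c("pct_hypomutated", "mean_mutations", "skewness",
                        "gini", "v4_34_pct")],
                list(group = res$group), mean), digits = 3)
cat("\nNote the negative skewness driven by the hypomutated component in\n",
    "the patient groups, and the higher IGHV4-34 usage in ERA.\n")
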