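#!/usr/bin/env Rscript
# Simulate desk-scale repertoires for the four donor groups and record the
# ground-truth group structure the later analyses should recover.
#
# Output: results/01_truth_group_summary.csv, one example FASTQ pair.

library(ighvrep)

dir.create("results", showWarnings = FALSE)
ref <- load_reference()
print(ref)

groups <- c("HC", "ERA", "ESRA", "SJOGREN")
n_donors <- 6L
n_reads <- 3000L

rows <- list()
for (g in groups) {
  preset <- donor_preset(g, n_reads = n_reads)
  for (s in seq_len(n_donors)) {
    tr <- simulate_donor(preset, seed = s, reference = ref,
                         emit_reads = FALSE)$truth
    igg <- tr[tr$isotype == "IgG", ]
    w <- rep(igg$v_mutation_count, igg$duplicate_count)
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, seed = s,
      molecules = nrow(igg), reads = sum(igg$duplicate_count),
      truth_pct_hypomutated = 100 * mean(w < 5),
      truth_mean_mutations = mean(w),
      truth_v4_34_pct = 100 *
        sum(igg$duplicate_count[grepl("^IGHV4-34", igg$v_call)]) /
        sum(igg$duplicate_count)
    )
  }
}
truth <- do.call(rbind, rows)
write.csv(truth, "results/01_truth_group_summary.csv", row.names = FALSE)

agg <- aggregate(truth[, -(1:2)], list(group = truth$group), mean)
cat("\nTruth-level group means over", n_donors, "donors:\n")
print(agg, digits = 3)
cat("\nThe ERA group should show the hypomutated excess (target 12.6%)\n",
    "against healthy controls (target 2.8%), with elevated IGHV4-34 use.\n")

# one donor's raw reads, for inspection with standard tools
sim <- simulate_donor(donor_preset("ERA", n_reads = 100L), seed = 1,
                      reference = ref)
write_fastq(sim$reads, "results/01_example_R1.fastq",
            "results/01_example_R2.fastq")
write_airr(sim$truth, "results/01_example_truth.tsv")
cat("\nwrote results/01_example_R{1,2}.fastq and 01_example_truth.tsv\n")
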