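#!/usr/bin/env Rscript
# Paired blood/synovium analysis: per-compartment mutation loads under the
# duplicate-count >= 2 filter, shared-sequence Venn counts, multi-
# compartmental clone lineages and synovium-to-blood egression calls.
#
# Output: results/04_paired_mutation_means.csv,
#         results/04_shared_sequences.csv,
#         results/04_egression_events.csv, results/lineages/*.gml

library(ighvrep)

dir.create("results/lineages", recursive = TRUE, showWarnings = FALSE)
ref <- load_reference()

n_pairs <- 4L
mut_rows <- shared_rows <- egr_rows <- list()

for (i in seq_len(n_pairs)) {
  spec <- paired_compartment_spec(n_reads = 2500L, egression_clones = 2L)
  pc <- simulate_paired_compartments(spec, seed = i, reference = ref)
  rb <- run_donor_pipeline(pc$blood, ref, min_duplicates = 2L)
  rs <- run_donor_pipeline(pc$synovium, ref, min_duplicates = 2L)
  mean_mut <- function(rep) {
    r <- rep$records[rep$records$isotype == "IgG", ]
    sum(r$v_mutation_count * r$duplicate_count) / sum(r$duplicate_count)
  }
  mut_rows[[i]] <- data.frame(pair = i, blood = mean_mut(rb),
                              synovium = mean_mut(rs))

  st <- shared_sequence_table(rb$records, rs$records)
  shared_rows[[i]] <- data.frame(pair = i, private_blood = st$private_a,
                                 private_synovium = st$private_b,
                                 shared = st$shared)

  trees <- lineage_trees(rb$records, rs$records, ref)
  for (cid in names(trees)) {
    ev <- call_egressions(trees[[cid]])
    if (nrow(ev)) {
      ev$pair <- i
      ev$clone <- cid
      egr_rows[[length(egr_rows) + 1L]] <- ev
      safe <- gsub("[^A-Za-z0-9]", "_", cid)
      write_lineage_gml(trees[[cid]],
                        sprintf("results/lineages/pair%02d_%s.gml", i, safe))
    }
  }
}

muts <- do.call(rbind, mut_rows)
write.csv(muts, "results/04_paired_mutation_means.csv", row.names = FALSE)
cat("Per-pair mean IgG mutation counts (duplicate >= 2):\n")
print(muts, digits = 4)
cat(sprintf("\nGroup means: blood %.2f vs synovium %.2f (synovium higher,\n",
            mean(muts$blood), mean(muts$synovium)))
cat("as configured: 15.27 vs 19.65).\n")

shared <- do.call(rbind, shared_rows)
write.csv(shared, "results/04_shared_sequences.csv", row.names = FALSE)
cat("\nShared unique non-singleton sequences per pair (near zero by\n",
    "construction: shared clones are <0.1% of the synovial repertoire):\n")
print(shared)

egr <- do.call(rbind, egr_rows)
write.csv(egr, "results/04_egression_events.csv", row.names = FALSE)
cat(sprintf("\n%d egression events across %d planted lineages; trees with\n",
            nrow(egr), n_pairs * 2L))
cat("events exported under results/lineages/ as GML.\n")
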