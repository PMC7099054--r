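germ_contig <- function(allele, insert_aa = "GRDT",
                        j = "IGHJ4*01", iso = "IgG") {
  al <- test_ref$alleles[[allele]]
  ins <- vapply(strsplit(insert_aa, "")[[1]], function(a) {
    c(G = "GGT", R = "CGT", D = "GAT", T = "ACT", A = "GCT")[[a]]
  }, "")
  paste0(al$nt_sequence, paste0(ins, collapse = ""),
         test_ref$j_genes[[j]], test_ref$c_primers[[iso]])
}

test_that("germline contigs are assigned their own allele with 0 mutations", {
  for (nm in c("IGHV1-2*01", "IGHV4-34*01", "IGHV6-1*01")) {
    va <- assign_v_allele(germ_contig(nm), test_ref)
    expect_true(va$assigned)
    expect_equal(va$v_call, nm)
    expect_equal(va$v_mutation_count, 0L)
    expect_equal(va$v_end, nchar(test_ref$alleles[[nm]]$nt_sequence))
  }
})

test_that("non-immunoglobulin sequences are unassignable", {
  set.seed(33)
  junk <- paste0(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
  va <- assign_v_allele(junk, test_ref)
  expect_false(va$assigned)
  expect_true(is.na(va$v_call))
})

test_that("mutation counting ignores junction content", {
  base <- germ_contig("IGHV3-7*01", insert_aa = "GRDT")
  div <- germ_contig("IGHV3-7*01", insert_aa = "AAAA")  # divergent junction
  vb <- assign_v_allele(c(base, div), test_ref)
  expect_equal(vb$v_mutation_count, c(0L, 0L))
  # two V substitutions + divergent junction still count 2
  mut <- plant_mutations(test_ref$alleles[["IGHV3-7*01"]]$nt_sequence, 2,
                         seed = 12)
  contig <- paste0(mut$sequence,
                   substr(div, nchar(mut$sequence) + 1L, nchar(div)))
  va <- assign_v_allele(contig, test_ref)
  expect_equal(va$v_mutation_count, 2L)
  expect_equal(count_mutations(va[1, ], test_ref), 2L)
})

test_that("junction extraction recovers the simulated CDR3 exactly", {
  p <- donor_preset("ERA", n_reads = 800L)
  sim <- simulate_donor(p, seed = 13, reference = test_ref,
                        emit_reads = FALSE)
  tr <- sim$truth
  va <- assign_v_allele(tr$sequence, test_ref)
  jx <- extract_junction(tr$sequence, va$v_end, test_ref)
  expect_identical(jx$junction_aa, tr$junction_aa)
  expect_identical(jx$junction, tr$junction)
  expect_identical(jx$j_call, sub("\\*.*", "", tr$j_call))
  expect_true(all(jx$productive))
  expect_true(all(substr(jx$junction_aa, 1, 1) == "C"))
  # a frameshift in the junction insert is flagged nonproductive
  fs <- tr$sequence[1]
  vlen <- nchar(test_ref$alleles[[tr$v_call[1]]]$nt_sequence)
  fs <- paste0(substr(fs, 1, vlen + 1), substr(fs, vlen + 3, nchar(fs)))
  jfs <- extract_junction(fs, vlen, test_ref)
  expect_true(is.na(jfs$junction_aa) || !jfs$productive)
})

test_that("isotype is called from the constant stub within 2 mismatches", {
  g <- germ_contig("IGHV1-2*01", iso = "IgG")
  m <- germ_contig("IGHV1-2*01", iso = "IgM")
  expect_equal(assign_isotype(c(g, m), test_ref), c("IgG", "IgM"))
  m1 <- m
  substr(m1, nchar(m1), nchar(m1)) <- "T"  # one stub mismatch
  expect_equal(assign_isotype(m1, test_ref), "IgM")
  scram <- paste0(substr(g, 1, nchar(g) - 20), strrep("ATCGAT", 4))
  expect_true(is.na(assign_isotype(substr(scram, 1, nchar(g)), test_ref)))
})

test_that("the pipeline reproduces simulator truth read for read", {
  d <- cached_small_donor()
  rec <- annotate_contigs(preprocess_reads(d$sim$reads)$contigs, test_ref)
  tr <- d$sim$truth
  m <- match(sub(":.*", "", rec$sequence_id), tr$sequence_id)
  expect_equal(nrow(rec), sum(tr$duplicate_count))
  # gene-level V call and exact mutation counts for every read
  expect_true(all(rec$v_gene == sub("\\*.*", "", tr$v_call[m])))
  expect_true(all(rec$v_mutation_count == tr$v_mutation_count[m]))
  expect_true(all(rec$junction_aa == tr$junction_aa[m]))
  expect_true(all(rec$isotype == tr$isotype[m]))
  # collapsing recovers the duplicate structure
  col <- collapse_duplicates(rec)
  # distinct truth molecules can share a sequence (same clone, same
  # mutations); collapsing sums them, so compare sequence-level totals
  truth_by_seq <- rowsum(tr$duplicate_count, tr$sequence)
  expect_true(all(col$duplicate_count ==
                    truth_by_seq[match(col$sequence,
                                       rownames(truth_by_seq)), 1]))
  expect_equal(sum(col$duplicate_count), sum(rec$duplicate_count))
})

test_that("collapse_duplicates merges identical sequences and filters", {
  rec <- data.frame(
    sequence_id = c("a", "b", "c", "d"),
    donor_id = "x", compartment = "blood",
    sequence = c("AAAA", "AAAA", "AAAA", "CCCC"),
    duplicate_count = 1L, stringsAsFactors = FALSE
  )
  col <- collapse_duplicates(rec)
  expect_equal(nrow(col), 2L)
  expect_equal(col$duplicate_count[col$sequence == "AAAA"], 3L)
  # conservation of total reads without a filter
  expect_equal(sum(col$duplicate_count), sum(rec$duplicate_count))
  # min_duplicates = 2 removes singletons
  col2 <- collapse_duplicates(rec, min_duplicates = 2L)
  expect_equal(col2$sequence, "AAAA")
  # identity when nothing is duplicated
  rec2 <- rec[c(1, 4), ]
  expect_equal(nrow(collapse_duplicates(rec2)), 2L)
})

test_that("the 25,000-read donor filter is a strict boundary", {
  mk <- function(n) data.frame(duplicate_count = n)
  expect_false(apply_donor_filter(mk(24999L))$include)
  expect_true(apply_donor_filter(mk(25000L))$include)
  expect_false(apply_donor_filter(mk(0L))$include)
  expect_true(apply_donor_filter(mk(100L), min_reads = 100L)$include)
})

test_that("motif flags populate only for IGHV4-34 calls", {
  d <- cached_small_donor()
  rec <- d$rep$records
  expect_true(all(is.na(rec$avy_intact[rec$v_gene != "IGHV4-34"])))
  v434 <- rec[rec$v_gene == "IGHV4-34", ]
  if (nrow(v434)) {
    expect_true(all(!is.na(v434$avy_intact)))
    # unmutated IGHV4-34 reads always carry intact motifs
    un <- v434[v434$v_mutation_count == 0, ]
    if (nrow(un)) {
      expect_true(all(un$avy_intact), all(un$nhs_intact))
    }
  }
})
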