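test_that("presets solve the somatic hypermutation mixture to target", {
  for (nm in c("HC", "ERA", "ESRA", "SJOGREN")) {
    p <- donor_preset(nm)
    # implied P(count < 5) and mean of the mixture equal the targets
    F4 <- pnbinom(4, size = p$size_hyper, mu = p$mu_hyper)
    implied_hypo <- p$w_hypo + (1 - p$w_hypo) * F4
    m_h <- sum((0:4) * 0.5^(0:4) / sum(0.5^(0:4)))
    implied_mean <- p$w_hypo * m_h + (1 - p$w_hypo) * p$mu_hyper
    expect_equal(100 * implied_hypo, p$pct_hypo, tolerance = 1e-8)
    expect_equal(implied_mean, p$mean_mut, tolerance = 1e-8)
    expect_true(p$w_hypo >= 0 && p$w_hypo <= 1)
  }
})

test_that("simulate_donor is byte-identical under a fixed seed", {
  p <- donor_preset("HC", n_reads = 300L)
  s1 <- simulate_donor(p, seed = 1, reference = test_ref)
  s2 <- simulate_donor(p, seed = 1, reference = test_ref)
  expect_identical(s1, s2)
  fq1 <- tempfile(); fq2 <- tempfile()
  write_fastq(s1$reads, fq1, tempfile())
  write_fastq(s2$reads, fq2, tempfile())
  expect_identical(readLines(fq1), readLines(fq2))
  s3 <- simulate_donor(p, seed = 2, reference = test_ref)
  expect_false(identical(s1$truth$sequence, s3$truth$sequence))
})

test_that("truth hypomutated mass matches the configured mixture", {
  p <- donor_preset("ERA", n_reads = 10000L, igm_fraction = 0)
  sim <- simulate_donor(p, seed = 7, reference = test_ref,
                        emit_reads = FALSE)
  tr <- sim$truth
  w <- rep(tr$v_mutation_count, tr$duplicate_count)
  frac <- mean(w < 5)
  target <- p$pct_hypo / 100
  # three binomial standard errors, inflated for duplicate clustering
  se <- sqrt(target * (1 - target) / nrow(tr))
  expect_lt(abs(frac - target), 3 * se + 0.01)
  # per-read mean near the calibration target
  expect_lt(abs(mean(w) - p$mean_mut), 0.5)
})

test_that("a degenerate mixture yields constant mutation counts", {
  p <- donor_preset("HC", n_reads = 200L, igm_fraction = 0)
  p$w_hypo <- 0
  p$mu_hyper <- 10
  p$size_hyper <- Inf
  sim <- simulate_donor(p, seed = 3, reference = test_ref,
                        emit_reads = FALSE)
  expect_true(all(sim$truth$v_mutation_count == 10L))
})

test_that("plant_mutations plants exactly k substitutions", {
  germ <- test_ref$alleles[["IGHV3-23*01"]]$nt_sequence
  r0 <- plant_mutations(germ, 0, seed = 1)
  expect_identical(r0$sequence, germ)
  r3 <- plant_mutations(germ, 3, seed = 1)
  expect_equal(length(r3$positions), 3L)
  d <- sum(strsplit(germ, "")[[1]] != strsplit(r3$sequence, "")[[1]])
  expect_equal(d, 3L)
  expect_error(plant_mutations("ACGT", 5), "exceeds")
  # mutated bases always differ from germline at the planted positions
  set.seed(5)
  for (k in c(1, 10, 40)) {
    r <- plant_mutations(germ, k)
    g <- strsplit(germ, "")[[1]]; m <- strsplit(r$sequence, "")[[1]]
    expect_true(all(g[r$positions] != m[r$positions]))
    expect_equal(sum(g != m), k)
  }
})

test_that("planted mutations are recovered by annotation (round trip)", {
  germ <- test_ref$alleles[["IGHV3-23*01"]]$nt_sequence
  tail_nt <- paste0("TGTGCGAGAGATACG", "TGGGGCCAAGGAACCCTGGTCACCGTCTCCTCA",
                    test_ref$c_primers$IgG)
  for (k in c(0, 4, 13)) {
    mut <- plant_mutations(germ, k, seed = k + 1)
    contig <- paste0(mut$sequence, tail_nt)
    va <- assign_v_allele(contig, test_ref)
    expect_equal(va$v_call, "IGHV3-23*01")
    expect_equal(va$v_mutation_count, k)
    expect_equal(count_mutations(va[1, ], test_ref), k)
  }
})

test_that("emitted read pairs are FASTQ-valid and overlap by construction", {
  p <- donor_preset("HC", n_reads = 400L)
  sim <- simulate_donor(p, seed = 9, reference = test_ref)
  r <- sim$reads
  expect_equal(nrow(r$r1), nrow(r$r2))
  expect_true(all(nchar(r$r1$seq) == nchar(r$r1$qual)))
  expect_true(all(grepl("^[ACGT]+$", r$r1$seq)))
  # amplicon lengths guarantee a >= 15 bp mate overlap
  amp_len <- nchar(sim$truth$sequence)
  expect_true(all(500L - amp_len >= 15L))
  fq <- tempfile()
  write_fastq(r, fq, tempfile())
  back <- read_fastq(fq)
  expect_identical(back$seq, r$r1$seq)
})

test_that("paired compartments respect sharing and egression structure", {
  # zero sharing: no clone ids in common
  spec0 <- paired_compartment_spec(n_reads = 600L,
                                   shared_clone_fraction = 0,
                                   egression_clones = 0L)
  pc0 <- simulate_paired_compartments(spec0, seed = 4, reference = test_ref,
                                      emit_reads = FALSE)
  expect_length(intersect(pc0$blood$truth$clone_id,
                          pc0$synovium$truth$clone_id), 0L)

  # configured sharing stays below the 0.1% ceiling at scale
  spec1 <- paired_compartment_spec(n_reads = 20000L,
                                   shared_clone_fraction = 0.0005,
                                   egression_clones = 0L)
  pc1 <- simulate_paired_compartments(spec1, seed = 2, reference = test_ref,
                                      emit_reads = FALSE)
  st <- pc1$synovium$truth
  shared_reads <- sum(st$duplicate_count[st$clone_id %in%
                                           pc1$blood$truth$clone_id])
  expect_lt(shared_reads / sum(st$duplicate_count), 0.001)

  # planted egression lineages appear exactly n times with the required
  # synovium -> blood parent-child pair in truth
  spec2 <- paired_compartment_spec(n_reads = 600L, egression_clones = 2L)
  pc2 <- simulate_paired_compartments(spec2, seed = 8, reference = test_ref,
                                      emit_reads = FALSE)
  bt <- pc2$blood$truth
  kids <- bt[!is.na(bt$lineage_parent) & bt$lineage_parent != "germline", ]
  expect_equal(nrow(kids), 2L)
  parents <- pc2$synovium$truth[match(kids$lineage_parent,
                                      pc2$synovium$truth$sequence_id), ]
  expect_true(all(parents$compartment == "synovium"))
  expect_true(all(kids$v_mutation_count == parents$v_mutation_count + 1L))
  expect_error(paired_compartment_spec(shared_clone_fraction = 1.5),
               "\\[0, 1\\]")
})

test_that("airr tsv round-trips the truth table", {
  p <- donor_preset("HC", n_reads = 120L)
  sim <- simulate_donor(p, seed = 6, reference = test_ref,
                        emit_reads = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_airr(sim$truth, path)
  back <- read_airr(path)
  expect_equal(back$sequence_id, sim$truth$sequence_id)
  expect_equal(back$v_mutation_count, sim$truth$v_mutation_count)
  expect_equal(back$junction_aa, sim$truth$junction_aa)
})
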