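mk_rec <- function(counts, dup = 1L, isotype = "IgG",
                   junction_aa = NULL, v_call = "IGHV1-2*01") {
  n <- length(counts)
  if (is.null(junction_aa)) junction_aa <- sprintf("CARJ%02dW", seq_len(n))
  data.frame(
    v_mutation_count = counts,
    duplicate_count = rep_len(dup, n),
    isotype = rep_len(isotype, n),
    junction_aa = junction_aa,
    v_call = rep_len(v_call, n),
    v_gene = sub("\\*.*", "", rep_len(v_call, n)),
    v_family = rep_len("IGHV1", n),
    stringsAsFactors = FALSE
  )
}

test_that("hypomutated percentage uses a strict < 5 threshold", {
  expect_equal(pct_hypomutated(mk_rec(c(0, 1, 4, 5, 6))), 60)
  expect_equal(pct_hypomutated(mk_rec(c(5, 8, 12))), 0)
  expect_equal(pct_hypomutated(mk_rec(c(0, 1)), threshold = 0L), 0)
  expect_equal(pct_hypomutated(mk_rec(c(0, 50)), threshold = Inf), 100)
  # read-weighting by duplicate count
  r <- mk_rec(c(0, 10), dup = c(3L, 1L))
  expect_equal(pct_hypomutated(r), 75)
  expect_warning(p <- pct_hypomutated(mk_rec(numeric(0))), "undefined")
  expect_true(is.na(p))
})

test_that("skewness follows the adjusted Fisher-Pearson formula", {
  expect_equal(skewness(c(1, 2, 3)), 0)
  expect_equal(skewness(c(0, 0, 0, 1)), 2)
  x <- c(2, 3, 5, 8, 13, 21)
  expect_equal(skewness(x), -skewness(-x))
  expect_warning(s <- skewness(c(1, 2)), "n < 3")
  expect_true(is.na(s))
  expect_warning(s2 <- skewness(c(3, 3, 3, 3)), "zero variance")
  expect_true(is.na(s2))
  # independent implementation (e1071 type 2) agrees to 1e-9
  set.seed(91)
  for (i in 1:25) {
    x <- rnbinom(sample(10:200, 1), mu = 12, size = 3)
    if (var(x) == 0) next
    expect_equal(skewness(x), e1071::skewness(x, type = 2),
                 tolerance = 1e-9)
  }
})

test_that("gini index matches its printed-formula worked examples", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(1, 9)), 0.4)
  expect_equal(gini_index(5), 0)
  expect_warning(g <- gini_index(integer(0)), "undefined")
  expect_true(is.na(g))
})

test_that("gini index agrees with the mean-absolute-difference oracle", {
  set.seed(14)
  for (i in 1:200) {
    y <- sample(1:500, sample(1:60, 1), replace = TRUE)
    expect_equal(gini_index(y), gini_mad_oracle(y), tolerance = 1e-9)
    # scale invariance
    expect_equal(gini_index(y * 7L), gini_index(y), tolerance = 1e-12)
  }
  # transfer principle: moving reads to a larger clonotype raises G
  y <- c(10, 10, 10, 10)
  expect_gt(gini_index(c(15, 5, 10, 10)), gini_index(y))
  expect_gt(gini_index(c(19, 1, 10, 10)), gini_index(c(15, 5, 10, 10)))
})

test_that("mutation distributions weight reads and clones as specified", {
  r <- mk_rec(c(0, 0, 3))
  h <- mutation_distribution(r)
  expect_equal(h$weight[h$mutation_count == 0], 2)
  expect_equal(h$weight[h$mutation_count == 3], 1)
  # one clone with read counts at 2 and 4 contributes once at the mean, 3
  r2 <- mk_rec(c(2, 4), junction_aa = c("CARWX", "CARWX"))
  hc <- mutation_distribution(r2, weighting = "clone")
  expect_equal(hc$mutation_count, 3)
  expect_equal(hc$weight, 1)
  expect_warning(he <- mutation_distribution(mk_rec(numeric(0))), "empty")
  expect_equal(nrow(he), 0L)
})

test_that("v gene usage is a read-weighted percentage", {
  r <- rbind(mk_rec(rep(1, 25), v_call = "IGHV4-34*01"),
             mk_rec(rep(1, 975), v_call = "IGHV3-23*01"))
  expect_equal(v_gene_usage(r, "IGHV4-34")$pct, 2.5)
  expect_equal(v_gene_usage(r, "IGHV1-69")$pct, 0)
  expect_error(v_gene_usage(r, "TRBV9"), "unknown gene")
  fam <- v_gene_usage(r, "IGHV4-34")$family_mean_mutations
  expect_true(all(c("IGHV1") %in% names(fam)) || length(fam) >= 1)
})

test_that("motif-intact percentages count IGHV4-34 reads only", {
  r <- mk_rec(rep(1, 4), v_call = "IGHV4-34*01")
  r$avy_intact <- c(TRUE, FALSE, TRUE, TRUE)
  r$nhs_intact <- TRUE
  expect_equal(motif_intact_pct(r, "AVY"), 75)
  expect_equal(motif_intact_pct(r, "NHS"), 100)
  r2 <- mk_rec(1, v_call = "IGHV3-23*01")
  r2$avy_intact <- NA
  expect_warning(m <- motif_intact_pct(r2, "AVY"), "undefined")
  expect_true(is.na(m))
})

test_that("clonotype frequencies sum to 100 and flag dominant clones", {
  tab <- data.frame(junction_aa = c("A", "B", "C"),
                    v_call = "IGHV1-2*01",
                    read_count = c(10L, 10L, 80L),
                    v_mutation_count = c(1, 7, 3))
  cf <- clonotype_frequencies(tab)
  expect_equal(sort(cf$pct), c(10, 10, 80))
  expect_equal(sum(cf$pct), 100)
  expect_true(all(cf$dominant))
  expect_equal(cf$compartment_class[cf$read_count == 10 & cf$pct == 10],
               c("hypomutated", "hypermutated"))
  singles <- data.frame(junction_aa = letters[1:8], v_call = "x",
                        read_count = 1L)
  expect_equal(clonotype_frequencies(singles)$pct, rep(100 / 8, 8))
})

test_that("clonotype tables group by junction, allele and read weight", {
  r <- mk_rec(c(1, 1, 9), junction_aa = c("CARW", "CARW", "CARW"),
              v_call = c("IGHV1-2*01", "IGHV1-2*01", "IGHV3-23*01"))
  ct <- clonotype_table(r)
  expect_equal(nrow(ct), 2L)  # same junction, different allele separates
  ct2 <- clonotype_table(r, by_mutation_count = TRUE)
  expect_equal(nrow(ct2), 2L)
  r$duplicate_count <- c(2L, 3L, 1L)
  expect_equal(sort(clonotype_table(r)$read_count), c(1L, 5L))
})

test_that("mutation targeting profile localizes planted mutations", {
  al <- test_ref$alleles[["IGHV3-23*01"]]
  vlen <- nchar(al$nt_sequence)
  mk <- function(obs) data.frame(
    isotype = "IgG", v_call = "IGHV3-23*01", v_obs = obs,
    duplicate_count = 1L, stringsAsFactors = FALSE)
  prof0 <- mutation_targeting_profile(mk(al$nt_sequence), test_ref)
  expect_true(all(prof0 == 0))
  s <- al$nt_sequence
  old <- substr(s, 100, 100)
  substr(s, 100, 100) <- setdiff(c("A", "C", "G", "T"), old)[1]
  prof1 <- mutation_targeting_profile(rbind(mk(al$nt_sequence), mk(s)),
                                      test_ref)
  expect_equal(which(prof1 > 0), 100L)
  expect_equal(prof1[100], 0.5)
})

test_that("repertoire summary assembles the per-donor quantities", {
  d <- cached_small_donor()
  s <- repertoire_summary(d$rep)
  expect_equal(nrow(s), 1L)
  expect_true(s$pct_hypomutated >= 0 && s$pct_hypomutated <= 100)
  expect_true(s$gini >= 0 && s$gini < 1)
  expect_true(s$max_clonotype_freq > 0.5)  # planted dominant clone
  # cross-check against truth
  tr <- d$sim$truth[d$sim$truth$isotype == "IgG", ]
  w <- rep(tr$v_mutation_count, tr$duplicate_count)
  expect_equal(s$mean_mutations, mean(w), tolerance = 1e-9)
  expect_equal(s$pct_hypomutated, 100 * mean(w < 5), tolerance = 1e-9)
  expect_equal(s$skewness, e1071::skewness(w, type = 2), tolerance = 1e-9)
})
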