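mk_members <- function(seqs, compartment, muts, ids = NULL, dup = 2L) {
  data.frame(sequence = seqs,
             compartment = rep_len(compartment, length(seqs)),
             duplicate_count = rep_len(dup, length(seqs)),
             sequence_id = ids %||% sprintf("s%02d", seq_along(seqs)),
             v_mutation_count = muts,
             v_call = "X", stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# independent parsimony oracle: phangorn Fitch over all ape topologies
parsimony_oracle <- function(seqs, germline) {
  labs <- c("germ", sprintf("t%d", seq_along(seqs)))
  chars <- do.call(rbind, strsplit(c(germline, seqs), ""))
  rownames(chars) <- labs
  pd <- phangorn::phyDat(chars, type = "DNA")
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  min(vapply(trees, function(tr) phangorn::parsimony(tr, pd), 0))
}

test_that("two divergent children give a star, nested sequences a chain", {
  germ <- "ACGTACGTACGTACGTACGT"
  s1 <- "TCGTACGTACGTACGTACGT"
  s2 <- "ACGAACGTACGTACGTACGT"
  g <- build_lineage(mk_members(c(s1, s2), "blood", c(1, 1)), germ)
  expect_equal(igraph::graph_attr(g, "parsimony_score"), 2)
  df <- igraph::as_data_frame(g)
  expect_setequal(df$from, "germline")  # star from the root
  # nested: germline+1 and germline+1+1 form a chain
  s3 <- "TCGAACGTACGTACGTACGT"  # s1 plus one more substitution
  g2 <- build_lineage(mk_members(c(s1, s3), "blood", c(1, 2),
                                 ids = c("p", "c")), germ)
  expect_equal(igraph::graph_attr(g2, "parsimony_score"), 2)
  df2 <- igraph::as_data_frame(g2)
  expect_true(all(df2 == rbind(c("germline", "p"), c("p", "c"))))
})

test_that("identical duplicate sequences collapse to one node", {
  germ <- "ACGTACGTACGT"
  s <- "TCGTACGTACGT"
  rec <- mk_members(c(s, s), "blood", c(1, 1), ids = c("a", "b"),
                    dup = c(3L, 2L))
  expect_warning(g <- build_lineage(rec, germ), "single unique")
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::V(g)$duplicate_count[2], 5L)
})

test_that("parsimony equals an independent exhaustive oracle", {
  set.seed(55)
  germ <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
  for (rep in 1:12) {
    n <- sample(2:5, 1)
    seqs <- vapply(seq_len(n), function(i) {
      plant_mutations(germ, sample(1:6, 1))$sequence
    }, "")
    seqs <- unique(seqs)
    g <- build_lineage(mk_members(seqs, "blood",
                                  rep(1, length(seqs))), germ)
    expect_equal(igraph::graph_attr(g, "parsimony_score"),
                 parsimony_oracle(seqs, germ))
  }
})

test_that("heuristic trees never score worse than the star topology", {
  set.seed(56)
  germ <- paste0(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                 collapse = "")
  for (rep in 1:5) {
    n <- sample(9:12, 1)
    seqs <- unique(vapply(seq_len(n), function(i) {
      plant_mutations(germ, sample(1:10, 1))$sequence
    }, ""))
    g <- build_lineage(mk_members(seqs, "blood", rep(1, length(seqs))),
                       germ)
    star <- sum(vapply(seqs, function(s) {
      sum(strsplit(s, "")[[1]] != strsplit(germ, "")[[1]])
    }, 0))
    expect_lte(igraph::graph_attr(g, "parsimony_score"), star)
  }
})

test_that("egression calls require a synovium-to-blood transition", {
  germ <- "ACGTACGTACGTACGTACGT"
  s1 <- "TCGTACGTACGTACGTACGT"
  s2 <- "TCGAACGTACGTACGTACGT"
  # all-blood tree: no events
  gb <- build_lineage(mk_members(c(s1, s2), "blood", c(1, 2)), germ)
  expect_equal(nrow(call_egressions(gb)), 0L)
  # germline -> synovial -> blood chain: exactly one event
  ge <- build_lineage(mk_members(c(s1, s2), c("synovium", "blood"),
                                 c(1, 2), ids = c("syn", "per")), germ)
  ev <- call_egressions(ge)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$from, "syn")
  expect_equal(ev$to, "per")
  # the reverse direction (blood parent, synovial child) is not egression
  gr <- build_lineage(mk_members(c(s1, s2), c("blood", "synovium"),
                                 c(1, 2)), germ)
  expect_equal(nrow(call_egressions(gr)), 0L)
})

test_that("egression travels through inferred nodes but not observed ones", {
  germ <- strrep("A", 30)
  syn <- paste0("TT", strrep("A", 28))        # 2 mutations
  b1 <- paste0("TTCC", strrep("A", 26))       # syn + 2
  b2 <- paste0("TTGG", strrep("A", 26))       # syn + 2 (sibling branch)
  g <- build_lineage(mk_members(c(syn, b1, b2),
                                c("synovium", "blood", "blood"),
                                c(2, 4, 4), ids = c("s", "b1", "b2")), germ)
  ev <- call_egressions(g)
  # both blood leaves hang below the synovial node (directly or through an
  # inferred intermediate), so both are egression targets
  expect_setequal(ev$to, c("b1", "b2"))
  expect_true(all(ev$from == "s"))
})

test_that("suspect lineages are discarded whole", {
  germ <- "ACGTACGTACGT"
  g1 <- build_lineage(mk_members(c("TCGTACGTACGT", "TCGAACGTACGT"),
                                 "blood", c(1, 2), ids = c("a", "b")), germ)
  g2 <- build_lineage(mk_members(c("ACGTACGTACGA", "ACGTACGAACGA"),
                                 "blood", c(1, 2), ids = c("c", "d")), germ)
  trees <- list(t1 = g1, t2 = g2)
  out <- discard_suspect_lineages(trees, "c")
  expect_named(out, "t1")
  expect_equal(attr(out, "n_discarded"), 1L)
  out2 <- discard_suspect_lineages(trees, character(0))
  expect_length(out2, 2L)
  out3 <- discard_suspect_lineages(trees, c("a", "d"))
  expect_length(out3, 0L)
})

test_that("gml export round-trips node attributes", {
  germ <- "ACGTACGTACGT"
  g <- build_lineage(mk_members(c("TCGTACGTACGT", "TCGAACGTACGT"),
                                c("synovium", "blood"), c(1, 2),
                                ids = c("a", "b")), germ)
  path <- tempfile(fileext = ".gml")
  write_lineage_gml(g, path)
  back <- read_lineage_gml(path)
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_setequal(igraph::vertex_attr(back, "name"), igraph::V(g)$name)
  # GML flattens attribute-name underscores
  expect_equal(sort(igraph::vertex_attr(back, "mutationcount")),
               sort(igraph::V(g)$mutation_count))
  expect_setequal(igraph::vertex_attr(back, "tissue"), igraph::V(g)$tissue)
})

test_that("planted egression clones are recovered through the full chain", {
  spec <- paired_compartment_spec(n_reads = 700L, egression_clones = 2L)
  pc <- simulate_paired_compartments(spec, seed = 17, reference = test_ref,
                                     emit_reads = FALSE)
  mk <- function(tr) {
    tr$v_gene <- sub("\\*.*", "", tr$v_call)
    tr$j_call <- sub("\\*.*", "", tr$j_call)
    tr
  }
  trees <- lineage_trees(mk(pc$blood$truth), mk(pc$synovium$truth),
                         test_ref)
  ev <- lapply(trees, call_egressions)
  with_events <- names(trees)[vapply(ev, nrow, 0L) > 0]
  expect_length(with_events, 2L)
  # child mutation counts never decrease along edges in planted lineages
  for (g in trees) {
    df <- igraph::as_data_frame(g)
    mc <- setNames(igraph::V(g)$mutation_count, igraph::V(g)$name)
    expect_true(all(mc[df$to] >= mc[df$from]))
  }
})
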