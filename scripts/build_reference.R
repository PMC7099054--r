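#!/usr/bin/env Rscript
# Generates the bundled synthetic IGHV germline reference:
#   inst/extdata/ighv_germline_synthetic.fasta  (IMGT-gapped, '.' = gap)
#   inst/extdata/ighv_germline_synthetic.json   (region bounds, motif sites,
#                                                J segments, C-region primers)
# The reference is fully synthetic: allele names follow IMGT conventions and
# the sequences respect the IMGT positional layout (conserved Cys 23/104,
# Trp 41, family-specific gap patterns, AVY/NHS motifs on IGHV4-34), but the
# sequences themselves are generated, not curated from any database.
# Deterministic: fixed seed; re-running reproduces the committed files.

set.seed(20240301)

STOP_CODONS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")
ALL_CODONS <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
SENSE_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)

N_IMGT_AA <- 104L

# IMGT aa positions left ungapped varies by family; gap sets chosen so every
# family keeps the conserved anchors and IGHV4 keeps aa 24-26 and 57-59.
FAMILY_GAPS <- list(
  IGHV1 = c(31L, 32L, 33L, 61L),
  IGHV2 = c(32L, 33L, 60L, 61L, 62L),
  IGHV3 = c(31L, 32L, 33L, 60L, 61L, 62L),
  IGHV4 = c(31L, 32L, 33L, 73L),
  IGHV5 = c(32L, 33L, 61L, 62L),
  IGHV6 = c(73L),
  IGHV7 = c(31L, 32L, 61L)
)

GENES <- list(
  IGHV1 = c("IGHV1-2", "IGHV1-18", "IGHV1-46", "IGHV1-69"),
  IGHV2 = c("IGHV2-5", "IGHV2-70"),
  IGHV3 = c("IGHV3-7", "IGHV3-23", "IGHV3-30", "IGHV3-48"),
  IGHV4 = c("IGHV4-4", "IGHV4-34", "IGHV4-39", "IGHV4-59"),
  IGHV5 = c("IGHV5-51"),
  IGHV6 = c("IGHV6-1"),
  IGHV7 = c("IGHV7-4-1", "IGHV7-81")
)
# genes with a second allele
TWO_ALLELE_GENES <- c("IGHV1-69", "IGHV3-23", "IGHV4-34", "IGHV5-51")

# codons pinned at IMGT positions (applied after all mutation steps)
aa_constraints <- function(gene) {
  cons <- list(`1` = "CAG", `23` = "TGC", `41` = "TGG", `104` = "TGC")
  if (gene == "IGHV4-34") {
    cons[["24"]] <- "GCT"; cons[["25"]] <- "GTT"; cons[["26"]] <- "TAT"  # A V Y
    cons[["57"]] <- "AAT"; cons[["58"]] <- "CAT"; cons[["59"]] <- "AGT"  # N H S
  } else if (grepl("^IGHV4", gene)) {
    cons[["24"]] <- "GGT"; cons[["25"]] <- "CTG"; cons[["26"]] <- "AGC"  # G L S
    cons[["57"]] <- "TAT"; cons[["58"]] <- "TAC"; cons[["59"]] <- "AGT"  # Y Y S
  }
  cons
}

translate_codon <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[codon])
}

random_codons <- function(n) sample(SENSE_CODONS, n, replace = TRUE)

apply_constraints <- function(codons, imgt_pos, gene) {
  cons <- aa_constraints(gene)
  for (p in names(cons)) {
    idx <- match(as.integer(p), imgt_pos)
    stopifnot(!is.na(idx))
    codons[idx] <- cons[[p]]
  }
  codons
}

mutate_codons <- function(codons, n_codon_swaps, imgt_pos, gene) {
  protected <- match(as.integer(names(aa_constraints(gene))), imgt_pos)
  free <- setdiff(seq_along(codons), protected)
  idx <- sample(free, n_codon_swaps)
  codons[idx] <- random_codons(n_codon_swaps)
  apply_constraints(codons, imgt_pos, gene)
}

point_mutate <- function(codons, n_subs, imgt_pos, gene) {
  protected <- match(as.integer(names(aa_constraints(gene))), imgt_pos)
  nt <- strsplit(paste0(codons, collapse = ""), "")[[1]]
  free_nt <- setdiff(seq_along(nt), as.vector(outer(1:3, (protected - 1) * 3, `+`)))
  done <- 0L
  while (done < n_subs) {
    pos <- sample(free_nt, 1L)
    old <- nt[pos]
    cand <- sample(setdiff(BASES, old), 1L)
    nt2 <- nt
    nt2[pos] <- cand
    cod <- substring(paste0(nt2, collapse = ""),
                     seq(1, length(nt2), 3), seq(3, length(nt2), 3))
    if (!any(cod %in% STOP_CODONS)) {
      nt <- nt2
      done <- done + 1L
    }
  }
  substring(paste0(nt, collapse = ""), seq(1, length(nt), 3), seq(3, length(nt), 3))
}

alleles <- list()
for (fam in names(GENES)) {
  gaps <- FAMILY_GAPS[[fam]]
  imgt_pos <- setdiff(seq_len(N_IMGT_AA), gaps)
  base <- random_codons(length(imgt_pos))
  for (gene in GENES[[fam]]) {
    gene_codons <- mutate_codons(base, 15L, imgt_pos, gene)
    n_all <- if (gene %in% TWO_ALLELE_GENES) 2L else 1L
    for (a in seq_len(n_all)) {
      codons <- if (a == 1L) gene_codons else
        point_mutate(gene_codons, 4L, imgt_pos, gene)
      codons <- apply_constraints(codons, imgt_pos, gene)
      stopifnot(!any(codons %in% STOP_CODONS))
      name <- sprintf("%s*%02d", gene, a)
      alleles[[name]] <- list(
        allele_name = name, family = fam, gene = gene,
        gap_positions = gaps, imgt_positions = imgt_pos,
        codons = codons
      )
    }
  }
}

# ungapped-nt region bounds from the IMGT aa region starts
region_bounds <- function(imgt_pos) {
  starts <- c(FR1 = 1L, CDR1 = 27L, FR2 = 39L, CDR2 = 56L, FR3 = 66L)
  ends <- c(FR1 = 27L, CDR1 = 39L, FR2 = 56L, CDR2 = 66L, FR3 = 105L)
  u <- function(b) 3L * sum(imgt_pos < b)
  lapply(names(starts), function(r) c(u(starts[[r]]), u(ends[[r]]))) |>
    stats::setNames(names(starts))
}

gapped_string <- function(al) {
  out <- character(N_IMGT_AA)
  out[] <- "..."
  out[al$imgt_positions] <- al$codons
  paste0(out, collapse = "")
}

meta <- list(
  version_tag = "ighvrep-synthetic-1.0",
  alleles = lapply(alleles, function(al) {
    rb <- region_bounds(al$imgt_positions)
    motifs <- NULL
    if (al$gene == "IGHV4-34") {
      u <- function(b) 3L * sum(al$imgt_positions < b)
      motifs <- list(AVY = c(u(24L), u(24L) + 9L),
                     NHS = c(u(57L), u(57L) + 9L))
    }
    list(family = al$family, gene = al$gene,
         gap_positions = al$gap_positions,
         region_bounds = rb, motif_sites = motifs)
  }),
  j_genes = list(
    `IGHJ4*01` = list(nt = "TGGGGCCAAGGAACCCTGGTCACCGTCTCCTCA"),
    `IGHJ6*01` = list(nt = "TGGGGGCAAGGGACCACGGTGACCGTGAGCTCA")
  ),
  c_primers = list(
    IgG = "GCTTCCACCAAGGGCCCATC",
    IgM = "GGGAGTGCATCCGCCCCAAC"
  )
)

# sanity: J genes translate in frame starting at W, no stops, distinct
for (j in meta$j_genes) {
  cod <- substring(j$nt, seq(1, nchar(j$nt), 3), seq(3, nchar(j$nt), 3))
  stopifnot(cod[1] == "TGG", !any(cod %in% STOP_CODONS))
}
jd <- mapply(function(a, b) sum(a != b),
             strsplit(meta$j_genes[[1]]$nt, ""), strsplit(meta$j_genes[[2]]$nt, ""))
stopifnot(jd >= 6)

# sanity: genes are mutually distant, alleles close
seqs <- vapply(alleles, function(al) paste0(al$codons, collapse = ""), "")
ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
for (i in seq_along(seqs)) for (j in seq_along(seqs)) {
  if (i >= j) next
  if (nchar(seqs[i]) != nchar(seqs[j])) next
  d <- ham(seqs[i], seqs[j])
  same_gene <- alleles[[i]]$gene == alleles[[j]]$gene
  if (same_gene) stopifnot(d >= 1, d <= 8) else stopifnot(d >= 15)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
fa <- file("inst/extdata/ighv_germline_synthetic.fasta", "w")
for (al in alleles) {
  cat(sprintf(">%s\n%s\n", al$allele_name, gapped_string(al)), file = fa)
}
close(fa)
jsonlite::write_json(meta, "inst/extdata/ighv_germline_synthetic.json",
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)
message("wrote ", length(alleles), " alleles")
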