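#' Assign germline V alleles to contigs
#'
#' Aligns each contig against every allele of the reference (global in the
#' germline, local in the contig; match +1, mismatch -1, gap open -4, gap
#' extend -1) and returns the best-scoring allele, with ties broken by
#' fewest mismatches and then lexicographic allele name. Candidate alleles
#' are pre-screened with a 13-mer seed-and-vote filter; the survivors are
#' evaluated on their best seed diagonal with a banded affine-gap fallback.
#' Contigs whose best alignment falls below the identity floor (default 70%
#' over at least 100 nt) are left unassigned.
#'
#' @param contigs character vector of contig sequences.
#' @param ref a [load_reference()] reference.
#' @param min_identity identity floor for an assignment.
#' @param min_aln_len minimum germline length for an assignment.
#' @return data frame with one row per contig: `assigned`, `v_call`,
#'   `v_mutation_count` (substitutions plus gap events in the V),
#'   `gap_events`, `v_end` (0-based exclusive end of the V in the contig),
#'   `v_identity`, `v_obs` (observed bases over germline coordinates,
#'   `-` at deleted positions).
#' @export
assign_v_allele <- function(contigs, ref, min_identity = 0.70,
                            min_aln_len = 100L) {
  nm <- sort(names(ref$alleles))
  seqs <- vapply(ref$alleles[nm], `[[`, "", "nt_sequence")
  res <- cpp_assign_v(contigs, unname(seqs),
                      min_identity = min_identity,
                      min_aln_len = as.integer(min_aln_len))
  data.frame(
    assigned = res$assigned,
    v_call = ifelse(res$assigned, nm[res$v_idx], NA_character_),
    v_mutation_count = res$mismatches + res$gap_events,
    gap_events = res$gap_events,
    v_end = res$v_end,
    v_identity = res$identity,
    v_obs = res$v_obs,
    stringsAsFactors = FALSE
  )
}

#' Count somatic mutations in an aligned V segment
#'
#' Recomputes, from the germline-coordinate view of an alignment, the number
#' of nucleotide differences between a read and its predicted germline V
#' allele: substitutions at aligned positions plus one per indel event.
#' Positions downstream of the V (junction, J segment) are never counted.
#'
#' @param alignment one row of [assign_v_allele()] output (or a list with
#'   `v_call`, `v_obs`, `gap_events`).
#' @param ref the reference the alignment was made against.
#' @return integer mutation count.
#' @export
count_mutations <- function(alignment, ref) {
  if (is.na(alignment$v_call)) return(NA_integer_)
  germ <- charToRaw(ref$alleles[[alignment$v_call]]$nt_sequence)
  obs <- charToRaw(alignment$v_obs)
  stopifnot(length(germ) == length(obs))
  aligned <- obs != charToRaw("-") & obs != charToRaw("N")
  subs <- sum(obs[aligned] != germ[aligned])
  as.integer(subs + alignment$gap_events)
}

#' Extract the CDR3 junction from annotated contigs
#'
#' The junction runs from the conserved 2nd-CYS codon (the final codon of
#' the germline V, located from the V alignment) through the J-segment
#' tryptophan of the first in-frame W-G-x-G motif, inclusive, translated in
#' the V reading frame. Junctions with no J motif, a stop codon, a frame
#' break, or fewer than 5 amino acids are flagged nonproductive /
#' undetermined.
#'
#' @param contigs character vector of contigs.
#' @param v_end 0-based exclusive V end positions from [assign_v_allele()].
#' @param ref reference (provides J segments for the J call).
#' @return data frame: `junction`, `junction_aa`, `junction_length`,
#'   `j_call` (J gene), `productive`.
#' @export
extract_junction <- function(contigs, v_end, ref) {
  n <- length(contigs)
  jstart <- v_end - 3L   # 0-based start of the Cys codon
  tail_nt <- substr(contigs, jstart + 1L, nchar(contigs))
  keep <- nchar(tail_nt) %/% 3L * 3L
  aa <- rep(NA_character_, n)
  okt <- !is.na(keep) & keep >= 3L
  aa[okt] <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAStringSet(
      substr(tail_nt[okt], 1L, keep[okt])))))
  m <- ifelse(is.na(aa), -1L, regexpr("WG.G", aa))
  junction_aa <- ifelse(m > 0L, substr(aa, 1L, m), NA_character_)
  junction <- ifelse(m > 0L,
                     substr(contigs, jstart + 1L, jstart + 3L * m),
                     NA_character_)
  jlen <- ifelse(m > 0L, nchar(junction_aa), NA_integer_)
  productive <- !is.na(junction_aa) & jlen >= 5L &
    !grepl("[*]", junction_aa)

  # J gene: compare the segment from the junction-terminal Trp codon with
  # each bundled J
  j_call <- rep(NA_character_, n)
  jn <- names(ref$j_genes)
  hit <- which(m > 0L)
  if (length(hit)) {
    wpos <- jstart[hit] + 3L * (m[hit] - 1L) + 1L
    dmat <- vapply(jn, function(j) {
      jseq <- ref$j_genes[[j]]
      seg <- substr(contigs[hit], wpos, wpos + nchar(jseq) - 1L)
      d <- cpp_hamming(seg, rep(jseq, length(seg)))
      ifelse(d < 0L, NA_integer_, d)
    }, integer(length(hit)))
    dmat <- matrix(dmat, nrow = length(hit))
    best <- apply(dmat, 1L, function(d) {
      if (all(is.na(d))) NA_integer_ else which.min(d)
    })
    j_call[hit] <- ifelse(is.na(best), NA_character_,
                          sub("\\*.*", "", jn[best]))
  }
  data.frame(junction = junction, junction_aa = junction_aa,
             junction_length = jlen, j_call = j_call,
             productive = productive, stringsAsFactors = FALSE)
}

#' Assign isotype from the constant-region stub
#'
#' Matches the 3' constant-region stub of each contig against the IgG and
#' IgM reverse-primer sequences, allowing up to `max_mismatch` mismatches;
#' the best match wins, and contigs matching neither (or both equally
#' outside tolerance) are undetermined.
#'
#' @param contigs character vector of contigs.
#' @param ref reference carrying `c_primers`.
#' @param max_mismatch maximum primer mismatches (default 2).
#' @return character vector `"IgG"`/`"IgM"`/`NA`.
#' @export
assign_isotype <- function(contigs, ref, max_mismatch = 2L) {
  iso <- names(ref$c_primers)
  dmat <- vapply(iso, function(i) {
    p <- ref$c_primers[[i]]
    stub <- substr(contigs, nchar(contigs) - nchar(p) + 1L, nchar(contigs))
    d <- cpp_hamming(stub, rep(p, length(stub)))
    ifelse(d < 0L, NA_integer_, d)
  }, integer(length(contigs)))
  dmat <- matrix(dmat, ncol = length(iso))
  apply(dmat, 1L, function(d) {
    if (all(is.na(d))) return(NA_character_)
    b <- which.min(d)
    if (d[b] > max_mismatch) return(NA_character_)
    if (sum(d == d[b], na.rm = TRUE) > 1L) return(NA_character_)
    iso[b]
  })
}

#' Annotate merged contigs into AIRR-style rearrangement records
#'
#' Runs V assignment, mutation counting, junction extraction, J calling and
#' isotype assignment, and populates AVY/NHS motif-intactness flags for
#' IGHV4-34 calls. Contigs that cannot be assigned, lack a junction, are
#' nonproductive, or have an undetermined isotype are dropped with counted
#' reasons (attribute `drop_log`).
#'
#' @param contigs data frame from [merge_pairs()] (`pair_id`, `sequence`),
#'   or a character vector of sequences.
#' @param ref a [load_reference()] reference.
#' @param donor_id,compartment labels stored on each record.
#' @param min_identity identity floor for V assignment.
#' @return data frame of rearrangement records (one per input read,
#'   `duplicate_count = 1`) with attribute `drop_log`.
#' @export
annotate_contigs <- function(contigs, ref, donor_id = "donor",
                             compartment = "blood", min_identity = 0.70) {
  if (is.character(contigs)) {
    contigs <- data.frame(pair_id = as.character(seq_along(contigs)),
                          sequence = contigs, stringsAsFactors = FALSE)
  }
  va <- assign_v_allele(contigs$sequence, ref, min_identity = min_identity)
  drop_log <- c(unassigned_v = sum(!va$assigned))
  keep <- va$assigned
  ctg <- contigs[keep, , drop = FALSE]
  va <- va[keep, , drop = FALSE]
  jx <- extract_junction(ctg$sequence, va$v_end, ref)
  ok_j <- !is.na(jx$junction_aa)
  drop_log["no_junction"] <- sum(!ok_j)
  ok_p <- ok_j & jx$productive
  drop_log["nonproductive"] <- sum(ok_j & !jx$productive)
  iso <- assign_isotype(ctg$sequence, ref)
  ok_i <- !is.na(iso)
  drop_log["isotype_undetermined"] <- sum(ok_p & !ok_i)
  sel <- ok_p & ok_i

  rec <- data.frame(
    sequence_id = ctg$pair_id[sel],
    donor_id = donor_id,
    compartment = compartment,
    isotype = iso[sel],
    v_call = va$v_call[sel],
    j_call = jx$j_call[sel],
    junction = jx$junction[sel],
    junction_aa = jx$junction_aa[sel],
    junction_length = jx$junction_length[sel],
    v_mutation_count = va$v_mutation_count[sel],
    v_identity = va$v_identity[sel],
    duplicate_count = 1L,
    sequence = ctg$sequence[sel],
    v_obs = va$v_obs[sel],
    stringsAsFactors = FALSE
  )
  rec$v_gene <- sub("\\*.*", "", rec$v_call)
  rec$v_family <- vapply(rec$v_call,
                         function(a) ref$alleles[[a]]$family, "",
                         USE.NAMES = FALSE)
  rec$avy_intact <- NA
  rec$nhs_intact <- NA
  v434 <- which(rec$v_gene == "IGHV4-34")
  for (i in v434) {
    al <- ref$alleles[[rec$v_call[i]]]
    rec$avy_intact[i] <- translate_motif(al, rec$v_obs[i], "AVY")
    rec$nhs_intact[i] <- translate_motif(al, rec$v_obs[i], "NHS")
  }
  attr(rec, "drop_log") <- drop_log
  rec
}

#' Collapse duplicate reads within donor and compartment
#'
#' Records with identical full nucleotide sequences within a donor and
#' compartment are merged, summing `duplicate_count`. With
#' `min_duplicates = 2` (the paired blood/synovium pathway) surviving
#' singletons are removed.
#'
#' @param records rearrangement records.
#' @param min_duplicates minimum duplicate count retained (default 1).
#' @return collapsed records.
#' @export
collapse_duplicates <- function(records, min_duplicates = 1L) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$donor_id, records$compartment, records$sequence,
               sep = "\r")
  dup_sum <- rowsum(records$duplicate_count, key)
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  out$duplicate_count <- as.integer(dup_sum[match(key[first],
                                                  rownames(dup_sum)), 1L])
  out <- out[out$duplicate_count >= min_duplicates, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Donor inclusion filter on total processed reads
#'
#' A donor is excluded from cohort analyses when the repertoire holds fewer
#' than `min_reads` total reads after processing (default 25000).
#'
#' @param records rearrangement records for one donor (post-collapse).
#' @param min_reads inclusion threshold.
#' @return list with `include` (logical) and `total_reads`.
#' @export
apply_donor_filter <- function(records, min_reads = 25000L) {
  total <- sum(records$duplicate_count)
  list(include = total >= min_reads, total_reads = total)
}
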