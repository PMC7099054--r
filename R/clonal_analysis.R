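uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# connected components of Hamming<=1 links among equal-length strings.
# For the default radius 1 this buckets junctions by each single masked
# position (strings sharing a mask key differ at most at that position),
# which finds all Hamming-1 neighbor pairs in near-linear time; larger radii
# fall back to all-pairs comparison.
hamming_components <- function(junctions, max_hamming = 1L) {
  n <- length(junctions)
  parent <- uf_new(n)
  if (n <= 1L) return(rep(1L, n))
  if (max_hamming == 1L) {
    L <- nchar(junctions[1])
    for (p in seq_len(L)) {
      key <- paste0(substr(junctions, 1L, p - 1L), "\x01",
                    substr(junctions, p + 1L, L))
      buckets <- split(seq_len(n), key)
      for (b in buckets) {
        if (length(b) > 1L) {
          for (i in b[-1L]) parent <- uf_union(parent, b[1L], i)
        }
      }
    }
  } else {
    for (i in seq_len(n - 1L)) {
      d <- cpp_hamming(rep(junctions[i], n - i), junctions[(i + 1L):n])
      for (j in which(d >= 0L & d <= max_hamming)) {
        parent <- uf_union(parent, i, i + j)
      }
    }
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
}

#' Single-linkage clonal clustering
#'
#' Groups records by shared V gene, J gene and junction length, then links
#' junctions within each group at Hamming distance <= `max_hamming`
#' (default 1) on the amino-acid junction; clonal clusters are the
#' connected components (single linkage, so chains merge). Cluster indices
#' are deterministic: within each group, clusters are numbered by their
#' lexicographically smallest junction.
#'
#' @param records rearrangement records (`v_gene`, `j_call`, `junction_aa`).
#' @param max_hamming linkage radius (default 1).
#' @param junction_col which junction to cluster on (amino acid by default;
#'   `"junction"` clusters the nucleotide sequence).
#' @return list of class `clonal_cluster_set`: `records` (input plus
#'   `clone_id`), `clusters` (per-cluster summary), `n_skipped` (records
#'   without a junction).
#' @export
cluster_clones <- function(records, max_hamming = 1L,
                           junction_col = "junction_aa") {
  miss <- is.na(records[[junction_col]]) | is.na(records$v_gene) |
    is.na(records$j_call)
  n_skipped <- sum(miss)
  rec <- records[!miss, , drop = FALSE]
  jl <- nchar(rec[[junction_col]])
  gkey <- paste(rec$v_gene, rec$j_call, jl, sep = "|")
  rec$clone_id <- NA_character_
  for (g in unique(gkey)) {
    sel <- which(gkey == g)
    jx <- rec[[junction_col]][sel]
    uj <- sort(unique(jx))
    comp <- hamming_components(uj, max_hamming)
    # number components by smallest member (uj is sorted, so the first
    # occurrence order of component roots is already lexicographic)
    cid <- match(comp, unique(comp))
    rec$clone_id[sel] <- sprintf("%s|c%04d", g, cid[match(jx, uj)])
  }
  rc <- rowsum(rec$duplicate_count, rec$clone_id)
  nrec <- rowsum(rep(1L, nrow(rec)), rec$clone_id)
  clusters <- data.frame(clone_id = rownames(rc),
                         read_count = as.integer(rc[, 1L]),
                         n_records = as.integer(nrec[, 1L]),
                         stringsAsFactors = FALSE)
  structure(list(records = rec, clusters = clusters, n_skipped = n_skipped),
            class = "clonal_cluster_set")
}

#' @export
print.clonal_cluster_set <- function(x, ...) {
  cat(sprintf("clonal_cluster_set: %d records in %d clusters (%d skipped)\n",
              nrow(x$records), nrow(x$clusters), x$n_skipped))
  invisible(x)
}

#' Repertoire clonal overlap score
#'
#' Clusters the union of two samples jointly (so "shared" is well defined)
#' and returns the total number of reads, from both samples, that belong to
#' clusters containing at least one record from each sample, divided by the
#' summed read counts of the two samples. Ranges 0 (no shared clusters) to
#' 1 (identical samples); symmetric by construction.
#'
#' @param records_a,records_b rearrangement records of the two samples.
#' @param max_hamming linkage radius for the joint clustering.
#' @return numeric in \[0, 1\].
#' @export
overlap_score <- function(records_a, records_b, max_hamming = 1L) {
  if (nrow(records_a) == 0L || nrow(records_b) == 0L) {
    warning("empty sample; overlap score undefined")
    return(NA_real_)
  }
  a <- records_a; a$.sample <- "a"
  b <- records_b; b$.sample <- "b"
  cols <- intersect(names(a), names(b))
  cs <- cluster_clones(rbind(a[cols], b[cols]), max_hamming)
  rec <- cs$records
  in_a <- rowsum(as.integer(rec$.sample == "a") * rec$duplicate_count,
                 rec$clone_id)
  in_b <- rowsum(as.integer(rec$.sample == "b") * rec$duplicate_count,
                 rec$clone_id)
  shared <- in_a[, 1L] > 0L & in_b[, 1L] > 0L
  sum(in_a[shared, 1L] + in_b[shared, 1L]) /
    (sum(rec$duplicate_count[rec$.sample == "a"]) +
       sum(rec$duplicate_count[rec$.sample == "b"]))
}

#' Shared-sequence counts between two samples
#'
#' Counts unique sequences private to each sample and shared between them,
#' where two sequences are identical if they have the same CDR3 nucleotide
#' sequence and use the same V and J genes. Intended for duplicate-collapsed
#' records with the duplicate-count >= 2 filter already applied (the paired
#' blood/synovium pathway).
#'
#' @param records_a,records_b rearrangement records.
#' @return list with `private_a`, `private_b`, `shared`.
#' @export
shared_sequence_table <- function(records_a, records_b) {
  key <- function(r) unique(paste(r$junction, r$v_gene, r$j_call, sep = "|"))
  ka <- key(records_a)
  kb <- key(records_b)
  shared <- intersect(ka, kb)
  list(private_a = length(setdiff(ka, kb)),
       private_b = length(setdiff(kb, ka)),
       shared = length(shared),
       shared_keys = shared)
}

#' Pairwise clonal overlap across a cohort
#'
#' Symmetric matrix of [overlap_score()] for every donor pair.
#'
#' @param cohort named list of rearrangement-record data frames (>= 2).
#' @param max_hamming linkage radius.
#' @return symmetric numeric matrix with donor names.
#' @export
public_sharing <- function(cohort, max_hamming = 1L) {
  n <- length(cohort)
  if (n < 2L) stop("public sharing requires at least 2 donors")
  nm <- names(cohort)
  if (is.null(nm)) nm <- paste0("donor", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  diag(m) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- overlap_score(cohort[[i]], cohort[[j]],
                                          max_hamming)
    }
  }
  m
}
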