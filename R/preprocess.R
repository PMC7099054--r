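#' Quality-trim reads at the 3' end
#'
#' Removes low-quality 3' tails at a Phred threshold (default Q30). The
#' default algorithm is the BWA-style running-sum rule: walking in from the
#' 3' end accumulating `threshold - q`, the read is cut at the position where
#' the running sum is maximal (and positive); `method = "hard"` instead cuts
#' at the first base below threshold. Trimming never lengthens a read.
#'
#' @param reads data frame with `id`, `seq`, `qual` (Phred+33).
#' @param q_threshold Phred threshold (default 30).
#' @param method `"bwa"` (running sum) or `"hard"` (first sub-threshold base).
#' @return the data frame with trimmed `seq`/`qual`; reads emptied by
#'   trimming are kept with zero length (pairing decides what to drop).
#' @export
quality_trim <- function(reads, q_threshold = 30, method = c("bwa", "hard")) {
  method <- match.arg(method)
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  if (any(grepl("[^\x21-\x7E]", reads$qual))) {
    stop("malformed quality string (non Phred+33 characters)")
  }
  thr_char <- rawToChar(as.raw(q_threshold + 33L))
  # fast path: only reads containing a base below threshold need work
  pat <- sprintf("[\x21-%s]", rawToChar(as.raw(q_threshold + 32L)))
  needs <- grepl(pat, reads$qual)
  for (i in which(needs)) {
    q <- utf8ToInt(reads$qual[i]) - 33L
    L <- length(q)
    if (method == "hard") {
      bad <- which(q < q_threshold)
      cut <- if (length(bad)) bad[1] - 1L else L
    } else {
      s <- cumsum(q_threshold - rev(q))
      m <- which.max(s)
      cut <- if (s[m] > 0) L - m else L
    }
    reads$seq[i] <- substr(reads$seq[i], 1L, cut)
    reads$qual[i] <- substr(reads$qual[i], 1L, cut)
  }
  reads
}

#' Merge paired-end reads into contigs
#'
#' Reverse-complements read 2 and searches all overlap offsets between the
#' 3' end of read 1 and the 5' end of the reverse-complemented read 2,
#' choosing the offset with the lowest mismatch ratio (mismatches / overlap
#' length; ties broken toward the longest overlap). Pairs whose best overlap
#' is shorter than `min_overlap` (default 15 bp) or whose mismatch ratio is
#' `>= max_mismatch_ratio` (default 0.25) are rejected, a counted outcome
#' rather than an error. At disagreeing overlap positions the higher-quality
#' base is kept.
#'
#' @param r1,r2 data frames with `id`, `seq`, `qual` (mates in file order).
#' @param min_overlap minimum acceptable overlap in bp.
#' @param max_mismatch_ratio rejection threshold (the boundary value itself
#'   is rejected).
#' @return list with `contigs` (data frame: `pair_id`, `sequence`,
#'   `overlap_len`, `mismatch_ratio`) and `rejects` (data frame: `pair_id`,
#'   `reason`).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 15L, max_mismatch_ratio = 0.25) {
  stopifnot(nrow(r1) == nrow(r2))
  empty <- nchar(r1$seq) == 0L | nchar(r2$seq) == 0L
  res <- cpp_merge_pairs(r1$seq[!empty], r2$seq[!empty],
                         r1$qual[!empty], r2$qual[!empty],
                         as.integer(min_overlap), max_mismatch_ratio)
  ids <- r1$id[!empty]
  ok <- res$status == "merged"
  contigs <- data.frame(pair_id = ids[ok],
                        sequence = res$sequence[ok],
                        overlap_len = res$overlap_len[ok],
                        mismatch_ratio = res$mismatch_ratio[ok],
                        stringsAsFactors = FALSE)
  rejects <- data.frame(
    pair_id = c(r1$id[empty], ids[!ok]),
    reason = c(rep("empty_after_trim", sum(empty)), res$status[!ok]),
    stringsAsFactors = FALSE
  )
  list(contigs = contigs, rejects = rejects)
}

#' Trim and merge a simulated donor's read pairs
#'
#' Convenience wrapper: [quality_trim()] both mates, then [merge_pairs()].
#'
#' @param reads the `reads` element of [simulate_donor()] output.
#' @param q_threshold,min_overlap,max_mismatch_ratio passed through.
#' @export
preprocess_reads <- function(reads, q_threshold = 30, min_overlap = 15L,
                             max_mismatch_ratio = 0.25) {
  r1 <- quality_trim(reads$r1, q_threshold)
  r2 <- quality_trim(reads$r2, q_threshold)
  merge_pairs(r1, r2, min_overlap, max_mismatch_ratio)
}
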