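#' Mutation-count distribution of a repertoire
#'
#' Read-weighted histogram of V-segment mutation counts (each read
#' contributes its duplicate count), with a clone-weighted variant in which
#' each clonotype (identical CDR3 amino-acid sequence + identical V allele)
#' contributes once, at the mean mutation count of its member reads.
#'
#' @param records rearrangement records.
#' @param isotype isotype to summarize (default `"IgG"`).
#' @param weighting `"read"` or `"clone"`.
#' @return data frame with `mutation_count` and `weight`.
#' @export
mutation_distribution <- function(records, isotype = "IgG",
                                  weighting = c("read", "clone")) {
  weighting <- match.arg(weighting)
  r <- records[records$isotype == isotype, , drop = FALSE]
  if (nrow(r) == 0L) {
    warning("no ", isotype, " records; empty histogram")
    return(data.frame(mutation_count = numeric(0), weight = numeric(0)))
  }
  if (weighting == "read") {
    tab <- rowsum(r$duplicate_count, r$v_mutation_count)
    data.frame(mutation_count = as.numeric(rownames(tab)),
               weight = as.numeric(tab[, 1L]))
  } else {
    key <- paste(r$junction_aa, r$v_call, sep = "\r")
    num <- rowsum(r$v_mutation_count * r$duplicate_count, key)
    den <- rowsum(r$duplicate_count, key)
    cm <- num[, 1L] / den[, 1L]
    tab <- table(cm)
    data.frame(mutation_count = as.numeric(names(tab)),
               weight = as.numeric(tab))
  }
}

#' Percentage of reads with fewer than `threshold` V mutations
#'
#' The hypomutated fraction: 100 x (reads with mutation count below the
#' threshold) / (total reads of the isotype), read-weighted by duplicate
#' count. The default threshold of 5 counts mutation loads 0-4 as
#' hypomutated (strictly fewer than 5).
#'
#' @param records rearrangement records.
#' @param isotype isotype (default `"IgG"`).
#' @param threshold strict upper bound on the hypomutated count.
#' @return percentage in \[0, 100\] (`NA` with a warning for zero reads).
#' @export
pct_hypomutated <- function(records, isotype = "IgG", threshold = 5L) {
  r <- records[records$isotype == isotype, , drop = FALSE]
  tot <- sum(r$duplicate_count)
  if (tot == 0L) {
    warning("no ", isotype, " reads; hypomutated percentage undefined")
    return(NA_real_)
  }
  100 * sum(r$duplicate_count[r$v_mutation_count < threshold]) / tot
}

#' Adjusted Fisher-Pearson standardized moment coefficient of skewness
#'
#' G1 = sqrt(n (n-1)) / (n - 2) * m3 / m2^(3/2), with m2 and m3 the biased
#' sample moments.
#'
#' @param values numeric vector (e.g. per-read mutation counts).
#' @return skewness (`NA` with a warning for n < 3 or zero variance).
#' @export
skewness <- function(values) {
  n <- length(values)
  if (n < 3L) {
    warning("skewness undefined for n < 3")
    return(NA_real_)
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  m3 <- mean((values - m)^3)
  if (m2 == 0) {
    warning("skewness undefined for zero variance")
    return(NA_real_)
  }
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}

#' Gini index of clonotype read counts
#'
#' With the clonotype read counts y_i sorted ascending and 1-based ranks i:
#' G = 2 * sum(i * y_i) / (n * sum(y_i)) - (n + 1) / n. Zero means all
#' clonotypes hold equal read counts; values approach 1 under extreme
#' clonal dominance. Tied counts may sort in any stable order; G is
#' unchanged by tie order.
#'
#' @param counts vector of per-clonotype read counts (all >= 1), e.g. the
#'   `read_count` column of [clonotype_table()].
#' @return Gini index in \[0, 1).
#' @export
gini_index <- function(counts) {
  n <- length(counts)
  if (n == 0L) {
    warning("empty clonotype table; Gini undefined")
    return(NA_real_)
  }
  stopifnot(all(counts >= 1))
  y <- sort(counts)
  2 * sum(seq_len(n) * y) / (n * sum(y)) - (n + 1) / n
}

#' Build a clonotype table from rearrangement records
#'
#' Clonotypes group reads with identical CDR3 amino-acid sequences and
#' identical predicted germline V allele; `by_mutation_count = TRUE` adds
#' the V mutation count to the clone definition (the variant used for
#' clonotype-frequency plots split by mutation load).
#'
#' @param records rearrangement records.
#' @param isotype isotype (default `"IgG"`).
#' @param by_mutation_count include the mutation count in the key.
#' @param collapsed if `TRUE`, count unique sequences instead of reads.
#' @return data frame: `junction_aa`, `v_call` (, `v_mutation_count`),
#'   `read_count`.
#' @export
clonotype_table <- function(records, isotype = "IgG",
                            by_mutation_count = FALSE, collapsed = FALSE) {
  r <- records[records$isotype == isotype, , drop = FALSE]
  key <- paste(r$junction_aa, r$v_call, sep = "\r")
  if (by_mutation_count) key <- paste(key, r$v_mutation_count, sep = "\r")
  w <- if (collapsed) rep(1L, nrow(r)) else r$duplicate_count
  tab <- rowsum(w, key)
  parts <- strsplit(rownames(tab), "\r", fixed = TRUE)
  out <- data.frame(
    junction_aa = vapply(parts, `[`, "", 1L),
    v_call = vapply(parts, `[`, "", 2L),
    read_count = as.integer(tab[, 1L]),
    stringsAsFactors = FALSE
  )
  if (by_mutation_count) {
    out$v_mutation_count <- as.numeric(vapply(parts, `[`, "", 3L))
  }
  out[order(-out$read_count), , drop = FALSE]
}

#' V-gene usage percentage
#'
#' Read-weighted percentage of the isotype's reads whose V call maps to a
#' gene (e.g. IGHV4-34), plus a per-family mean-mutation breakdown.
#'
#' @param records rearrangement records.
#' @param gene V gene name.
#' @param isotype isotype (default `"IgG"`).
#' @return list with `pct` and `family_mean_mutations` (named vector).
#' @export
v_gene_usage <- function(records, gene = "IGHV4-34", isotype = "IgG") {
  r <- records[records$isotype == isotype, , drop = FALSE]
  known <- unique(r$v_gene)
  tot <- sum(r$duplicate_count)
  pct <- if (tot == 0L) NA_real_ else
    100 * sum(r$duplicate_count[r$v_gene == gene]) / tot
  num <- rowsum(r$v_mutation_count * r$duplicate_count, r$v_family)
  den <- rowsum(r$duplicate_count, r$v_family)
  fam <- setNames(num[, 1L] / den[, 1L], rownames(num))
  if (!gene %in% known && pct == 0) {
    # legitimate zero, but flag impossible names
    if (!grepl("^IGHV[1-7]", gene)) stop("unknown gene name: ", gene)
  }
  list(pct = pct, family_mean_mutations = fam)
}

#' Motif-intact percentage over IGHV4-34 reads
#'
#' Read-weighted percentage of IGHV4-34 reads of the isotype in which the
#' AVY (FR1) or NHS (CDR2) motif is intact at the amino-acid level.
#' Reads with indeterminate motif status (ambiguous bases) are excluded
#' from both numerator and denominator.
#'
#' @param records rearrangement records (with `avy_intact`/`nhs_intact`).
#' @param motif `"AVY"` or `"NHS"`.
#' @param isotype isotype (default `"IgG"`).
#' @return percentage (`NA` with a warning if there are no IGHV4-34 reads).
#' @export
motif_intact_pct <- function(records, motif = c("AVY", "NHS"),
                             isotype = "IgG") {
  motif <- match.arg(motif)
  col <- if (motif == "AVY") "avy_intact" else "nhs_intact"
  r <- records[records$isotype == isotype & records$v_gene == "IGHV4-34", ,
               drop = FALSE]
  r <- r[!is.na(r[[col]]), , drop = FALSE]
  tot <- sum(r$duplicate_count)
  if (tot == 0L) {
    warning("no IGHV4-34 ", isotype, " reads; motif percentage undefined")
    return(NA_real_)
  }
  100 * sum(r$duplicate_count[r[[col]]]) / tot
}

#' Per-clonotype repertoire frequencies
#'
#' Percentage of the analyzed reads carried by each clonotype, split into
#' hypomutated (mean mutation count below `threshold`) and hypermutated
#' clonotypes; clonotypes above `flag_above` percent (default 0.5) are
#' flagged.
#'
#' @param table a [clonotype_table()] (ideally `by_mutation_count = TRUE`).
#' @param threshold hypomutation threshold (default 5).
#' @param flag_above dominance flag threshold in percent.
#' @return the table with `pct`, `compartment_class`, `dominant` columns.
#' @export
clonotype_frequencies <- function(table, threshold = 5, flag_above = 0.5) {
  stopifnot(nrow(table) > 0L)
  table$pct <- 100 * table$read_count / sum(table$read_count)
  if (!is.null(table$v_mutation_count)) {
    table$compartment_class <- ifelse(table$v_mutation_count < threshold,
                                      "hypomutated", "hypermutated")
  }
  table$dominant <- table$pct > flag_above
  table
}

#' Positional mutation-targeting profile
#'
#' Frequency of mutation at each germline V position (ungapped coordinates
#' of each read's assigned allele), read-weighted and normalized by the
#' read-weighted coverage of the position.
#'
#' @param records rearrangement records retaining `v_obs`.
#' @param ref the germline reference.
#' @param isotype isotype (default `"IgG"`).
#' @return numeric vector of per-position mutation frequencies (length =
#'   longest allele; positions beyond a read's allele length contribute no
#'   coverage).
#' @export
mutation_targeting_profile <- function(records, ref, isotype = "IgG") {
  r <- records[records$isotype == isotype, , drop = FALSE]
  maxlen <- max(vapply(ref$alleles, function(a) nchar(a$nt_sequence), 0L))
  mut <- cov <- numeric(maxlen)
  if (nrow(r) == 0L) return(mut)
  germ_raw <- lapply(ref$alleles, function(a) charToRaw(a$nt_sequence))
  gap <- charToRaw("-")
  for (i in seq_len(nrow(r))) {
    g <- germ_raw[[r$v_call[i]]]
    o <- charToRaw(r$v_obs[i])
    L <- length(g)
    w <- r$duplicate_count[i]
    covered <- o != gap
    idx <- seq_len(L)
    cov[idx] <- cov[idx] + w * covered
    mm <- covered & (o != g)
    mut[idx] <- mut[idx] + w * mm
  }
  ifelse(cov > 0, mut / cov, 0)
}

#' Per-donor repertoire summary
#'
#' One row of the quantities reported per donor and isotype: mean mutation
#' count, skewness of the read-weighted mutation distribution, hypomutated
#' percentage, Gini index over clonotypes, IGHV4-34 usage, motif-intact
#' percentages and the top clonotype frequency.
#'
#' @param repertoire a `donor_repertoire` (or a records data frame).
#' @param isotype isotype (default `"IgG"`).
#' @return one-row data frame.
#' @export
repertoire_summary <- function(repertoire, isotype = "IgG") {
  records <- if (inherits(repertoire, "donor_repertoire"))
    repertoire$records else repertoire
  donor_id <- if (inherits(repertoire, "donor_repertoire"))
    repertoire$donor_id else records$donor_id[1]
  r <- records[records$isotype == isotype, , drop = FALSE]
  reads <- rep(r$v_mutation_count, r$duplicate_count)
  ct <- clonotype_table(records, isotype)
  has434 <- any(r$v_gene == "IGHV4-34")
  data.frame(
    donor_id = donor_id,
    isotype = isotype,
    total_reads = sum(r$duplicate_count),
    mean_mutations = mean(reads),
    skewness = skewness(reads),
    pct_hypomutated = pct_hypomutated(records, isotype),
    gini = gini_index(ct$read_count),
    v4_34_pct = v_gene_usage(records, "IGHV4-34", isotype)$pct,
    avy_intact_pct = if (has434) motif_intact_pct(records, "AVY", isotype)
                     else NA_real_,
    nhs_intact_pct = if (has434) motif_intact_pct(records, "NHS", isotype)
                     else NA_real_,
    max_clonotype_freq = 100 * max(ct$read_count) / sum(ct$read_count),
    stringsAsFactors = FALSE
  )
}
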