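#' @useDynLib ighvrep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Load the bundled synthetic IGHV germline reference
#'
#' Reads an IMGT-gapped germline V-allele FASTA together with its JSON
#' sidecar (region bounds, motif coordinates, J segments and constant-region
#' primer stubs) and returns a validated `germline_reference` object.
#'
#' The reference bundled with the package
#' (`ighv_germline_synthetic.{fasta,json}` under `extdata`) is fully
#' synthetic: allele names and the positional layout follow IMGT conventions
#' (conserved Cys at IMGT aa 23 and 104, Trp 41, family-specific gap
#' patterns, AVY and NHS motifs on IGHV4-34) but the sequences are generated,
#' not curated from any database. It exists so that every pipeline stage can
#' be exercised and ground-truthed without a database download.
#'
#' @param fasta_path path to the gapped FASTA; defaults to the bundled file.
#' @param json_path path to the JSON sidecar; defaults to the file next to
#'   `fasta_path` with extension `.json`.
#' @return A `germline_reference`: list with `alleles` (named list of
#'   `germline_allele`), `j_genes`, `c_primers`, `version_tag`.
#' @export
load_reference <- function(fasta_path = NULL, json_path = NULL) {
  if (is.null(fasta_path)) {
    fasta_path <- system.file("extdata", "ighv_germline_synthetic.fasta",
                              package = "ighvrep", mustWork = TRUE)
  }
  if (is.null(json_path)) {
    json_path <- sub("\\.fasta$", ".json", fasta_path)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- names(seqs)
  if (anyDuplicated(nm)) {
    stop("duplicate allele name(s) in FASTA: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  meta <- jsonlite::read_json(json_path)
  alleles <- list()
  for (i in seq_along(seqs)) {
    name <- nm[i]
    m <- meta$alleles[[name]]
    if (is.null(m)) stop("allele ", name, " missing from sidecar metadata")
    gapped <- as.character(seqs[[i]])
    ungapped <- gsub("[.\\-]", "", gapped)
    rb <- lapply(m$region_bounds, function(x) as.integer(unlist(x)))
    motifs <- NULL
    if (!is.null(m$motif_sites)) {
      motifs <- lapply(m$motif_sites, function(x) as.integer(unlist(x)))
    }
    al <- new_germline_allele(
      allele_name = name, family = m$family, gene = m$gene,
      nt_sequence = ungapped, imgt_gapped = gapped,
      region_bounds = rb, motif_sites = motifs
    )
    alleles[[name]] <- al
  }
  ref <- structure(
    list(
      alleles = alleles,
      j_genes = lapply(meta$j_genes, function(j) j$nt),
      c_primers = lapply(meta$c_primers, identity),
      version_tag = meta$version_tag
    ),
    class = "germline_reference"
  )
  validate_reference(ref)
}

new_germline_allele <- function(allele_name, family, gene, nt_sequence,
                                imgt_gapped, region_bounds, motif_sites) {
  structure(
    list(allele_name = allele_name, family = family, gene = gene,
         nt_sequence = nt_sequence, imgt_gapped = imgt_gapped,
         region_bounds = region_bounds, motif_sites = motif_sites),
    class = "germline_allele"
  )
}

validate_reference <- function(ref) {
  stopifnot(inherits(ref, "germline_reference"))
  for (al in ref$alleles) {
    degapped <- gsub("[.\\-]", "", al$imgt_gapped)
    if (!identical(degapped, al$nt_sequence)) {
      stop("gap inconsistency for allele ", al$allele_name)
    }
    len <- nchar(al$nt_sequence)
    rb <- al$region_bounds[c("FR1", "CDR1", "FR2", "CDR2", "FR3")]
    if (any(vapply(rb, is.null, TRUE))) {
      stop("incomplete region bounds for ", al$allele_name)
    }
    bounds <- unlist(rb)
    starts <- bounds[seq(1, 10, 2)]
    ends <- bounds[seq(2, 10, 2)]
    if (starts[1] != 0L || ends[5] != len || any(ends[-5] != starts[-1])) {
      stop("region bounds do not partition the V for ", al$allele_name)
    }
    if (al$gene == "IGHV4-34") {
      if (is.null(al$motif_sites$AVY) || is.null(al$motif_sites$NHS)) {
        stop("IGHV4-34 allele ", al$allele_name, " lacks AVY/NHS motif sites")
      }
      for (mi in al$motif_sites) {
        if (mi[2] - mi[1] != 9L || mi[1] %% 3L != 0L) {
          stop("motif interval on ", al$allele_name,
               " is not a codon-aligned 9 nt window")
        }
      }
    }
  }
  fams <- vapply(ref$alleles, function(a) a$family, "")
  if (length(unique(fams)) < 1L) stop("empty reference")
  ref
}

#' Write a germline reference back to FASTA + JSON
#'
#' Inverse of [load_reference()]; round-tripping reproduces the allele set.
#'
#' @param ref a `germline_reference`.
#' @param fasta_path,json_path output paths.
#' @export
write_reference <- function(ref, fasta_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.fasta$", ".json", fasta_path)
  con <- file(fasta_path, "w")
  on.exit(close(con))
  for (al in ref$alleles) {
    cat(sprintf(">%s\n%s\n", al$allele_name, al$imgt_gapped), file = con)
  }
  meta <- list(
    version_tag = ref$version_tag,
    alleles = lapply(ref$alleles, function(al) {
      list(family = al$family, gene = al$gene,
           region_bounds = al$region_bounds,
           motif_sites = al$motif_sites)
    }),
    j_genes = lapply(ref$j_genes, function(nt) list(nt = nt)),
    c_primers = ref$c_primers
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(fasta_path)
}

#' @export
print.germline_reference <- function(x, ...) {
  fams <- table(vapply(x$alleles, function(a) a$family, ""))
  cat("germline_reference [", x$version_tag, "]: ",
      length(x$alleles), " V alleles in ", length(fams), " families; ",
      length(x$j_genes), " J segments\n", sep = "")
  invisible(x)
}

# codon -> aa via the standard genetic code; NA if any base ambiguous
translate_nt <- function(nt) {
  n <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- NA_character_
  aa
}

#' Test whether a germline motif is intact in an observed sequence
#'
#' Translates the observed codons spanning an annotated motif (AVY in FR1 or
#' the NHS glycosylation site in CDR2 of IGHV4-34) and compares residues to
#' the germline motif. Intactness is evaluated at the amino-acid level, so
#' synonymous nucleotide substitutions leave a motif intact: the biology of
#' both motifs (a hydrophobic patch; an N-glycosylation sequon) is carried by
#' the residues, not the codons.
#'
#' @param allele a `germline_allele` carrying `motif_sites`.
#' @param observed_nt observed nucleotides aligned to the allele's ungapped
#'   coordinates (same length/coordinate system as `allele$nt_sequence`;
#'   `-` or `N` allowed for uncovered/ambiguous positions).
#' @param motif motif name, e.g. `"AVY"` or `"NHS"`.
#' @param sequon for `"NHS"` only: if `TRUE`, accept any N-X-S/T sequon
#'   rather than requiring the exact germline residues. Off by default.
#' @return `TRUE` if intact, `FALSE` if not, `NA` if an ambiguous base or a
#'   gap falls inside the motif window (indeterminate).
#' @export
translate_motif <- function(allele, observed_nt, motif, sequon = FALSE) {
  site <- allele$motif_sites[[motif]]
  if (is.null(site)) {
    stop("motif '", motif, "' is not annotated on allele ", allele$allele_name)
  }
  win <- substr(observed_nt, site[1] + 1L, site[2])
  if (nchar(win) < site[2] - site[1]) {
    stop("observed sequence does not cover the ", motif, " motif window")
  }
  if (grepl("[^ACGT]", win)) return(NA)
  obs_aa <- translate_nt(win)
  germ_aa <- translate_nt(substr(allele$nt_sequence, site[1] + 1L, site[2]))
  if (sequon && motif == "NHS") {
    return(obs_aa[1] == "N" && obs_aa[3] %in% c("S", "T") && obs_aa[2] != "P")
  }
  all(obs_aa == germ_aa)
}

# internal helpers used across modules -------------------------------------

allele_table <- function(ref) {
  data.frame(
    allele_name = vapply(ref$alleles, `[[`, "", "allele_name"),
    gene = vapply(ref$alleles, `[[`, "", "gene"),
    family = vapply(ref$alleles, `[[`, "", "family"),
    length = vapply(ref$alleles, function(a) nchar(a$nt_sequence), 0L),
    row.names = NULL
  )
}

allele_gene <- function(ref, allele_name) {
  ref$alleles[[allele_name]]$gene
}
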