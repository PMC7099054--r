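#' Run the full per-donor pipeline on simulated reads
#'
#' Quality-trims and merges the donor's paired reads, annotates the contigs
#' against the germline reference, and collapses duplicate sequences.
#'
#' @param sim a [simulate_donor()] result (with `reads`).
#' @param ref a [load_reference()] reference.
#' @param min_duplicates duplicate-count filter after collapsing (default 1;
#'   the paired blood/synovium pathway uses 2).
#' @param compartment compartment label (defaults to the truth table's).
#' @return list of class `donor_repertoire`: `records`, `donor_id`,
#'   `total_reads`, `drop_log`, `merge_rejects`.
#' @export
run_donor_pipeline <- function(sim, ref, min_duplicates = 1L,
                               compartment = NULL) {
  if (is.null(compartment)) compartment <- sim$truth$compartment[1]
  pp <- preprocess_reads(sim$reads)
  rec <- annotate_contigs(pp$contigs, ref, donor_id = sim$donor_id,
                          compartment = compartment)
  drop_log <- attr(rec, "drop_log")
  rec <- collapse_duplicates(rec, min_duplicates = min_duplicates)
  structure(
    list(records = rec, donor_id = sim$donor_id,
         total_reads = sum(rec$duplicate_count),
         drop_log = drop_log, merge_rejects = pp$rejects),
    class = "donor_repertoire"
  )
}

#' @export
print.donor_repertoire <- function(x, ...) {
  cat(sprintf("donor_repertoire %s: %d records, %d reads\n",
              x$donor_id, nrow(x$records), x$total_reads))
  invisible(x)
}
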