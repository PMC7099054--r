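#' @importFrom stats pnbinom rnbinom rgeom rnorm runif uniroot setNames
#' @importFrom utils head read.delim write.table
NULL

# Published group means the presets are calibrated to (percent / counts):
# hypomutated fraction of IgG reads (mutation count < 5), overall mean IgG
# mutation count, and IGHV4-34 usage. Values without a published group mean
# (ESRA/SJOGREN mean mutations and IGHV4-34 usage; the synovial hypomutated
# fraction) are fixed realistic choices documented in the methods vignette.
PRESET_TARGETS <- list(
  HC      = list(pct_hypo = 2.8,  mean_mut = 16.5,  v4_34_pct = 0.65),
  ERA     = list(pct_hypo = 12.6, mean_mut = 12.8,  v4_34_pct = 2.41),
  ESRA    = list(pct_hypo = 8.4,  mean_mut = 14.0,  v4_34_pct = 1.50),
  SJOGREN = list(pct_hypo = 8.3,  mean_mut = 14.0,  v4_34_pct = 1.00)
)

HYPO_GEOM_Q <- 0.5       # P(k) propto q^k on {0..4}
HYPER_SIZE <- 20         # negative-binomial dispersion of the SHM component

hypo_probs <- function(q = HYPO_GEOM_Q) {
  p <- q^(0:4)
  p / sum(p)
}

hypo_mean <- function(q = HYPO_GEOM_Q) sum((0:4) * hypo_probs(q))

# substitution alternatives per base
ALT_BASE <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))

substitute_bases <- function(chars, pos) {
  if (length(pos)) {
    pick <- sample.int(3L, length(pos), replace = TRUE)
    chars[pos] <- mapply(function(b, i) ALT_BASE[[b]][i], chars[pos], pick,
                         USE.NAMES = FALSE)
  }
  chars
}

# Solve the two-component somatic-hypermutation mixture so that
#   P(count < 5) = pct_hypo/100   and   E[count] = mean_mut.
# Hypomutated component: truncated geometric on {0..4}; hypermutated:
# negative binomial with mean mu and size HYPER_SIZE (whose own sub-5 mass
# is accounted for in the constraint).
solve_shm_mixture <- function(pct_hypo, mean_mut, size = HYPER_SIZE) {
  H <- pct_hypo / 100
  mh <- hypo_mean()
  w_of <- function(mu) {
    F4 <- pnbinom(4, size = size, mu = mu)
    (H - F4) / (1 - F4)
  }
  f <- function(mu) {
    w <- w_of(mu)
    w * mh + (1 - w) * mu - mean_mut
  }
  mu <- uniroot(f, c(mean_mut * 0.8, mean_mut * 1.6), tol = 1e-10)$root
  w <- w_of(mu)
  if (w < 0 || w > 1) {
    stop("infeasible mixture: pct_hypo = ", pct_hypo, ", mean = ", mean_mut)
  }
  list(w_hypo = w, mu_hyper = mu, size_hyper = size)
}

#' Donor preset for the repertoire simulator
#'
#' Returns the simulation parameters for one donor group. The somatic
#' hypermutation model is a two-component mixture per IgG read: a
#' hypomutated component (truncated geometric on 0-4 mutations) and a
#' hypermutated component (negative binomial), with the mixture weight and
#' hypermutated mean solved so that the expected fraction of reads with
#' fewer than 5 mutations and the expected mean mutation count equal the
#' group calibration targets (`HC` 2.8% hypomutated, `ERA` 12.6% and mean
#' 12.8, `ESRA` 8.4%, `SJOGREN` 8.3%; IGHV4-34 usage 0.65% for `HC`, 2.41%
#' for `ERA`). Clonotype sizes follow a truncated discrete power law
#' (exponent 2.5) with an optional planted dominant clone above 0.5% of
#' reads; read duplication counts are geometric.
#'
#' @param name one of `"HC"`, `"ERA"`, `"ESRA"`, `"SJOGREN"`.
#' @param n_reads total IgG reads per donor (default 10000).
#' @param igm_fraction additional IgM reads as a fraction of `n_reads`.
#' @param pct_hypo,mean_mut,v4_34_pct override the calibration targets.
#' @param clone_exponent power-law exponent for clone sizes.
#' @param dominant_clone_frac planted top-clone read fraction (0 disables).
#' @param dup_geom_p geometric parameter for duplication counts
#'   (P(dup = d) = p (1-p)^(d-1)).
#' @return an object of class `donor_preset`.
#' @export
donor_preset <- function(name = c("HC", "ERA", "ESRA", "SJOGREN"),
                         n_reads = 10000L, igm_fraction = 0.1,
                         pct_hypo = NULL, mean_mut = NULL, v4_34_pct = NULL,
                         clone_exponent = 2.5, dominant_clone_frac = 0.01,
                         dup_geom_p = 0.6) {
  name <- match.arg(name)
  tg <- PRESET_TARGETS[[name]]
  if (is.null(pct_hypo)) pct_hypo <- tg$pct_hypo
  if (is.null(mean_mut)) mean_mut <- tg$mean_mut
  if (is.null(v4_34_pct)) v4_34_pct <- tg$v4_34_pct
  if (n_reads < 1) stop("n_reads must be >= 1")
  mix <- solve_shm_mixture(pct_hypo, mean_mut)
  structure(
    list(name = name, n_reads = as.integer(n_reads),
         igm_fraction = igm_fraction,
         pct_hypo = pct_hypo, mean_mut = mean_mut, v4_34_pct = v4_34_pct,
         w_hypo = mix$w_hypo, mu_hyper = mix$mu_hyper,
         size_hyper = mix$size_hyper,
         igm_w_hypo = 0.75, igm_mu_hyper = 6,
         clone_exponent = clone_exponent,
         dominant_clone_frac = dominant_clone_frac,
         dup_geom_p = dup_geom_p),
    class = "donor_preset"
  )
}

#' @export
print.donor_preset <- function(x, ...) {
  cat(sprintf(
    "donor_preset %s: %d IgG reads; target %.1f%% hypomutated, mean %.1f mutations, %.2f%% IGHV4-34\n  mixture: w_hypo = %.4f, mu_hyper = %.2f (size %d)\n",
    x$name, x$n_reads, x$pct_hypo, x$mean_mut, x$v4_34_pct,
    x$w_hypo, x$mu_hyper, x$size_hyper))
  invisible(x)
}

# amino acids and a codon per aa (reverse translation draws uniformly)
AA20 <- setdiff(unique(as.character(Biostrings::GENETIC_CODE)), "*")
CODONS_BY_AA <- split(names(Biostrings::GENETIC_CODE),
                      as.character(Biostrings::GENETIC_CODE))

rev_translate <- function(aa) {
  vapply(strsplit(aa, "")[[1]], function(a) {
    cods <- CODONS_BY_AA[[a]]
    cods[sample.int(length(cods), 1L)]
  }, "") |> paste0(collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

with_seed <- function(seed, code) {
  force(seed)  # the seed expression may itself consume RNG draws
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Plant substitution mutations into a germline sequence
#'
#' Draws `k` distinct positions (uniform over the sequence, or over
#' `positions` if given) and substitutes each base with a different base.
#'
#' @param germline_nt nucleotide string.
#' @param k number of substitutions; must not exceed the available positions.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @param positions optional integer vector of candidate 1-based positions.
#' @return list with `sequence` (mutated string) and `positions` (sorted).
#' @export
plant_mutations <- function(germline_nt, k, seed = NULL, positions = NULL) {
  run <- function() {
    pool <- if (is.null(positions)) seq_len(nchar(germline_nt)) else positions
    if (k > length(pool)) stop("k exceeds the number of mutable positions")
    ch <- strsplit(germline_nt, "")[[1]]
    pos <- sort(pool[sample.int(length(pool), k)])
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
    list(sequence = paste0(ch, collapse = ""), positions = pos)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# clone sizes (in molecules): truncated discrete power law
draw_clone_sizes <- function(n_mol, exponent, smax) {
  sizes <- integer(0)
  s <- seq_len(max(smax, 2L))
  pr <- s^(-exponent)
  pr <- pr / sum(pr)
  while (sum(sizes) < n_mol) {
    sizes <- c(sizes, sample(s, 256L, replace = TRUE, prob = pr))
  }
  cum <- cumsum(sizes)
  cut <- which(cum >= n_mol)[1]
  sizes <- sizes[seq_len(cut)]
  sizes[cut] <- sizes[cut] - (cum[cut] - n_mol)
  sizes[sizes > 0L]
}

draw_mutation_counts <- function(n, w_hypo, mu, size) {
  comp <- runif(n) < w_hypo
  k <- integer(n)
  k[comp] <- sample(0:4, sum(comp), replace = TRUE, prob = hypo_probs())
  k[!comp] <- if (is.infinite(size)) round(mu) else # degenerate point mass
    rnbinom(sum(!comp), size = size, mu = mu)
  k
}

# molecules for one isotype: clone structure + per-molecule mutations
simulate_isotype <- function(preset, ref, n_reads, isotype, donor_id,
                             compartment, id_offset = 0L) {
  genes <- unique(vapply(ref$alleles, `[[`, "", "gene"))
  allele_names <- names(ref$alleles)
  gene_of <- vapply(ref$alleles, `[[`, "", "gene")
  j_names <- names(ref$j_genes)

  mean_dup <- 1 / preset$dup_geom_p
  n_mol <- max(1L, round(n_reads / mean_dup))
  smax <- max(10L, round(0.02 * n_mol))
  sizes <- draw_clone_sizes(n_mol, preset$clone_exponent, smax)
  if (preset$dominant_clone_frac > 0 && isotype == "IgG") {
    sizes <- c(max(2L, round(preset$dominant_clone_frac * n_mol)), sizes)
  }
  n_clone <- length(sizes)

  # clone-level identity
  is_v434 <- runif(n_clone) < preset$v4_34_pct / 100
  other_genes <- setdiff(genes, "IGHV4-34")
  clone_gene <- ifelse(is_v434, "IGHV4-34",
                       other_genes[sample.int(length(other_genes), n_clone,
                                              replace = TRUE)])
  clone_v <- vapply(clone_gene, function(g) {
    alls <- allele_names[gene_of == g]
    alls[sample.int(length(alls), 1L)]
  }, "")
  clone_j <- j_names[sample.int(length(j_names), n_clone, replace = TRUE)]
  jlen <- pmin(pmax(round(rnorm(n_clone, 15, 2)), 8L), 24L)
  # the junction-terminal Trp must be the first in-frame W-G-x-G; resample
  # the rare insert that would fake one upstream
  clone_insert_aa <- vapply(jlen, function(l) {
    repeat {
      ins <- paste0(sample(AA20, l - 2L, replace = TRUE), collapse = "")
      if (regexpr("WG.G", paste0("C", ins, "WGQG")) == nchar(ins) + 2L) {
        return(ins)
      }
    }
  }, "")
  clone_insert_nt <- vapply(clone_insert_aa, function(aa) {
    if (nchar(aa) == 0) "" else rev_translate(aa)
  }, "", USE.NAMES = FALSE)
  clone_junction_aa <- paste0("C", clone_insert_aa, "W")

  mol_clone <- rep.int(seq_len(n_clone), sizes)
  n_mol <- length(mol_clone)

  w <- if (isotype == "IgG") preset$w_hypo else preset$igm_w_hypo
  mu <- if (isotype == "IgG") preset$mu_hyper else preset$igm_mu_hyper
  kvec <- draw_mutation_counts(n_mol, w, mu, preset$size_hyper)

  dup <- rgeom(n_mol, preset$dup_geom_p) + 1L
  total <- cumsum(dup)
  if (total[n_mol] > n_reads) {
    keep <- which(total <= n_reads)
    if (length(keep) < n_mol) {
      last <- length(keep) + 1L
      rem <- n_reads - (if (length(keep)) total[length(keep)] else 0L)
      if (rem > 0L) {
        dup <- c(dup[keep], rem)
        idx <- c(keep, last)
      } else {
        dup <- dup[keep]; idx <- keep
      }
      mol_clone <- mol_clone[idx]; kvec <- kvec[idx]
      n_mol <- length(idx)
    }
  } else if (total[n_mol] < n_reads) {
    dup[n_mol] <- dup[n_mol] + (n_reads - total[n_mol])
  }

  v_chars <- lapply(ref$alleles, function(a) strsplit(a$nt_sequence, "")[[1]])
  seqs <- character(n_mol)
  mut_pos <- vector("list", n_mol)
  stub <- ref$c_primers[[isotype]]
  for (i in seq_len(n_mol)) {
    cl <- mol_clone[i]
    vname <- clone_v[cl]
    vch <- v_chars[[vname]]
    vlen <- length(vch)
    k <- min(kvec[i], vlen - 3L)
    kvec[i] <- k
    if (k > 0L) {
      pos <- sort(sample.int(vlen - 3L, k))  # spare the 2nd-CYS codon
      vch <- substitute_bases(vch, pos)
      mut_pos[[i]] <- pos
    } else mut_pos[[i]] <- integer(0)
    seqs[i] <- paste0(paste0(vch, collapse = ""), clone_insert_nt[cl],
                      ref$j_genes[[clone_j[cl]]], stub)
  }

  ids <- sprintf("%s_%s_%s_m%06d", donor_id, substr(compartment, 1L, 2L),
                 tolower(isotype), id_offset + seq_len(n_mol))
  clone_jnt <- vapply(seq_len(n_clone), function(cl) {
    v <- ref$alleles[[clone_v[cl]]]$nt_sequence
    paste0(substr(v, nchar(v) - 2L, nchar(v)), clone_insert_nt[cl],
           substr(ref$j_genes[[clone_j[cl]]], 1L, 3L))
  }, "")
  junction_nt <- clone_jnt[mol_clone]

  data.frame(
    sequence_id = ids,
    donor_id = donor_id,
    compartment = compartment,
    isotype = isotype,
    clone_id = sprintf("%s_%s_%s_c%04d", donor_id, substr(compartment, 1L, 2L),
                       tolower(isotype), mol_clone),
    v_call = clone_v[mol_clone],
    j_call = clone_j[mol_clone],
    junction_aa = clone_junction_aa[mol_clone],
    junction = junction_nt,
    v_mutation_count = kvec,
    mutation_positions = vapply(mut_pos, paste, "", collapse = ","),
    duplicate_count = dup,
    sequence = seqs,
    suspect = FALSE,
    lineage_parent = NA_character_,
    merge_fail = FALSE,
    lowqual_tail = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate one donor repertoire
#'
#' Generates the ground-truth molecule table for one donor under a
#' [donor_preset()] and, optionally, paired-end 250 bp reads with overlapping
#' mates. Amplicons run from the start of the germline V segment through the
#' CDR3 junction and J segment into a short isotype-identifying
#' constant-region stub, mirroring a FR1-primer/constant-primer design.
#' Identical seeds give byte-identical output.
#'
#' @param preset a [donor_preset()].
#' @param seed integer seed.
#' @param reference a [load_reference()] object.
#' @param donor_id donor label used in sequence/clone ids.
#' @param n_reads override the preset's total IgG reads.
#' @param compartment tissue label stored in the truth table.
#' @param emit_reads if `FALSE`, only the truth table is produced.
#' @param n_lowqual number of molecules given a low-quality (Q2) 3' tail on
#'   read 1 (exercises quality trimming); flagged in truth.
#' @param n_unmergeable number of molecules whose read 2 is scrambled so the
#'   pair cannot merge; flagged in truth.
#' @return list with `truth` (one row per unique molecule; AIRR-style
#'   columns) and, when `emit_reads`, `reads`: a list with `r1` and `r2`
#'   data frames (`id`, `seq`, `qual`), one row per read (duplicates
#'   emitted).
#' @export
simulate_donor <- function(preset, seed, reference = load_reference(),
                           donor_id = sprintf("%s%03d", preset$name, seed),
                           n_reads = preset$n_reads,
                           compartment = "blood", emit_reads = TRUE,
                           n_lowqual = 0L, n_unmergeable = 0L) {
  stopifnot(inherits(preset, "donor_preset"))
  if (n_reads < 1) stop("n_reads must be >= 1")
  if (preset$v4_34_pct > 0 &&
      !any(vapply(reference$alleles, `[[`, "", "gene") == "IGHV4-34")) {
    stop("preset requests IGHV4-34 usage but the reference has no IGHV4-34 allele")
  }
  with_seed(seed, {
    truth <- simulate_isotype(preset, reference, as.integer(n_reads), "IgG",
                              donor_id, compartment)
    n_igm <- round(preset$igm_fraction * n_reads)
    if (n_igm >= 1) {
      truth <- rbind(truth,
                     simulate_isotype(preset, reference, as.integer(n_igm),
                                      "IgM", donor_id, compartment))
    }
    if (n_lowqual > 0L) {
      truth$lowqual_tail[seq_len(min(n_lowqual, nrow(truth)))] <- TRUE
    }
    if (n_unmergeable > 0L) {
      idx <- nrow(truth) - seq_len(min(n_unmergeable, nrow(truth))) + 1L
      truth$merge_fail[idx] <- TRUE
    }
    out <- list(truth = truth, donor_id = donor_id, preset = preset$name)
    if (emit_reads) out$reads <- emit_read_pairs(truth)
    class(out) <- "simulated_repertoire"
    out
  })
}

# paired 250 bp reads over each molecule's amplicon, duplicates included
emit_read_pairs <- function(truth) {
  idx <- rep.int(seq_len(nrow(truth)), truth$duplicate_count)
  amp <- truth$sequence[idx]
  L <- nchar(amp)
  r1 <- substr(amp, 1L, 250L)
  r2 <- revcomp(substr(amp, pmax(L - 249L, 1L), L))
  dup_i <- sequence(truth$duplicate_count)
  ids <- sprintf("%s:%d", truth$sequence_id[idx], dup_i)
  q1 <- strrep("F", nchar(r1))
  q2 <- strrep("F", nchar(r2))
  low <- truth$lowqual_tail[idx]
  if (any(low)) {
    n1 <- nchar(r1[low])
    q1[low] <- paste0(strrep("F", n1 - 10L), strrep("#", 10L))
  }
  bad <- truth$merge_fail[idx]
  if (any(bad)) {
    r2[bad] <- vapply(nchar(r2[bad]), function(n) {
      paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, "")
  }
  list(r1 = data.frame(id = ids, seq = r1, qual = q1, stringsAsFactors = FALSE),
       r2 = data.frame(id = ids, seq = r2, qual = q2, stringsAsFactors = FALSE))
}

#' Specification for a paired blood/synovium simulation
#'
#' Calibrated to the published paired-compartment observations: the synovial
#' repertoire carries more mutations than the paired peripheral blood (group
#' means 19.65 vs 15.27), clonal sharing between compartments is nearly
#' absent (shared clones below 0.1% of synovial reads), and egression
#' lineages (a peripheral sequence descending from a synovial one) are rare
#' and planted explicitly.
#'
#' @param n_reads IgG reads per compartment.
#' @param shared_clone_fraction fraction of synovial reads in clones also
#'   seeded in blood (default 0.0005, i.e. <0.1%).
#' @param egression_clones number of planted egression lineages.
#' @param n_suspect number of shared molecules flagged as suspected index
#'   misassignment (exercises the lineage discard rule).
#' @param blood_mean,blood_pct_hypo,synovial_mean,synovial_pct_hypo
#'   per-compartment mutation targets (defaults: blood 15.27 / 8.4%,
#'   synovium 19.65 / 2%).
#' @return an object of class `paired_spec`.
#' @export
paired_compartment_spec <- function(n_reads = 5000L,
                                    shared_clone_fraction = 0.0005,
                                    egression_clones = 2L,
                                    n_suspect = 0L,
                                    blood_mean = 15.27, blood_pct_hypo = 8.4,
                                    synovial_mean = 19.65,
                                    synovial_pct_hypo = 2.0) {
  if (shared_clone_fraction < 0 || shared_clone_fraction > 1) {
    stop("shared_clone_fraction must be in [0, 1]")
  }
  blood <- donor_preset("ESRA", n_reads = n_reads, igm_fraction = 0,
                        pct_hypo = blood_pct_hypo, mean_mut = blood_mean)
  syn <- donor_preset("ESRA", n_reads = n_reads, igm_fraction = 0,
                      pct_hypo = synovial_pct_hypo, mean_mut = synovial_mean)
  structure(
    list(n_reads = as.integer(n_reads),
         shared_clone_fraction = shared_clone_fraction,
         egression_clones = as.integer(egression_clones),
         n_suspect = as.integer(n_suspect),
         blood_preset = blood, synovial_preset = syn),
    class = "paired_spec"
  )
}

#' Simulate paired blood and synovial repertoires for one donor
#'
#' Blood and synovium are drawn independently under their compartment
#' presets; a configured fraction of synovial molecules is then re-seeded
#' into blood clones (shared clones), and `egression_clones` lineages are
#' planted in which a blood sequence carries the synovial member's mutations
#' plus one extra (a synovium-to-periphery parent-child pair in truth).
#'
#' @param spec a [paired_compartment_spec()].
#' @param seed integer seed.
#' @param reference a [load_reference()] object.
#' @param donor_id donor label.
#' @param emit_reads whether to emit FASTQ-ready read pairs.
#' @return list with `blood` and `synovium` simulated repertoires.
#' @export
simulate_paired_compartments <- function(spec, seed,
                                         reference = load_reference(),
                                         donor_id = sprintf("PAIR%03d", seed),
                                         emit_reads = TRUE) {
  stopifnot(inherits(spec, "paired_spec"))
  with_seed(seed, {
    blood <- simulate_donor(spec$blood_preset, seed = sample.int(1e6, 1),
                            reference = reference,
                            donor_id = donor_id, compartment = "blood",
                            emit_reads = FALSE)
    syn <- simulate_donor(spec$synovial_preset, seed = sample.int(1e6, 1),
                          reference = reference,
                          donor_id = donor_id, compartment = "synovium",
                          emit_reads = FALSE)
    bt <- blood$truth
    st <- syn$truth

    # share: move ~shared_clone_fraction of synovial reads into blood clones
    if (spec$shared_clone_fraction > 0) {
      target_reads <- round(spec$shared_clone_fraction * sum(st$duplicate_count))
      ord <- order(st$duplicate_count)  # take singleton-scale molecules
      take <- integer(0)
      got <- 0L
      for (i in ord) {
        if (got >= target_reads) break
        take <- c(take, i)
        got <- got + st$duplicate_count[i]
      }
      if (length(take)) {
        src <- sample(seq_len(nrow(bt)), length(take), replace = TRUE)
        v_chars <- lapply(reference$alleles,
                          function(a) strsplit(a$nt_sequence, "")[[1]])
        for (j in seq_along(take)) {
          i <- take[j]; b <- src[j]
          st$clone_id[i] <- bt$clone_id[b]
          st$v_call[i] <- bt$v_call[b]
          st$j_call[i] <- bt$j_call[b]
          st$junction_aa[i] <- bt$junction_aa[b]
          st$junction[i] <- bt$junction[b]
          # rebuild sequence: germline V of the blood clone, own mutations
          vch <- v_chars[[bt$v_call[b]]]
          k <- min(st$v_mutation_count[i], length(vch) - 3L)
          pos <- if (k > 0) sort(sample.int(length(vch) - 3L, k)) else integer(0)
          vch <- substitute_bases(vch, pos)
          st$v_mutation_count[i] <- k
          st$mutation_positions[i] <- paste(pos, collapse = ",")
          tail_nt <- substr(bt$sequence[b],
                            length(v_chars[[bt$v_call[b]]]) + 1L,
                            nchar(bt$sequence[b]))
          st$sequence[i] <- paste0(paste0(vch, collapse = ""), tail_nt)
        }
        if (spec$n_suspect > 0) {
          st$suspect[take[seq_len(min(spec$n_suspect, length(take)))]] <- TRUE
        }
      }
    }

    # planted egression lineages: synovial parent, blood child with one
    # extra mutation on top of the parent's
    if (spec$egression_clones > 0) {
      v_chars <- lapply(reference$alleles,
                        function(a) strsplit(a$nt_sequence, "")[[1]])
      for (e in seq_len(spec$egression_clones)) {
        tmpl <- bt[sample.int(nrow(bt), 1L), ]
        cid <- sprintf("%s_egr_c%02d", donor_id, e)
        # a fresh clone identity: own V/J draw and a new junction, so the
        # planted lineage cannot collide with an existing clonotype
        vname <- sample(names(reference$alleles), 1L)
        jname <- sample(names(reference$j_genes), 1L)
        ins_len <- sample(10:18, 1L)
        repeat {
          ins <- paste0(sample(AA20, ins_len, replace = TRUE),
                        collapse = "")
          if (regexpr("WG.G", paste0("C", ins, "WGQG")) == ins_len + 2L) break
        }
        ins_nt <- rev_translate(ins)
        jseg <- reference$j_genes[[jname]]
        tail_nt <- paste0(ins_nt, jseg, reference$c_primers$IgG)
        tmpl$v_call <- vname
        tmpl$j_call <- jname
        tmpl$junction_aa <- paste0("C", ins, "W")
        vseq <- reference$alleles[[vname]]$nt_sequence
        tmpl$junction <- paste0(substr(vseq, nchar(vseq) - 2L, nchar(vseq)),
                                ins_nt, substr(jseg, 1L, 3L))
        vch <- v_chars[[vname]]
        vlen <- length(vch)
        k <- max(6L, rnbinom(1, size = HYPER_SIZE, mu = spec$synovial_preset$mu_hyper))
        k <- min(k, vlen - 4L)
        pos <- sort(sample.int(vlen - 3L, k))
        sch <- substitute_bases(vch, pos)
        extra <- sample(setdiff(seq_len(vlen - 3L), pos), 1L)
        pch <- substitute_bases(sch, extra)
        mk_row <- function(id, comp, ch, kk, pp, parent, dup) {
          r <- tmpl
          r$sequence_id <- id; r$compartment <- comp
          r$clone_id <- cid
          r$v_mutation_count <- kk
          r$mutation_positions <- paste(pp, collapse = ",")
          r$duplicate_count <- dup
          r$sequence <- paste0(paste0(ch, collapse = ""), tail_nt)
          r$suspect <- FALSE
          r$lineage_parent <- parent
          r
        }
        sid <- sprintf("%s_egrS%02d", donor_id, e)
        pid <- sprintf("%s_egrP%02d", donor_id, e)
        st <- rbind(st, mk_row(sid, "synovium", sch, k, pos, "germline", 3L))
        bt <- rbind(bt, mk_row(pid, "blood", pch, k + 1L,
                               sort(c(pos, extra)), sid, 2L))
      }
    }
    blood$truth <- bt
    syn$truth <- st
    if (emit_reads) {
      blood$reads <- emit_read_pairs(bt)
      syn$reads <- emit_read_pairs(st)
    }
    list(blood = blood, synovium = syn, spec = spec, donor_id = donor_id)
  })
}

# ---------------------------------------------------------------------------
# FASTQ / AIRR TSV io
# ---------------------------------------------------------------------------

#' Write simulated read pairs to FASTQ files
#' @param reads the `reads` element of a simulated repertoire.
#' @param r1_path,r2_path output FASTQ paths.
#' @export
write_fastq <- function(reads, r1_path, r2_path) {
  wr <- function(df, path) {
    writeLines(paste0("@", df$id, "\n", df$seq, "\n+\n", df$qual), path)
  }
  wr(reads$r1, r1_path)
  wr(reads$r2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read a FASTQ file into a data frame of id/seq/qual
#' @param path FASTQ path.
#' @export
read_fastq <- function(path) {
  x <- readLines(path)
  if (length(x) %% 4L != 0L) stop("malformed FASTQ: ", path)
  data.frame(id = sub("^@", "", sub(" .*", "", x[c(TRUE, FALSE, FALSE, FALSE)])),
             seq = x[c(FALSE, TRUE, FALSE, FALSE)],
             qual = x[c(FALSE, FALSE, FALSE, TRUE)],
             stringsAsFactors = FALSE)
}

#' Write / read AIRR-style rearrangement TSV
#'
#' Standard tab-separated interchange with AIRR column names
#' (`sequence_id`, `v_call`, `j_call`, `junction`, `junction_aa`,
#' `duplicate_count`, ...) plus pipeline extension columns.
#' @param df rearrangement data frame.
#' @param path TSV path.
#' @export
write_airr <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_airr
#' @export
read_airr <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
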