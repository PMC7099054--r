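---
title: "Methods: IGHV repertoire analysis with a calibrated simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IGHV repertoire analysis with a calibrated simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`ighvrep` implements a B-cell receptor heavy-chain (IGHV) amplicon analysis
pipeline: paired-end read quality trimming and overlap merging, germline
V-allele assignment with somatic-hypermutation (SHM) counting, CDR3
junction extraction and isotype calling, per-donor repertoire statistics,
single-linkage clonal clustering with repertoire overlap scores,
maximum-parsimony clonal lineage trees with synovium-to-blood egression
calling, and nonparametric cohort comparisons. A seeded repertoire
simulator with presets calibrated to published group means for early
rheumatoid arthritis (ERA), established RA (ESRA), Sjögren's syndrome and
healthy controls (HC) supplies ground truth for every stage, so the whole
pipeline is testable without sequencing data.

# The germline reference

The bundled reference (`inst/extdata/ighv_germline_synthetic.{fasta,json}`)
is **fully synthetic**: 22 V alleles across families IGHV1–IGHV7 whose
names and positional layout follow IMGT conventions (conserved Cys at IMGT
aa 23 and 104, Trp 41, family-specific gap patterns, a two-allele
IGHV4-34 gene carrying the AVY motif at IMGT aa 24–26 in FR1 and the NHS
glycosylation motif at aa 57–59 in CDR2), but whose sequences were
generated by a seeded script (`scripts/build_reference.R`), not curated
from a database. Genes within a family differ at roughly 35–45 nt and
alleles of one gene at about 4 nt, giving the aligner a realistic
assignment problem while keeping genes unambiguous. Two J segments
(starting at the J-Trp codon of the W-G-x-G motif) and 20-nt IgG/IgM
constant-region primer stubs complete the amplicon model.

All internal coordinates are 0-based half-open on the ungapped germline
sequence; IMGT positions exist only as derived metadata in the sidecar.
Motif intactness is evaluated at the amino-acid level (translate the
observed codons, compare residues), because both motifs' biology — a
hydrophobic patch, an N-glycosylation sequon — is residue-level; a
synonymous nucleotide change therefore leaves a motif intact. A stricter
N-X-S/T sequon interpretation of NHS is available via
`translate_motif(..., sequon = TRUE)` but is off by default.

# The simulator and its calibration

Each donor preset draws per-molecule SHM counts from a two-component
mixture: a *hypomutated* component, truncated geometric on {0, …, 4}
(ratio 0.5, mean ≈ 0.84), and a *hypermutated* component, negative
binomial with dispersion `size = 20`. Given a group's target hypomutated
percentage H (reads with fewer than 5 mutations) and target mean mutation
count M, the mixture weight w and hypermutated mean μ are solved so that

* w + (1 − w)·F_NB(4; μ, 20) = H/100, and
* w·0.84 + (1 − w)·μ = M,

i.e. the sub-5 mass of the hypermutated tail is part of the calibration,
not an error term. Calibration targets: HC 2.8% hypomutated, ERA 12.6%
with mean 12.8, ESRA 8.4%, Sjögren 8.3%; IGHV4-34 usage 2.41% (ERA) and
0.65% (HC). Values with no published group mean are fixed realistic
choices made once: HC mean mutation count 16.5 (healthy IgG repertoires
are the most mutated group here), ESRA/Sjögren means 14.0, ESRA IGHV4-34
usage 1.5%, Sjögren 1.0%. The paired blood/synovium specification
calibrates the compartments to means 15.27 (blood, 8.4% hypomutated) and
19.65 (synovium, 2% hypomutated — a choice reflecting the more mutated,
antigen-experienced synovial compartment).

Clone structure: clonotype sizes (in molecules) follow a truncated
discrete power law with exponent 2.5 (cap at 2% of molecules), plus one
planted dominant clone at 1% of reads so that every IgG repertoire
contains clonotypes above the 0.5% dominance threshold. Junctions are
random in-frame CDR3s (`C` + random amino acids + J-Trp), length
approximately normal with mean 15 aa, clipped to 8–24; inserts that would
fake an early in-frame W-G-x-G are resampled so junction extraction is
exactly invertible. Duplication counts are geometric (p = 0.6, mean 1.67
reads per molecule). Mutations are substitutions placed uniformly over the
V segment excluding the 2nd-CYS codon (the junction anchor is strongly
conserved in vivo); an optional hotspot weighting was considered and
rejected since positional targeting is not analyzed here. Reads are 250 bp
paired-end over the amplicon (V + junction + J + constant stub,
365–425 nt), guaranteeing mate overlap ≥ 75 bp; constant Q37 qualities,
with deliberate Q2 tails or scrambled mates available to exercise the trim
and merge failure paths.

What the simulator does **not** emulate: sequencing errors and indels,
within-clone mutation-lineage structure (each molecule's SHM count is an
independent mixture draw, so clones do not form tight mutation clusters —
which is why the clone-definition variant that includes the mutation count
fragments large simulated clones), biased V/J pairing, isotype-specific
junction repertoires, and chimeras/index hopping beyond a truth-labelled
suspect flag. Passing recovery tests therefore demonstrates correctness of
the statistics under the stated model, not robustness to platform noise.

# Preprocessing

Quality trimming is 3'-only, BWA-style: walking in from the 3' end
accumulating (30 − q), the read is cut where the running sum is maximal;
a hard cut at the first sub-Q30 base is available via `method = "hard"`.
Merging reverse-complements mate 2 and scans all overlap offsets, choosing
the offset minimizing the mismatch ratio (mismatches / overlap length),
ties resolved toward the longest overlap; disagreeing bases take the
higher-quality call. Pairs are rejected — a counted outcome, not an
error — when the best overlap is under 15 bp or the ratio is ≥ 0.25 (the
boundary value itself rejects). With error-free overlaps this selection is
exact; with errors, very short spurious exact overlaps can in principle
outcompete the true overlap, a known property of pure ratio minimization
that the error-free generator sidesteps.

# Annotation

V assignment scores every contig against every allele under match +1,
mismatch −1, gap open −4, gap extend −1, global in the germline and local
in the contig. A 13-mer seed-and-vote prescreen selects the top three
candidate alleles and their best diagonals; each candidate is evaluated
ungapped on its diagonal, with banded affine-gap dynamic programming
(half-width 5) as fallback when the ungapped identity cannot clear the 70%
assignment floor yet seed support indicates real homology (the indel
case). Ties break by fewest mismatches, then lexicographic allele name —
so a read mutated to exact equidistance between two alleles of one gene
deterministically takes the alphabetically first; gene-level calls are
unaffected. The mutation count is the number of nucleotide differences
over the aligned V segment — substitutions plus one per indel event —
and never includes the junction or J. The full V, including the
FR1-primer-binding region, is counted; excluding the primer region would
be preferable with real primers, where mismatches there are synthesis
artifacts, and is noted as a difference from any particular published
pipeline rather than a reproduction of one.

The junction is translated in the V frame from the conserved 2nd-CYS
(located by the alignment, not by sequence match — a mutated Cys codon
still anchors the junction) through the Trp of the first in-frame W-G-x-G;
junctions with no motif, a stop, a frame break, or under 5 aa are dropped
as undetermined/nonproductive. The J call is the best-Hamming J segment
from the Trp onward; the isotype is the constant-stub match within 2
mismatches. Duplicate collapsing merges identical nucleotide sequences
within donor and compartment, summing counts; the paired-compartment
pathway additionally drops sequences with duplicate count < 2. Donors with
fewer than 25,000 processed reads are flagged for exclusion from cohort
analyses (strict boundary; configurable).

# Repertoire statistics

* **Hypomutated percentage**: 100 × reads with mutation count < 5 / total
  reads, read-weighted by duplicate count (strictly fewer than 5, i.e.
  counts 0–4).
* **Skewness**: adjusted Fisher–Pearson standardized moment coefficient,
  G1 = √(n(n−1))/(n−2) · m3/m2^{3/2} with biased sample moments.
* **Gini index** over clonotype read counts (clonotype = identical CDR3
  amino-acid sequence + identical V allele): with counts sorted ascending
  and 1-based ranks, G = 2·Σ i·y_i /(n·Σ y_i) − (n+1)/n. Tie order cannot
  change G; a single clonotype gives 0 (flagged degenerate). The suite
  property-tests this rank form against the mean-absolute-difference form
  to 1e-9.
* **IGHV4-34 usage** and **motif-intact percentages** are read-weighted;
  motif status is computed only on IGHV4-34 calls, and indeterminate reads
  (ambiguous bases in the motif window) are excluded from both numerator
  and denominator.
* Read-weighted and clone-weighted mutation histograms are separate,
  explicit outputs; the clone-weighted variant assigns each clonotype the
  mean count of its member reads.
* Whether Gini should be computed before or after duplicate collapsing is
  genuinely open; the default is read-weighted, with
  `clonotype_table(..., collapsed = TRUE)` for the collapsed variant.

# Clonal clustering, overlap and sharing

Records are grouped by V gene, J gene and junction length; within a group,
junctions link at Hamming distance ≤ 1 (amino-acid junctions) and clusters
are the connected components — single linkage, so chains merge. The
implementation buckets junctions by each single masked position, which
finds all Hamming-1 pairs in near-linear time and is property-tested
against a brute-force all-pairs union-find oracle. Cluster indices are
deterministic (numbered by lexicographically smallest member).

The overlap score of two jointly clustered samples is the total number of
reads, from both samples, in clusters containing at least one record from
each, divided by the summed reads of both samples — the only reading of
the definition that attains 1 for identical samples, consistent with its
stated 0–1 range. The Venn-style shared-sequence count uses the stricter
identity CDR3 *nucleotide* sequence + V gene + J gene, on
duplicate-filtered records, matching its separate definition.

# Lineage trees and egression

Multi-compartmental clones (≥ 1 blood and ≥ 1 synovium member after the
duplicate ≥ 2 filter) are given germline-rooted maximum-parsimony trees by
Fitch counting: exhaustive search over all unrooted binary topologies up
to 7 unique sequences (10,395 topologies at 7), stepwise addition with
nearest-neighbor-interchange refinement beyond. The root sequence is the
clone's modal V germline plus the modal observed non-V tail (the junction
insert is not germline-encoded). Ancestral states are reconstructed
top-down preferring the parent state on ties; inferred nodes identical to
an observed child (or to their parent) are contracted, which is how
observed sequences become internal nodes. Correctness is tested against an
independent exhaustive oracle (phangorn Fitch over all ape topologies).

An egression event is a transition from a synovium-labelled node to a
blood-labelled node along a directed edge or a path whose intermediate
nodes are all inferred; the tissue of inferred nodes is never imputed, and
paths do not continue through observed nodes (their own transitions are
counted from their own traversal). Whether intermediate *observed* blood
nodes should also transmit an egression signal is left as an explicit
alternative; the direct-transition rule is the conservative reading. Trees
containing any sequence flagged as suspected index misassignment are
discarded whole; the flag is an input (simulator truth or a user column),
never inferred, since no operational definition of the evidence is
available. Trees export to GML (attribute names flatten underscores) and
round-trip through igraph.

# Cohort statistics

Two independent groups: Mann–Whitney U (exact for small pooled n, normal
approximation with tie correction beyond); two paired groups: Wilcoxon
signed rank; three or more: Kruskal–Wallis with Dunn's post-hoc z tests on
the joint ranks (tie-corrected). All p-values two-tailed. Multiplicity is
controlled by the Holm–Šídák step-down, implemented in-package —
adjusted_i = max_{j≤i} 1 − (1 − p_(j))^{m−j+1}, clipped to 1 — and
property-tested against a brute-force step-down oracle; the base tests
delegate to `stats::wilcox.test`/`kruskal.test`, with the small-n
Mann–Whitney contract verified against full permutation enumeration.

# Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 20 donors ×
10,000 IgG reads per preset for parameter recovery (group means fall
within the published 95% confidence intervals), 100,000+ reads for exact
mutation-count agreement, 500 random junction groups for clustering
oracle equivalence, 1,000 random tables for the Gini oracle, and 50
seeded paired simulations (2 planted egression lineages each) for
egression recall/false positives — sizes chosen as the smallest at which
the binomial sampling error of every recovered group mean sits well
inside its target interval. Tolerances: analytic identities are exact or
1e-9; stochastic recovery uses the published interval half-widths.
Degenerate inputs (empty repertoires, zero variance, single clonotypes,
single-sequence clones) warn and return `NA` or trivial objects rather
than erroring, so cohort loops never abort on an edge case.

# Known limitations

Indel handling in the V is minimal (counted as one difference per event;
never exercised by the generator); the aligner's identity floor (70%) is
untuned against real mispriming artifacts; junction extraction assumes
the amplicon retains the full V through the constant stub; lineage trees
assume equal-length member sequences (guaranteed within a cluster here,
not for arbitrary real clones with junction-length-altering indels); and
all parameter-recovery evidence is conditional on the simulator's
generative model described above.
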