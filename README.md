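# ighvrep

B-cell receptor heavy-chain (IGHV) repertoire analysis with a calibrated
repertoire simulator.

In rheumatoid arthritis and Sjögren's syndrome, a failure of B-cell
tolerance shows up in the class-switched IgG repertoire as an excess of
*hypomutated* sequences — IgG reads carrying fewer than 5 nucleotide
mutations relative to their predicted germline V segment — together with
elevated usage of the self-reactive IGHV4-34 gene and germline-intact AVY
(FR1) and NHS (CDR2) motifs. `ighvrep` implements the complete analysis
chain for such amplicon data, for computational immunologists who want
each step testable against planted ground truth:

1. **Simulation** — donor repertoires (clone-size power law, geometric
   read duplication, two-component somatic-hypermutation mixture, 250 bp
   overlapping paired-end reads) under presets calibrated to published
   group means: healthy controls 2.8% hypomutated, early RA 12.6% (mean
   12.8 mutations/read), established RA 8.4%, Sjögren's 8.3%; IGHV4-34
   usage 0.65% vs 2.41%.
2. **Preprocessing** — Q30 3' quality trimming and mate merging; pairs
   with a best overlap under 15 bp or a mismatch ratio ≥ 0.25 are
   rejected.
3. **Annotation** — germline V assignment (seed-and-vote + banded
   alignment against a bundled synthetic IMGT-style reference), mutation
   counting over the V segment, CDR3 junction extraction (Cys104 through
   the J-Trp), J and isotype calls, duplicate collapsing, 25,000-read
   donor inclusion filter.
4. **Repertoire statistics** — per-donor hypomutated percentage,
   adjusted Fisher–Pearson skewness, Gini clonality index over
   (CDR3-aa, V-allele) clonotypes

   `G = 2 Σᵢ i·y₍ᵢ₎ / (n Σᵢ y₍ᵢ₎) − (n+1)/n`  (counts sorted ascending),

   IGHV4-34 usage and motif-intact percentages, clonotype frequencies
   with >0.5% dominance flags.
5. **Clonal analysis** — single-linkage clustering at Hamming distance 1
   within V gene/J gene/junction-length groups; repertoire overlap score
   (reads in shared clusters over summed reads, range 0–1); Venn-style
   shared-sequence counts (CDR3 nucleotide + V + J identity).
6. **Lineages** — maximum-parsimony trees for multi-compartmental
   (blood + synovium) clones, rooted at the germline, with
   synovium-to-blood egression calling and GML export.
7. **Cohort statistics** — Mann–Whitney / Wilcoxon / Kruskal–Wallis +
   Dunn, two-tailed, with Holm–Šídák adjustment.

The bundled germline reference is synthetic (IMGT-style layout, not
database sequences); see the methods vignette
(`vignettes/ighv-repertoire-methods.Rmd`) for the models, calibration
equations, numerical choices and limitations.

## Worked example

```r
library(ighvrep)
ref <- load_reference()

preset <- donor_preset("ERA", n_reads = 5000L)
preset
#> donor_preset ERA: 5000 IgG reads; target 12.6% hypomutated, mean 12.8 mutations, 2.41% IGHV4-34
#>   mixture: w_hypo = 0.1186, mu_hyper = 14.41 (size 20)

sim <- simulate_donor(preset, seed = 1, reference = ref)   # reads + truth
rep <- run_donor_pipeline(sim, ref)                        # trim, merge, annotate
rep
#> donor_repertoire ERA001: 3218 records, 5500 reads

t(round(repertoire_summary(rep)[, -(1:2)], 3))
#> total_reads        5000.000
#> mean_mutations       12.514
#> skewness             -0.126
#> pct_hypomutated      14.520
#> gini                  0.478
#> v4_34_pct             2.540
#> avy_intact_pct       68.504
#> nhs_intact_pct       70.866
#> max_clonotype_freq    1.800
```

The donor's 5,000 IgG reads (plus 10% IgM, hence 5,500 total) collapse to
3,218 unique sequences; 14.5% of IgG reads carry fewer than 5 V
mutations (one seed's draw around the 12.6% ERA target), the mutation
distribution is left-skewed by that hypomutated component, 2.54% of reads
use IGHV4-34, and the planted dominant clone holds 1.8% of the
repertoire. Every number is checkable against `sim$truth`.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end at desk scale
and write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_cohorts.R` | simulate all four donor groups, record truth group means, write example FASTQ |
| `02_repertoire_statistics.R` | full pipeline per donor; per-donor summary CSV |
| `03_clonal_structure.R` | Gini by hypo/hypermutated compartment, dominant clonotypes, public-sharing matrix |
| `04_paired_compartments_lineages.R` | paired blood/synovium means, shared sequences, lineage trees + egression events (GML) |
| `05_cohort_comparisons.R` | nonparametric group comparisons with Holm–Šídák adjustment |

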