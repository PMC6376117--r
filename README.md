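# circmine

Detection and characterisation of exonic circular RNAs (circRNAs) from
paired-end RNA-seq, for transcriptomics researchers studying circRNA
biogenesis and function.

Back-splicing joins the 3' end of a downstream exon (donor) to the 5'
end of an upstream exon (acceptor), producing a covalently closed RNA
circle. The only direct sequence evidence for a circRNA is a read that
crosses this back-splice junction. circmine implements:

* **Detection** — an annotation-anchored back-splice junction library
  (every exon pair *a ≤ d* per transcript) searched by exact /
  mismatch-tolerant string matching, with linear-transcriptome
  subtraction, ≥ 8 nt anchors either side of the junction point, a
  unique-best-junction rule, and verification that the mate lies inside
  the anticipated circle. Counts are normalised to **JPM** (junction
  reads per million mapped): JPM = pairs / (mapped/10⁶), retained at
  mean JPM ≥ 0.1 per cell type, with a polysome-fraction rescue rule.
* **Matched reference sets** — cell-specific (FPKM ≥ 1), non-circ,
  exon-count/gene-length/expression-adjusted (seeded nearest-neighbour
  matching) and position-adjusted (largest-remainder allocation) control
  sets.
* **Structural statistics** — acceptor/donor positional profiles
  normalised to exon frequency, circle exon-span histograms, exon and
  intron length tables under inclusive cognate-isoform assignment, all
  compared by the two-sided Mann–Whitney U test.
* **Polysome fractions** — per-fraction JPM matrices, the calculated
  free pool Free\* = 9 × total − Σ(fractions 1..8), inclusive
  translation-candidate (tc-circRNA) selection at mean fraction JPM
  ≥ 0.1, a circular ORF scanner (AUG/CUG/GUG starts, up to three passes
  of the circle, infinite-loop detection), m6A overlap, and
  proportion-test feature enrichment.
* **miRNA sponge scoring** — exact seed matches (reverse complement of
  miRNA positions 2–7) over the circular sequence including the
  junction wrap, AGO-footprint support (≥ 50% of the ~20-nt site within
  a ±10 nt–extended footprint), per-circRNA and per-seed collective
  summaries.
* **NET-seq Pol II dwell analysis** — replicate averaging, per-nt
  capping at 10, Pol II/nt region densities, position-adjusted
  comparisons and exon-scaled metagene profiles with 300-nt flanks.
* **A deterministic synthetic-data generator** — toy genomes with
  planted circRNAs (acceptor bias at ordinal 2, span peak at 2, 5×
  flanking introns), paired-end reads with truth-tagged IDs, nine
  sedimentation libraries, NET-seq coverage with boundary stalls, and
  planted AGO/seed-match/m6A sites — so the entire pipeline runs and is
  testable without any downloads.

## Worked example

Simulate the default toy study (20 genes, 10 planted circRNAs, 50,000
error-free read pairs) and run the full detection path:

```r
library(circmine)
run <- run_toy_pipeline(seed = 1)
run$recall;  run$precision
#> [1] 1
#> [1] 1
run$records[order(-jpm)][1:3, .(key, gene, acceptor_ordinal, donor_ordinal, n_pairs, jpm)]
#>                      key   gene acceptor_ordinal donor_ordinal n_pairs  jpm
#> 1: chrS1:141534:141708:+   G007                2             2     275 2750
#> 2: chrS1:320265:321912:+   G017                5             6     205 2050
#> 3: chrS1:258112:258565:-   G014                2             3     197 1970
```

All ten planted junctions are recovered with no false calls (recall and
precision 1). JPM values are large because the toy library is small —
275 verified junction pairs in 10⁵ mapped reads is 2,750 JPM. The
acceptor-position profile, normalised to exon frequency, peaks at the
second transcribed exon, the planted (and biologically expected)
signature:

```r
run$acceptor_profile
#>    position count exon_count ratio frequency
#> 1:        1     0         10   0.0       0.0
#> 2:        2     7         10   0.7       0.7
#> 3:        3     0         10   0.0       0.0
#> 4:        4     1         10   0.1       0.1
#> 5:        5     2         10   0.2       0.2
```

Scanning the first detected circle for open reading frames:

```r
orfs <- find_circ_orfs(circle_sequence(run$sim, run$sim$truth[1]))
orfs[1:2]
#>    start codon   context frame stop_pos n_codons infinite_loop crosses_junction
#> 1:     1   ATG GCCATGGAC     0       37       13         FALSE            FALSE
#> 2:     6   CTG GGACTGCGG     2       15        4         FALSE            FALSE
```

A command-line wrapper over the same functions lives in
`inst/scripts/circmine.R` (`simulate` writes a complete synthetic
dataset as FASTA/RefFlat/FASTQ/bedGraph/BED/TSV; `detect` runs the
pipeline and writes the circRNA table plus truth evaluation).

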