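---
title: "Methods: detecting and characterising exonic circRNAs with circmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and characterising exonic circRNAs with circmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circmine)
library(data.table)
```

## The problem

Exonic circular RNAs (circRNAs) arise when the spliceosome joins the 3'
end of a downstream exon (the *donor*) to the 5' end of an upstream exon
(the *acceptor*), producing a covalently closed circle. In paired-end
RNA-seq a circRNA is visible only through reads that cross its
back-splice junction: a sequence join that cannot occur on any linear
transcript. circmine implements an annotation-anchored caller for such
junctions and the downstream analyses used to characterise circRNA
biogenesis and candidate functions: matched reference gene/feature sets,
positional and length statistics of circRNA-producing loci,
polysome-fraction analysis for translation candidates, AGO-anchored
miRNA seed-match (sponge) scoring, and RNA polymerase II dwell-time
analysis from NET-seq coverage.

Real datasets of this kind run to tens or hundreds of millions of read
pairs. The package therefore ships a deterministic synthetic-data
generator that plants circRNAs with known coordinates and abundances in
a toy genome, so that every stage of the pipeline can be run, inspected
and tested end-to-end in seconds.

## Detection model

The caller never discovers junctions de novo. It enumerates every
candidate back-splice junction implied by the annotation — all exon
pairs (acceptor ordinal $a$, donor ordinal $d$) with $a \le d$ within
each transcript — and builds, for each, a junction sequence: the donor
exon's 3'-terminal $k$-mer followed by the acceptor exon's 5'-terminal
$k$-mer in transcript orientation (flanks truncated when an exon is
shorter than $k$). Candidates sharing a junction key
(chromosome, circle start, circle end, strand) across isoforms are
merged.

A read pair contributes to a circRNA call when all of the following
hold:

1. **Not linear.** The pair is discarded if both reads match a spliced
   transcript or the genome contiguously, in either orientation, within
   the mismatch budget.
2. **Junction hit.** One read matches a junction sequence with at least
   `min_anchor` nucleotides on *each* side of the junction point and at
   most `max_mismatches` substitutions.
3. **Uniqueness.** A read whose best matches name more than one junction
   key is discarded.
4. **Mate inside the circle.** The other read must match the circular
   spliced sequence (searched in its doubled form, so mates that
   themselves cross the junction also verify).

Matching is plain string search: exact membership via Aho–Corasick
dictionaries, with a seed-and-extend fallback for the mismatch-tolerant
path (a read within $m$ substitutions of a window must share one of
$m+1$ exact segments with it). This keeps the pipeline self-contained —
no external aligner — while enforcing exactly the annotation-anchored
verification the method requires.

Counts are normalised to **JPM** (junction reads per million mapped
reads): $\mathrm{JPM} = c / (M/10^6)$ for $c$ verified pairs and $M$
mapped reads in the sample. A circRNA is retained when its mean JPM
across a cell type's samples is $\ge$ 0.1 (inclusive), or — when
polysome-fraction data are available — when its mean JPM across the
eight ribosomal fractions reaches the same threshold (the rescue rule).

Key parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `k` | `read_length - min_anchor` | junction flank length (nt); any junction-spanning read with valid anchors fits in the library entry |
| `min_anchor` | 8 nt | matched length required either side of the junction point |
| `max_mismatches` | 1 | substitutions tolerated per read |
| `jpm_threshold` | 0.1 JPM | inclusive abundance cutoff |

The anchor and uniqueness rules are explicit package choices: the
original analyses delegated them to an aligner's internals, which are
not reproducible in a self-contained reimplementation. Candidate
junctions include first/last exons; mis-assignments to ordinal 1 are
reported rather than forbidden. Skipping of internal exons within a
circle is not modelled.

## Reference sets

Every comparison is made against a matched control:

* **cell-specific** — genes with mean FPKM $\ge 1$ (FPKM computed on the
  union of exons across isoforms; how the original quantifier
  apportioned multi-isoform reads is not documented, so the
  deterministic union-length definition is used and stated here);
* **non-circ** — cell-specific genes minus circRNA-producing genes;
* **exon-count / gene-length / expression-adjusted** — pool genes drawn
  without replacement, each target matched to its nearest-property
  neighbour, ties broken by a seeded shuffle. The construction is a pure
  function of (pool, targets, seed) and reports achieved vs target
  means. Sampling *with* replacement is available as an explicit error
  suggestion when the pool is exhausted;
* **position-adjusted** — features drawn per ordinal position with
  largest-remainder count allocation, so the achieved distribution
  matches the target within one feature per position.

"Randomly selected to match" admits many schemes; nearest-neighbour
without replacement was chosen because it is reproducible, reports its
matching error, and cannot silently drift.

## Structural statistics

Ordinal positions are strand-aware: exon 1 is the 5'-most transcribed
exon, and intron $N$ lies between exons $N$ and $N+1$. Acceptor/donor
positional profiles divide the count of back-splice ends at each ordinal
position by the number of annotated exons existing at that position,
then rescale the ratios to sum to one — the second division is
interpreted as normalisation over occupied positions, which makes the
profile invariant to uniform scaling of exon counts. Because the true
source isoform of a circRNA is generally unknowable, every annotated
isoform whose exons cover the circle span contributes one
(circRNA, isoform) observation — the inclusive assignment; its known
side effect is a low rate of spurious ordinal-1 acceptor calls.

Length tables follow the molecule-class × role × kind layout
(single-/multi-exon circRNA; acceptor/internal/donor; exon/intron), with
flanking introns defined in transcription order (upstream of the
acceptor exon; downstream of the donor exon). References use internal
features only (first and last exons removed). All distributional
comparisons use the two-sided Mann–Whitney U test: `stats::wilcox.test`
with exact enumeration when $n_1+n_2 \le 16$ without ties, otherwise the
normal approximation with continuity correction; fully tied degenerate
inputs return $P = 1$. The test suite checks the implementation against
a from-scratch enumeration of all $\binom{n_1+n_2}{n_1}$ labelings.

## Polysome fractions and circular ORFs

Each of the nine libraries (total cytoplasmic + fractions 1–8,
monosome through octasome-plus) is normalised with its own mapped total.
The calculated free pool is

$$\mathrm{Free}^{*} = 9 \times \mathrm{total} - \sum_{i=1}^{8} f_i,$$

implemented exactly as printed (the ×9 factor is retained verbatim;
equalising depth across the nine libraries is the presumed but unstated
rationale). Negative values are flagged and floored at zero in reports.
Translation candidates (tc-circRNAs) are circRNAs whose mean JPM over
the eight fractions is $\ge$ 0.1, inclusive; the total column plays no
part.

The circular ORF scanner treats the spliced exonic sequence as a circle
with the back-splice junction between its last and first nucleotide.
Every AUG and near-cognate CUG/GUG start (the union is the default and
is configurable) is walked codon-by-codon for at most three full passes
of the circle; the first in-frame UAG/UAA/UGA terminates the ORF, and a
start with no stop within three passes is an *infinite-loop* ORF — only
possible when the circle length is divisible by three, since otherwise
the frame drifts through all three registers. ORFs whose walk passes the
junction are flagged. The scanner is validated against a brute-force
triple-concatenation linear scan on 1,000 random circles of 30–300 nt.

## Sponge scoring

Seed matches are exact reverse complements of miRNA positions 2–7
(Watson–Crick only, no G:U), scanned over the circular sequence with the
first five nucleotides appended so junction-spanning matches are found;
overlapping matches count at their distinct start positions. A predicted
target site is the ~20-nt region centred on the hexamer (7-nt flanks by
default) and is AGO-supported when at least 50% of it overlaps an AGO
footprint extended by 10 nt on each side; junction-spanning sites are
scored by their best genomic arm. The thermodynamics-based
hybridisation pre-filter used upstream in the original workflow is
deliberately out of scope: the seed and AGO filters are the decisive
criteria, and a hook for an external duplex-energy scorer can be layered
on top of the returned match table. RBP footprints are assigned to an
exon class when $\ge 75\%$ of the footprint overlaps it; per protein,
the proportion of exons bearing at least one footprint is compared
between circularised and non-circularised exons with a
continuity-corrected two-sample proportion test (raw site counts can
exceed exon counts and are reported alongside).

## NET-seq dwell analysis

NET-seq signal per nucleotide is read as a surrogate for Pol II dwell
time (inverse elongation speed). The pipeline order is fixed: average
the two replicates positionwise (missing positions contribute zero),
cap per-nucleotide counts at 10, then measure. The cap guards region
means against rare extreme loci; whether the original capping acted per
nucleotide or per feature region is ambiguous, and the per-nucleotide
reading was chosen and is configurable. Region density is summed signal
over length ("Pol II/nt"). Table-style comparisons test circRNA exons
and introns against position-adjusted reference features with the
rank-sum test. Metagene profiles scale each exon to a fixed number of
bins by length-weighted linear rebinning (fractional nucleotides split
proportionally, so a constant track stays exactly constant) and
aggregate 300 nt of flanking intron at natural scale from the exon edge
in transcription direction; flank positions that run off the chromosome
are excluded from the mean rather than zero-filled.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume:

* multi-exon genes (5+ exons, Poisson-distributed) with lognormal
  internal exons (~120 nt median), longer terminal exons, lognormal
  introns (~800 nt) with an inflated first intron — typical mammalian
  architecture;
* planted circRNAs with acceptor positions biased to ordinal 2, exon
  spans peaked at 2, and both flanking introns inflated 5-fold — the
  qualitative signatures the structural analyses should recover;
* paired-end reads drawn from spliced linear transcripts and from the
  circular sequences (junction-crossing reads arise naturally from the
  fragment model); read IDs carry the ground-truth class so detector
  output can be scored without alignment;
* nine sedimentation libraries under per-class loading models, with
  circRNA mass concentrated in the low (mono- to tetrasome) fractions
  and the residue forming the free pool sampled only by the total
  library;
* NET-seq coverage as Poisson noise around gene rate × dwell, with
  exon/intron dwell factors, boundary stall bumps and optional
  positional acceleration, two independently seeded replicates;
* planted miRNA seed matches with and without covering AGO footprints
  (including one junction-spanning match), plus m6A sites.

The default configuration — 20 genes, 10 planted circRNAs, 50,000
error-free read pairs, each circle leaving well over 20
junction-crossing pairs — is the study condition for the detector tests;
the structural and NET-seq recovery experiments use 60 genes with 30 and
20 planted circRNAs respectively, sizes at which the planted signatures
are statistically identifiable while the whole suite runs in minutes on
one CPU. Every random draw is governed by a single master seed (fixed
offsets separate the generator stages), so all outputs are byte-identical
across runs and platforms.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: sequencing errors beyond uniform
substitutions (no quality-dependent or indel errors), alignment
ambiguity from repeats and paralogues, reverse-complementary intronic
motifs and RBP-driven looping kinetics, RNA editing, isoform-rich
annotations (one isoform per gene by default), and library-preparation
biases. Detector recall/precision of 1.0 on the simulation bounds
implementation correctness, not performance on real libraries.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GTF/GRanges
  conversions happen in one helper pair, preventing off-by-one drift.
* Inclusive thresholds throughout (`>=` at 0.1 JPM and 1 FPKM), tested
  at the boundary.
* Mann–Whitney and proportion tests return $P = 1$ on fully degenerate
  (zero-variance) inputs instead of NaN.
* Junction keys are plain strings (`chrom:start:end:strand`), unique by
  construction; ties in matched sampling are broken by a seeded shuffle
  so set construction is reproducible.
* A planted circle shorter than the read length is skipped with a
  warning; empty inputs yield empty, correctly-typed tables rather than
  errors wherever the operation is total.

## Limitations

The caller is annotation-anchored: junctions outside the supplied gene
models are invisible, as are intron-retaining (EIciRNA) and fusion
transcripts. The uniqueness rule is a package-level stand-in for
aligner-internal filtering. FPKM apportionment across isoforms is the
union-exon simplification. Thermodynamic miRNA-target hybridisation and
conservation-based target scoring are not implemented. NET-seq reads are
consumed as coverage tracks; no FASTQ-level nascent-RNA processing is
attempted.
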