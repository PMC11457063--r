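---
title: "Quantifying regulatory architecture from ATAC-seq peaks"
author: "peakarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regulatory architecture from ATAC-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakarch)
```

## The question the package answers

Genes differ in how their accessibility landscape is organised. Broadly
expressed "housekeeping-like" genes tend to carry a single accessible
region at the transcription start site (TSS), while developmentally dynamic
genes often carry complex landscapes of several distal elements in introns
and intergenic space. Cell cycle genes are an instructive case: during
terminal differentiation they are transcriptionally repressed, yet most of
them retain a simple, promoter-proximal accessible region — consistent with
continued occupancy by repressive complexes (the E2F/DREAM axis) rather
than enhancer decommissioning.

`peakarch` turns that comparison into a tested, reusable pipeline. Given
replicate ATAC-seq peak calls across tissues and ordered developmental time
points, a gene annotation, and a gene set of interest, it asks: **does the
gene set's regulatory architecture differ from the genome-wide
background?** Architecture is measured two ways:

1. the *genomic-feature distribution* of peaks (promoter / exon / intron /
   downstream / intergenic), and
2. the *peaks-per-gene* distribution (genes binned by how many peaks are
   assigned to them; a single peak means "simple", many peaks "complex").

Both comparisons carry non-parametric bootstrap confidence intervals, and a
pair of proportions is flagged significant when the intervals do not
overlap. Companion stages classify transcriptionally repressed genes over
the time course, partition peaks by housekeeping (HK) versus developmental
(DEV) enhancer-class overlap, and draw average accessibility metaprofiles.

## Pipeline model and assumptions

**Consensus peaks.** For each tissue × time point, the union of replicate
peaks is merged into maximal overlapping-or-book-ended intervals, and a
merged interval is retained only if *every* replicate contributes at least
one overlapping (>= 1 bp) peak. This is the strict "identified in all
replicates" rule; it deliberately favours specificity over sensitivity, and
a consensus interval no longer carries any single replicate's summit or
signal value. Peaks overlapping a blacklist or annotated LINE/LTR repeat
region by >= 1 bp are then removed. Upstream read processing — trimming,
alignment, deduplication, selection of sub-nucleosomal (< 120 bp)
fragments, peak calling — is out of scope; `filter_fragments()` implements
the fragment-size rule for completeness but the pipeline starts from peak
calls.

**Feature assignment.** Each peak is represented by a single anchor base:
the called summit when present, otherwise the interval midpoint. The anchor
is classified by precedence *promoter > exon > intron > downstream >
intergenic* over the features of all genes, so every peak receives exactly
one category and category proportions always sum to 1. Promoter precedence
reflects the centrality of promoter-proximal accessibility in this
analysis. The nearest gene is the one minimising |anchor − TSS|, with exact
ties broken by the lexicographically smallest gene id so runs are
reproducible; the signed TSS distance is reported in transcription
orientation. An alternative any-overlap classification (`assign_by =
"overlap"`) is available because annotation tools differ on this point; the
anchor rule is the default since it matches one-category-per-peak bar
plots.

**Assumptions.** Genes are annotated at gene resolution: exons are unioned
across transcripts, so isoform-specific promoters and UTR subcategories are
not modelled. Assignment is proximity-based; the package makes no attempt
to link enhancers to targets through chromatin contact or correlation, and
a distal peak "belonging" biologically to a far gene will be counted to its
nearest TSS, as in any nearest-gene annotation.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `promoter_up` | 1000 | bp | promoter window upstream of the TSS |
| `promoter_down` | 100 | bp | promoter window downstream of the TSS |
| `downstream_len` | 1000 | bp | "downstream" region past the gene end |
| `max_span` | 120 | bp | strict fragment-size cutoff (`< 120` kept) |
| `n_reps` | 1000 | — | bootstrap replications |
| `conf` | 0.95 | — | CI level |
| `seed` | 1729 | — | master seed; all randomness derives from it |
| `bin_edges` | 1..5 | peaks | peaks-per-gene bins (use `1:10` for a >=10 top bin) |
| `threshold` | 0 | logCPM | strict expression cutoff |
| `min_overlap` | 1 | bp | enhancer-class overlap requirement |
| `flank`, `bin_size` | 1000, 10 | bp | metaprofile window and bin width |

The promoter and downstream windows are explicit because annotation tools
differ and published figure legends rarely state them; 1 kb upstream /
100 bp downstream is a conventional compact promoter for metazoan
annotations. The expression threshold is likewise explicit: "expressed in
at least one sample" is operationalised as logCPM strictly greater than 0
(about one count per million) in at least one sample.

## The bootstrap, precisely

The resampling unit differs between the two panels, and this is the only
choice that gives both valid intervals: for the feature distribution the
unit is the *peak assignment*; for peaks-per-gene bins it is the *gene*
carrying its peak count. Each of the 1,000 replications redraws n units
with replacement and recomputes the proportions; the interval is the
percentile interval at (1 − conf)/2 and 1 − (1 − conf)/2, and the point
estimate is the observed proportion. Percentile intervals were chosen over
normal-approximation or BCa intervals as the simplest method consistent
with a non-parametric bootstrap of a proportion.

Implementation note: because the resampled proportions depend on the data
only through the category counts, redrawing n labelled units is
distributionally identical to drawing the count vector from
Multinomial(n, observed proportions). The package draws the counts
directly, which makes 1,000 replications at n in the tens of thousands
effectively free and makes the replicate distribution trivially invariant
to input order. Intervals are deterministic given `seed`, and the global
RNG stream is left untouched.

Two proportions are called significantly different when their intervals
are disjoint; intervals sharing an endpoint overlap. CI non-overlap is
conservative relative to a direct two-sample test, and no multiple-testing
correction is applied — the flag mirrors the error-bar convention of the
bar-plot comparison it supports, and both the gene-set and the background
distributions are bootstrapped because both bars carry error bars.

Degenerate inputs behave sensibly: a single-category input yields
width-zero intervals; empty assignment sets are an error for the
distribution (there is nothing to estimate) and a skip-with-note in the
orchestrated pipeline.

## Repressed-gene classification

Counts are normalised to logCPM, `log2((count + prior) / (libsize +
2 prior) * 1e6)` with prior 0.5 — plain library-size scaling, not a
trimmed-mean method, because the classifier depends only on within-gene
trends across samples, which global library scaling preserves. Within one
tissue, expression per gene is averaged over replicates at each ranked time
point (means, not medians; configurable in principle by pre-aggregating), and a
gene is called *repressed* when those means strictly decrease between every
consecutive pair of time points and the gene is expressed above threshold
in at least one sample. Ties disqualify: "continual decrease" is read
literally, so a flat step is not repression. Repressed calls are therefore
always a subset of expressed calls. Row-wise Z-scores (sample sd, n − 1;
constant rows map to zero) are provided for display-style scaling.

Under negative-binomial noise with dispersion 0.1, three replicates and a
mean halving per time point over four time points — with repressed genes a
minority of the transcriptome, so library composition stays stable — the
acceptance suite measures sensitivity around 0.96 with a false-positive
rate among flat genes near 1% (the chance rate for a strict 4-point
decrease is 1/24).

## The synthetic data generator

The generator emulates the study design the pipeline targets: three
tissues sampled at three ordered time points with three ATAC replicates
each, 600 non-overlapping multi-exon genes on two 3-Mb chromosomes, and a
planted gene set covering 10% of genes. Gene-set members are 90% "simple"
(one promoter-proximal peak, centred 200 bp upstream of the TSS, present
at every time point); background genes are 40% simple, and complex genes
carry 2–6 distal peaks in introns or upstream intergenic space, with
intergenic enhancers concentrated at background (developmental-like)
genes. Distal peaks are lost at the final time point with probability 0.8,
emulating enhancer decommissioning after cell cycle exit. Replicate copies
jitter peak boundaries (truncated normal, sd 20 bp) and drop peaks with
probability 0.05. Expression counts are negative binomial (dispersion 0.1)
with class-specific mean trajectories: halving per time point (repressed —
80% of the gene set, 15% of the background), flat, or doubling (induced).
HK enhancer regions cover the promoter peaks of 45% of genes (a third of
those also receive a DEV region, forming the BOTH class) and DEV regions
cover 20% of distal peaks, so the union-set overlap pattern is
HK-dominated with a minority DEV and BOTH share. Coverage tracks are a
rectangular model — a baseline plus a fixed enrichment over each present
peak, scaled to counts per million.

Sizes are desk scale, roughly a twentieth of a fly-tissue ATAC dataset, so
the whole pipeline runs in seconds; the acceptance experiments use n = 300
versus n = 20,000 peaks for calibration (200 coverage datasets; 100 null
and 100 power simulations) and 50 classifier simulations of 500 genes.

Placement is *verified*: every distal peak must be nearest (by the
assignment rule) to its host gene, and background noise peaks must be
nearest a gene outside the planted set. At desk scale the gene set spans
10% of genes — five times its share in a real genome — so unverified random
placement would contaminate the gene set's peak composition with
noise peaks and blur the planted contrast; verification keeps the truth
labels exact with respect to the pipeline's own rules. A self-audit
(`audit_simulation()`) rebuilds the consensus from the emitted replicate
files and checks that assigned categories agree with planted ones (>= 98%
required under default jitter; in practice agreement is complete).

What passing on synthetic data does *not* show: real ATAC data have
irregular peak shapes, copy-number and mappability artifacts, summit drift
between replicates larger than boundary jitter, exonic and
downstream peaks (the generator plants none, so those categories exercise
only the zero-count path end-to-end, though unit tests cover them
directly), and nearest-gene assignment errors for genuinely distal
enhancers. Results on the generator validate the *machinery*, not any
biological claim about a new dataset.

All generator stages derive fixed child seeds from one master seed, so the
emitted file set — GFF3, narrowPeak, BEDs, bedGraphs, counts, truth JSON,
pipeline config — is byte-identical across runs with the same parameters,
and individual stages can be regenerated independently.

## Numerical and coordinate conventions

Internally every interval lives in a `GRanges` (1-based, closed), the
single convention all Bioconductor interval arithmetic assumes;
`rtracklayer` performs the 0-based half-open conversions for BED-family
formats at the I/O boundary, and GFF3/GTF are native. Midpoint anchors use
the lower central base for even-width peaks. Book-ended peaks (end of one
= start of the next − 1) merge during consensus building, matching
maximal-run extraction over per-base occupancy. Metaprofile windows
truncated by a chromosome end are zero-padded, minus-strand TSS windows
are reversed into transcription orientation, and peak-center anchors are
never reversed. Coverage gaps in bedGraph input count as zero.

## Known limitations

* Nearest-TSS assignment is a proxy; no enhancer–gene linking.
* CI non-overlap is conservative and uncorrected across categories/bins;
  treat the flags as the bar-plot convention they are, not as a formal
  multiple-testing procedure.
* The repression classifier requires strict monotonicity; genes repressed
  with a plateau are deliberately not called.
* logCPM uses plain library-size normalisation; strong composition shifts
  between samples (e.g. if a large fraction of the transcriptome changes)
  will tilt trends, which matters for the classifier's absolute rates.
* The generator does not simulate reads, fragment-size mixtures, or
  nucleosome positioning; signal-level realism is limited to rectangular
  enrichment.
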