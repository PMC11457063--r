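# peakarch

Regulatory-architecture analysis of ATAC-seq peaks across developmental
time courses.

## The problem

During terminal differentiation, cells exit the cell cycle and repress
hundreds of cell cycle genes — yet most of those genes keep an accessible
region at their transcription start site, while the few rate-limiting
genes with complex, modular enhancer landscapes lose accessibility at
their distal elements ("enhancer decommissioning"). Testing claims of this
kind requires comparing the *regulatory architecture* of a gene set
against the genome-wide background with honest uncertainty estimates.

`peakarch` is for epigenomics analysts who have replicate ATAC-seq peak
calls across tissues and ordered time points, a gene annotation, and a
gene set of interest (e.g. cell cycle genes). It builds
all-replicate-consensus peak sets, removes blacklist/repeat regions,
assigns each peak a genomic feature and nearest gene, and compares two
architecture summaries between the gene set and the background:

* **Feature distribution** — the proportions of peaks in promoter, exon,
  intron, downstream and intergenic space. A peak's category comes from a
  single anchor base (summit, else midpoint) under the precedence
  promoter > exon > intron > downstream > intergenic.
* **Peaks-per-gene** — genes binned by the number of peaks assigned to
  them (1, 2, 3, 4, >=5 by default; >=10 top bin available), a proxy for
  simple versus complex architecture.

For each proportion *p̂* (of *n* resampled peaks or genes) the package
draws *B* = 1,000 non-parametric bootstrap replicates and reports the
percentile interval [q₀.₀₂₅, q₀.₉₇₅]; two proportions are flagged
significantly different when their 95% intervals are disjoint. Companion
stages classify *repressed* genes (per-time-point replicate-mean logCPM
strictly decreasing between every consecutive time point, and expressed
above logCPM 0 somewhere), partition peaks by overlap with housekeeping
(HK) versus developmental (DEV) enhancer sets, and compute average
accessibility metaprofiles ±1 kb around peak centers or TSSs.

A fully deterministic synthetic-data generator plants simple-vs-complex
architectures with ground truth (annotation, replicate narrowPeak files
with jitter and dropout, distal-peak decommissioning at the last time
point, negative-binomial counts, enhancer BEDs, bedGraph coverage), so
every stage is testable without downloading anything.

## Worked example

Generate a synthetic dataset and run the core comparison for one tissue
and time point:

```r
library(peakarch)

sim <- simulate_dataset(sim_params(seed = 1), file.path(tempdir(), "demo"))
cfg <- read_run_config(sim$paths$config)

reps <- lapply(cfg$peaks$wing$L3, read_narrowpeak)
cons <- consensus_peaks(reps)
cons <- exclude_regions(cons, c(read_bed(cfg$blacklist), read_bed(cfg$repeats)))
length(cons)
#> [1] 1472

models <- read_gene_models(cfg$annotation)
idx <- build_feature_index(models)          # promoter 1 kb up / 100 bp down
asn <- assign_peaks(cons, idx)
cc <- subset_by_gene_set(asn, readLines(cfg$gene_set),
                         known_genes = models$genes$gene_id)
nrow(cc)
#> [1] 54

ci_cc  <- bootstrap_category_ci(cc,  seed = 1)   # 1,000 replications
ci_all <- bootstrap_category_ci(asn, seed = 2)
compare_ci_tables(ci_cc, ci_all)
#>     category estimate_set lower_set upper_set estimate_background significant
#> 1   promoter         0.87    0.7778     0.944               0.357        TRUE
#> 2       exon         0.00    0.0000     0.000               0.000       FALSE
#> 3     intron         0.13    0.0556     0.222               0.382        TRUE
#> 4 downstream         0.00    0.0000     0.000               0.000       FALSE
#> 5 intergenic         0.00    0.0000     0.000               0.261        TRUE
```

Of the 1,472 consensus peaks, 54 are nearest to planted gene-set genes;
87% of those sit at promoters versus 36% genome-wide, and the depletion at
introns and intergenic space is likewise flagged by non-overlapping 95%
CIs — the planted simple-architecture signature. `peaks_per_gene()` +
`bootstrap_bin_ci()` make the same comparison per gene (bin 1 enriched,
top bins depleted), and `run_all(cfg, outdir)` executes every stage from
the YAML config, writing 15 TSV tables and a machine-readable
`report.json`.

A thin CLI over the same functions ships in `inst/scripts/peakarch`
(subcommands `simulate`, `validate`, `run-all`, `consensus`, `annotate`,
`arch-stats`, `expr-classify`, `overlap`, `profile`).

See `vignettes/regulatory-architecture.Rmd` for the model, parameter and
calibration details.

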