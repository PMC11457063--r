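#' Parameters for the synthetic dataset generator
#'
#' Defines the study conditions the generator emulates: a multi-tissue
#' developmental time course (three tissues, three ordered time points,
#' three ATAC replicates each), a genome of non-overlapping multi-exon
#' genes, a planted gene set whose members mostly carry a single
#' promoter-proximal peak ("simple" architecture) against a background rich
#' in "complex" genes with several intronic/intergenic peaks, distal-peak
#' decommissioning at the final time point, negative-binomial expression
#' with monotone-decreasing / flat / induced classes, housekeeping (HK)
#' enhancers placed over promoter peaks and developmental (DEV) enhancers
#' over distal peaks, and rectangular coverage enrichment over present
#' peaks. Sizes are desk scale (hundreds of genes, ~1.5k peaks per
#' condition), roughly a twentieth of a fly-tissue ATAC dataset.
#'
#' @param seed Master seed; every stage derives a fixed child seed from it.
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes Total genes (split evenly across chromosomes).
#' @param min_gene_spacing Minimum bp between consecutive gene spans.
#' @param fraction_geneset Fraction of genes in the planted gene set.
#' @param p_simple_geneset,p_simple_background Probability a gene-set /
#'   background gene has simple (single promoter peak) architecture.
#' @param tissues Character vector of tissue labels.
#' @param timepoints Named integer vector: time point label -> rank.
#' @param n_replicates ATAC replicates per tissue x time point.
#' @param peak_width_range Planted peak width range in bp.
#' @param n_distal_range Number of distal peaks per complex gene.
#' @param p_distal_intergenic_geneset,p_distal_intergenic_background
#'   Probability a distal peak of a complex gene is placed intergenically
#'   (upstream of the TSS) rather than in an intron; background
#'   (developmental-like) genes carry more intergenic enhancers than
#'   gene-set members. Every distal peak is verified to be nearest its host
#'   gene's TSS so the planted peaks-per-gene truth matches the assignment
#'   rule.
#' @param jitter_sd Truncated-normal jitter sd (bp) applied to replicate
#'   peak boundaries.
#' @param dropout_prob Probability a replicate misses a present peak.
#' @param decommission_prob Probability a distal peak of a complex gene is
#'   lost (absent) at the last time point.
#' @param n_background_peaks Gene-unrelated intergenic peaks per genome.
#' @param n_blacklist,n_repeats Number of blacklist / repeat regions, each
#'   seeded with decoy peaks that the exclusion step must remove.
#' @param base_mean Median negative-binomial mean at the first time point.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param class_probs_geneset,class_probs_background Probabilities of the
#'   expression classes (repressed, flat, induced).
#' @param hk_gene_fraction Fraction of genes whose promoter peak is covered
#'   by an HK enhancer.
#' @param both_fraction Fraction of HK-covered promoter peaks that also get
#'   a DEV region (the BOTH class).
#' @param dev_peak_fraction Fraction of distal peaks covered by a DEV
#'   enhancer.
#' @param enhancer_width Width of planted enhancer regions (bp).
#' @param coverage_baseline,coverage_peak_height Rectangular coverage model:
#'   baseline level everywhere plus this height over each present peak,
#'   CPM-scaled per track.
#' @return A list of class `SimulationParams`.
#' @export
sim_params <- function(seed = 1729L,
                       n_chroms = 2L, chrom_length = 3e6, n_genes = 600L,
                       min_gene_spacing = 3000L,
                       fraction_geneset = 0.1,
                       p_simple_geneset = 0.9, p_simple_background = 0.4,
                       tissues = c("wing", "eye", "brain"),
                       timepoints = c(L3 = 1L, APF24 = 2L, APF44 = 3L),
                       n_replicates = 3L,
                       peak_width_range = c(200L, 500L),
                       n_distal_range = c(2L, 6L),
                       p_distal_intergenic_geneset = 0.1,
                       p_distal_intergenic_background = 0.4,
                       jitter_sd = 20, dropout_prob = 0.05,
                       decommission_prob = 0.8,
                       n_background_peaks = 60L,
                       n_blacklist = 4L, n_repeats = 4L,
                       base_mean = 256, dispersion = 0.1,
                       class_probs_geneset = c(repressed = 0.8, flat = 0.15, induced = 0.05),
                       class_probs_background = c(repressed = 0.15, flat = 0.7, induced = 0.15),
                       hk_gene_fraction = 0.45, both_fraction = 0.33,
                       dev_peak_fraction = 0.2, enhancer_width = 600L,
                       coverage_baseline = 1, coverage_peak_height = 10) {
  p <- as.list(environment())
  stopifnot(p$fraction_geneset >= 0, p$fraction_geneset <= 1,
            p$dropout_prob >= 0, p$dropout_prob <= 1,
            p$decommission_prob >= 0, p$decommission_prob <= 1,
            p$chrom_length > 0, p$n_genes > 0, p$n_replicates >= 1,
            abs(sum(p$class_probs_geneset) - 1) < 1e-9,
            abs(sum(p$class_probs_background) - 1) < 1e-9)
  class(p) <- "SimulationParams"
  p
}

#' Generate the synthetic gene annotation
#'
#' Places non-overlapping genes with 2-4 exons sequentially along each
#' chromosome with random spacing above the configured minimum, assigns
#' gene-set membership, simple/complex architecture, and expression class.
#' Deterministic given the seed.
#'
#' @param params A `SimulationParams` object.
#' @return A list with `models` (as [read_gene_models()]) and `truth_genes`
#'   (`data.frame` with `gene_id`, coordinates, `strand`, `tss`,
#'   `in_geneset`, `architecture`, `expr_class`).
#' @export
generate_annotation <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  with_seed(child_seed(params$seed, "annotation"), {
    per_chrom <- ceiling(params$n_genes / params$n_chroms)
    recs <- list(); exon_list <- list()
    gi <- 0L
    for (ci in seq_len(params$n_chroms)) {
      chrom <- paste0("chr", ci)
      cursor <- 10000
      n_here <- min(per_chrom, params$n_genes - gi)
      for (k in seq_len(n_here)) {
        gi <- gi + 1L
        gene_id <- sprintf("g%04d", gi)
        n_ex <- sample(2:4, 1L)
        widths <- sample(200:400, n_ex, replace = TRUE)
        gaps <- sample(1000:2500, n_ex - 1L, replace = TRUE)
        span <- sum(widths) + sum(gaps)
        gap_before <- runif(1, params$min_gene_spacing, params$min_gene_spacing + 3000)
        start <- round(cursor + gap_before)
        end <- start + span - 1L
        if (end > params$chrom_length - 10000)
          stop("genes do not fit on ", chrom,
               "; increase chrom_length or reduce n_genes")
        ex_starts <- start + cumsum(c(0L, widths[-n_ex] + gaps))
        strand <- sample(c("+", "-"), 1L)
        recs[[gi]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                 start = start, end = end, strand = strand,
                                 stringsAsFactors = FALSE)
        exon_list[[gene_id]] <- IRanges::IRanges(ex_starts, width = widths)
        cursor <- end
      }
    }
    tg <- do.call(rbind, recs)
    tg$tss <- ifelse(tg$strand == "+", tg$start, tg$end)
    n <- nrow(tg)
    n_set <- round(params$fraction_geneset * n)
    tg$in_geneset <- FALSE
    tg$in_geneset[sample.int(n, n_set)] <- TRUE
    p_simple <- ifelse(tg$in_geneset, params$p_simple_geneset,
                       params$p_simple_background)
    tg$architecture <- ifelse(runif(n) < p_simple, "simple", "complex")
    classes <- c("repressed", "flat", "induced")
    tg$expr_class <- vapply(seq_len(n), function(i) {
      pr <- if (tg$in_geneset[i]) params$class_probs_geneset
            else params$class_probs_background
      sample(classes, 1L, prob = pr)
    }, "")

    genes <- GenomicRanges::GRanges(tg$chrom, IRanges::IRanges(tg$start, tg$end),
                                    strand = tg$strand)
    genes$gene_id <- tg$gene_id
    sl <- setNames(rep(params$chrom_length, params$n_chroms),
                   paste0("chr", seq_len(params$n_chroms)))
    GenomeInfoDb::seqlengths(genes) <- sl[GenomeInfoDb::seqlevels(genes)]
    n_ex_per <- vapply(exon_list[tg$gene_id], length, 1L)
    ex_flat <- GenomicRanges::GRanges(
      rep(tg$chrom, n_ex_per),
      unlist(IRanges::IRangesList(exon_list[tg$gene_id]), use.names = FALSE))
    exons <- GenomicRanges::split(
      ex_flat, factor(rep(tg$gene_id, n_ex_per), levels = tg$gene_id))
    list(models = list(genes = genes, exons = exons), truth_genes = tg)
  })
}

# positions at distance > margin from every gene span on a chromosome
sample_intergenic_center <- function(chrom_len, gene_spans, existing_centers,
                                     margin, min_sep, max_try = 200L) {
  for (i in seq_len(max_try)) {
    p <- round(runif(1, 5000, chrom_len - 5000))
    near_gene <- any(p >= gene_spans$start - margin & p <= gene_spans$end + margin)
    near_peak <- length(existing_centers) && any(abs(existing_centers - p) < min_sep)
    if (!near_gene && !near_peak) return(p)
  }
  NA_real_
}

#' Generate replicate peak sets with ground truth
#'
#' Plants one promoter-proximal peak per gene (all time points), 2-6 distal
#' intronic/intergenic peaks per complex gene (each lost at the final time
#' point with the decommission probability), background intergenic peaks,
#' and decoy peaks inside blacklist/repeat regions. Every replicate copy is
#' boundary-jittered (truncated normal, clipped to the chromosome) and
#' dropped with the dropout probability. The truth table records each peak's
#' intended category, host gene, analytically-computed nearest gene, and the
#' conditions where it is present.
#'
#' @param sim Output of [generate_annotation()].
#' @param params A `SimulationParams` object.
#' @return `sim` extended with `truth_peaks` (`data.frame`), `presence`
#'   (logical matrix, peak x "tissue|timepoint"), `replicate_peaks` (named
#'   list "tissue|timepoint" -> list of per-replicate `GRanges`), and
#'   `blacklist`/`repeats` (`GRanges`).
#' @export
generate_peaks <- function(sim, params) {
  tg <- sim$truth_genes
  models <- sim$models
  idx <- build_feature_index(models)
  with_seed(child_seed(params$seed, "peaks"), {
    wlo <- params$peak_width_range[1]; whi <- params$peak_width_range[2]
    pk <- list()
    add_peak <- function(chrom, center, width, category, host_gene, kind) {
      half <- width %/% 2L
      start <- as.integer(center - half)
      end <- as.integer(start + width - 1L)
      pk[[length(pk) + 1L]] <<- data.frame(
        chrom = chrom, start = start, end = end, center = as.integer(center),
        category = category, host_gene = host_gene, kind = kind,
        stringsAsFactors = FALSE)
    }
    # promoter peak for every gene, centered 200 bp upstream of the TSS
    # (inside the default promoter window with margin on both edges)
    for (i in seq_len(nrow(tg))) {
      ctr <- if (tg$strand[i] == "+") tg$tss[i] - 200L else tg$tss[i] + 200L
      add_peak(tg$chrom[i], ctr, sample(wlo:whi, 1L), "promoter",
               tg$gene_id[i], "promoter")
    }
    # distal peaks for complex genes: introns preferred, sometimes
    # intergenic upstream of the TSS; every candidate is verified to be
    # nearest its host gene's TSS under the assignment rule, so planted
    # peaks-per-gene counts survive the pipeline
    introns <- idx$intron
    intr_by_gene <- split(seq_along(introns), introns$gene_id)
    gene_spans_by_chrom <- split(tg[, c("start", "end")], tg$chrom)
    nearest_is_host <- function(chrom, ctr, gid) {
      identical(nearest_tss(chrom, ctr, idx$tss)$gene_id, gid)
    }
    for (i in which(tg$architecture == "complex")) {
      n_d <- sample(params$n_distal_range[1]:params$n_distal_range[2], 1L)
      gid <- tg$gene_id[i]
      p_ig <- if (tg$in_geneset[i]) params$p_distal_intergenic_geneset
              else params$p_distal_intergenic_background
      used <- numeric(0)
      for (d in seq_len(n_d)) {
        w <- sample(wlo:whi, 1L)
        placed <- FALSE
        if (runif(1) < p_ig) {
          gs <- gene_spans_by_chrom[[tg$chrom[i]]]
          for (try in 1:10) {
            off <- round(runif(1, 1400, 2400))
            ctr <- if (tg$strand[i] == "+") tg$tss[i] - off else tg$tss[i] + off
            other <- gs$start != tg$start[i] | gs$end != tg$end[i]
            ok <- ctr > 5000 && ctr < params$chrom_length - 5000 &&
              !any(ctr >= gs$start[other] - 1300 & ctr <= gs$end[other] + 1300) &&
              !(length(used) && any(abs(used - ctr) < w + 100)) &&
              nearest_is_host(tg$chrom[i], ctr, gid)
            if (ok) {
              add_peak(tg$chrom[i], ctr, w, "intergenic", gid, "distal")
              used <- c(used, ctr); placed <- TRUE
              break
            }
          }
        }
        if (!placed) {
          cand <- intr_by_gene[[gid]]
          if (!is.null(cand)) {
            cand <- cand[IRanges::width(introns[cand]) >= w + 300L]
            for (ic in cand[sample.int(length(cand))]) {
              lo <- GenomicRanges::start(introns[ic]) + 150L + w %/% 2L
              hi <- GenomicRanges::end(introns[ic]) - 150L - w %/% 2L
              if (lo > hi) next
              ctr <- round(runif(1, lo, hi))
              if (length(used) && any(abs(used - ctr) < w + 100)) next
              if (!nearest_is_host(tg$chrom[i], ctr, gid)) next
              add_peak(tg$chrom[i], ctr, w, "intron", gid, "distal")
              used <- c(used, ctr); placed <- TRUE
              break
            }
          }
        }
      }
    }
    peaks_df <- do.call(rbind, pk)
    # background intergenic peaks, far from every gene; their nearest gene
    # is verified to be outside the planted gene set, so the gene set's
    # peak composition is fully determined by the architecture parameters
    geneset_ids <- tg$gene_id[tg$in_geneset]
    for (ci in seq_len(params$n_chroms)) {
      chrom <- paste0("chr", ci)
      gs <- gene_spans_by_chrom[[chrom]]
      n_bg <- params$n_background_peaks %/% params$n_chroms
      ctrs <- peaks_df$center[peaks_df$chrom == chrom]
      for (b in seq_len(n_bg)) {
        w <- sample(wlo:whi, 1L)
        for (try in 1:30) {
          p <- sample_intergenic_center(params$chrom_length, gs, ctrs,
                                        margin = 1300, min_sep = whi + 200)
          if (is.na(p)) break
          if (nearest_tss(chrom, p, idx$tss)$gene_id %in% geneset_ids) next
          add_peak(chrom, p, w, "intergenic", NA_character_, "background")
          ctrs <- c(ctrs, p)
          break
        }
      }
    }
    peaks_df <- do.call(rbind, pk)
    # blacklist / repeat regions with decoy peaks inside them
    excl <- list()
    for (kind in c("blacklist", "repeat")) {
      n_r <- if (kind == "blacklist") params$n_blacklist else params$n_repeats
      for (r in seq_len(n_r)) {
        chrom <- paste0("chr", sample.int(params$n_chroms, 1L))
        gs <- gene_spans_by_chrom[[chrom]]
        ctrs <- peaks_df$center[peaks_df$chrom == chrom]
        p <- sample_intergenic_center(params$chrom_length, gs, ctrs,
                                      margin = 2500, min_sep = 3000)
        if (is.na(p)) next
        excl[[length(excl) + 1L]] <- data.frame(
          chrom = chrom, start = as.integer(p - 1000L),
          end = as.integer(p + 999L), kind = kind, stringsAsFactors = FALSE)
        add_peak(chrom, p, sample(wlo:whi, 1L), "intergenic", NA_character_,
                 paste0("decoy_", kind))
        peaks_df <- do.call(rbind, pk)
      }
    }
    peaks_df <- do.call(rbind, pk)
    excl_df <- do.call(rbind, excl)
    peaks_df$peak_id <- sprintf("pk%05d", seq_len(nrow(peaks_df)))
    # analytic nearest gene (same rule as the assignment engine)
    nn <- nearest_tss(peaks_df$chrom, peaks_df$center, idx$tss)
    peaks_df$nearest_gene <- nn$gene_id
    # decommissioning of distal peaks at the last time point
    peaks_df$decommissioned <- FALSE
    is_distal <- peaks_df$kind == "distal"
    peaks_df$decommissioned[is_distal] <-
      runif(sum(is_distal)) < params$decommission_prob

    conds <- expand.grid(timepoint = names(params$timepoints),
                         tissue = params$tissues, stringsAsFactors = FALSE)
    conds <- conds[, c("tissue", "timepoint")]
    cond_key <- paste(conds$tissue, conds$timepoint, sep = "|")
    last_rank <- max(params$timepoints)
    presence <- matrix(TRUE, nrow(peaks_df), nrow(conds),
                       dimnames = list(peaks_df$peak_id, cond_key))
    for (j in seq_len(nrow(conds))) {
      if (params$timepoints[[conds$timepoint[j]]] == last_rank)
        presence[peaks_df$decommissioned, j] <- FALSE
    }
    # replicate emission: jitter + dropout
    rep_peaks <- list()
    for (j in seq_len(nrow(conds))) {
      present <- peaks_df[presence[, j], , drop = FALSE]
      reps <- list()
      for (r in seq_len(params$n_replicates)) {
        keep <- runif(nrow(present)) >= params$dropout_prob
        sub <- present[keep, , drop = FALSE]
        ds <- round(pmax(pmin(rnorm(nrow(sub), 0, params$jitter_sd), 60), -60))
        de <- round(pmax(pmin(rnorm(nrow(sub), 0, params$jitter_sd), 60), -60))
        st <- pmax(1L, as.integer(sub$start + ds))
        en <- pmin(as.integer(params$chrom_length),
                   as.integer(sub$end + de))
        bad <- en <= st
        st[bad] <- sub$start[bad]; en[bad] <- sub$end[bad]
        gr <- GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(st, en))
        gr$name <- sprintf("%s_r%d", sub$peak_id, r)
        gr$score <- 100L
        gr$signalValue <- 5
        gr$pValue <- 10
        gr$qValue <- 8
        gr$peak <- pmin(pmax(sub$center - st, 0L), en - st)
        reps[[r]] <- GenomicRanges::sort(gr)
      }
      rep_peaks[[cond_key[j]]] <- reps
    }
    excl_gr <- GenomicRanges::GRanges(excl_df$chrom,
                                      IRanges::IRanges(excl_df$start, excl_df$end))
    sim$truth_peaks <- peaks_df
    sim$presence <- presence
    sim$replicate_peaks <- rep_peaks
    sim$blacklist <- excl_gr[excl_df$kind == "blacklist"]
    sim$repeats <- excl_gr[excl_df$kind == "repeat"]
    sim
  })
}

#' Generate a negative-binomial expression matrix with ground-truth classes
#'
#' Draws counts per gene and sample from a negative binomial whose mean
#' follows the gene's planted class: halving per time point rank
#' (repressed), constant (flat), or doubling (induced). Per-gene baseline
#' means vary log-normally around `base_mean`.
#'
#' @param sim Output of [generate_annotation()] (or later stages).
#' @param params A `SimulationParams` object.
#' @return `sim` extended with `counts` (matrix genes x samples) and
#'   `sample_sheet`.
#' @export
generate_counts <- function(sim, params) {
  tg <- sim$truth_genes
  with_seed(child_seed(params$seed, "counts"), {
    sheet <- expand.grid(replicate = seq_len(params$n_replicates),
                         timepoint = names(params$timepoints),
                         tissue = params$tissues, stringsAsFactors = FALSE)
    sheet <- sheet[, c("tissue", "timepoint", "replicate")]
    sheet$timepoint_rank <- params$timepoints[sheet$timepoint]
    sheet$sample_id <- sprintf("%s_%s_rep%d", sheet$tissue, sheet$timepoint,
                               sheet$replicate)
    sheet <- sheet[, c("sample_id", "tissue", "timepoint", "timepoint_rank",
                       "replicate")]
    base <- params$base_mean * 2^rnorm(nrow(tg), 0, 0.5)
    mult <- c(repressed = 0.5, flat = 1, induced = 2)
    mu <- outer(seq_len(nrow(tg)), seq_len(nrow(sheet)),
                function(i, j) base[i] *
                  mult[tg$expr_class[i]]^(sheet$timepoint_rank[j] - 1))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / params$dispersion),
                     nrow = nrow(tg),
                     dimnames = list(tg$gene_id, sheet$sample_id))
    sim$counts <- counts
    sim$sample_sheet <- sheet
    sim
  })
}

#' Generate enhancer class regions and coverage tracks
#'
#' Places housekeeping (HK) enhancer regions over the promoter peaks of a
#' random fraction of genes and developmental (DEV) regions over a random
#' fraction of distal peaks; a fraction of HK-covered promoter peaks also
#' receive a DEV region (the BOTH class). Coverage per tissue x time point
#' is a rectangular model — baseline everywhere plus a fixed enrichment over
#' every present planted peak — scaled to counts per million.
#'
#' @param sim Output of [generate_peaks()].
#' @param params A `SimulationParams` object.
#' @return `sim` extended with `hk_enhancers`, `dev_enhancers` (`GRanges`)
#'   and `coverage` (named list "tissue|timepoint" -> `RleList`).
#' @export
generate_enhancers_and_coverage <- function(sim, params) {
  pk <- sim$truth_peaks
  with_seed(child_seed(params$seed, "enhancers"), {
    half <- params$enhancer_width %/% 2L
    prom <- pk[pk$kind == "promoter", , drop = FALSE]
    n_hk <- round(params$hk_gene_fraction * nrow(prom))
    hk_rows <- prom[sample.int(nrow(prom), n_hk), , drop = FALSE]
    both_rows <- hk_rows[runif(nrow(hk_rows)) < params$both_fraction, ,
                         drop = FALSE]
    dist_rows <- pk[pk$kind == "distal", , drop = FALSE]
    n_dev <- round(params$dev_peak_fraction * nrow(dist_rows))
    dev_rows <- dist_rows[sample.int(nrow(dist_rows), n_dev), , drop = FALSE]
    mk <- function(rows) {
      if (!nrow(rows)) return(GenomicRanges::GRanges())
      GenomicRanges::sort(GenomicRanges::GRanges(
        rows$chrom, IRanges::IRanges(rows$center - half,
                                     rows$center + half - 1L)))
    }
    sim$hk_enhancers <- mk(hk_rows)
    sim$dev_enhancers <- mk(rbind(dev_rows, both_rows))
    sim$enhancer_truth <- list(hk_peaks = hk_rows$peak_id,
                               both_peaks = both_rows$peak_id,
                               dev_peaks = dev_rows$peak_id)
  })
  seqlens <- setNames(rep(params$chrom_length, params$n_chroms),
                      paste0("chr", seq_len(params$n_chroms)))
  cov <- list()
  for (key in colnames(sim$presence)) {
    present <- pk[sim$presence[, key], , drop = FALSE]
    gr <- GenomicRanges::GRanges(present$chrom,
                                 IRanges::IRanges(present$start, present$end),
                                 seqinfo = GenomeInfoDb::Seqinfo(names(seqlens),
                                                                 seqlens))
    v <- GenomicRanges::coverage(gr) * params$coverage_peak_height +
      params$coverage_baseline
    cov[[key]] <- cpm_scale_track(v)
  }
  sim$coverage <- cov
  sim
}

#' Generate and write a complete synthetic dataset
#'
#' Runs all generator stages and writes the file set a real analysis would
#' start from: GFF3 annotation, per-replicate narrowPeak files, blacklist
#' and repeat BEDs, gene-set list, counts and sample sheet TSVs, HK/DEV
#' enhancer BEDs, per-condition bedGraph coverage, a machine-readable truth
#' JSON, and a ready-to-run pipeline config YAML. Byte-identical given the
#' same parameters and seed.
#'
#' @param params A `SimulationParams` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the in-memory simulation object with an added `paths`
#'   element.
#' @export
simulate_dataset <- function(params, dir) {
  sim <- generate_annotation(params)
  sim <- generate_peaks(sim, params)
  sim <- generate_counts(sim, params)
  sim <- generate_enhancers_and_coverage(sim, params)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(dir, "coverage"), showWarnings = FALSE)
  paths <- list(annotation = file.path(dir, "genes.gff3"),
                gene_set = file.path(dir, "geneset.txt"),
                blacklist = file.path(dir, "blacklist.bed"),
                repeats = file.path(dir, "repeats.bed"),
                hk = file.path(dir, "hk_enhancers.bed"),
                dev = file.path(dir, "dev_enhancers.bed"),
                counts = file.path(dir, "counts.tsv"),
                samples = file.path(dir, "samples.tsv"),
                truth = file.path(dir, "truth.json"),
                config = file.path(dir, "config.yaml"))
  write_gene_models(sim$models, paths$annotation)
  writeLines(sim$truth_genes$gene_id[sim$truth_genes$in_geneset],
             paths$gene_set)
  write_bed(sim$blacklist, paths$blacklist)
  write_bed(sim$repeats, paths$repeats)
  write_bed(sim$hk_enhancers, paths$hk)
  write_bed(sim$dev_enhancers, paths$dev)
  write_tsv(data.frame(gene_id = rownames(sim$counts), sim$counts,
                       check.names = FALSE), paths$counts)
  write_tsv(sim$sample_sheet, paths$samples)

  peak_files <- list()
  for (key in names(sim$replicate_peaks)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    files <- character(0)
    for (r in seq_along(sim$replicate_peaks[[key]])) {
      f <- file.path(dir, "peaks",
                     sprintf("%s_%s_rep%d.narrowPeak", parts[1], parts[2], r))
      export_narrowpeak(sim$replicate_peaks[[key]][[r]], f)
      files <- c(files, f)
    }
    peak_files[[parts[1]]][[parts[2]]] <- files
  }
  cov_files <- list()
  for (key in names(sim$coverage)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    f <- file.path(dir, "coverage", sprintf("%s_%s.bedGraph", parts[1], parts[2]))
    gr <- as(sim$coverage[[key]], "GRanges")
    rtracklayer::export(gr[gr$score != 0], f, format = "bedGraph")
    cov_files[[paste(parts[1], parts[2], sep = "|")]] <- f
  }

  truth <- list(genes = sim$truth_genes,
                peaks = sim$truth_peaks,
                presence = as.data.frame(sim$presence),
                enhancers = sim$enhancer_truth,
                seed = params$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)

  config <- list(
    annotation = paths$annotation,
    gene_set = paths$gene_set,
    blacklist = paths$blacklist,
    repeats = paths$repeats,
    peaks = peak_files,
    timepoint_ranks = as.list(params$timepoints),
    enhancers = list(hk = paths$hk, dev = paths$dev),
    counts = paths$counts,
    samples = paths$samples,
    coverage = cov_files,
    params = list(promoter_up = 1000L, promoter_down = 100L,
                  downstream_len = 1000L, n_reps = 1000L, conf = 0.95,
                  seed = params$seed, expression_threshold = 0,
                  bin_edges = 1:5, flank = 1000L, bin_size = 10L,
                  assign_by = "anchor")
  )
  yaml::write_yaml(config, paths$config)
  sim$paths <- c(paths, list(peaks = peak_files, coverage = cov_files))
  invisible(sim)
}

# narrowPeak writer with the standard 10 columns (rtracklayer's BED writer
# does not emit the +4 columns, so write them explicitly; coordinates are
# converted to the format's 0-based half-open convention).
export_narrowpeak <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = gr$name, score = gr$score, strand = ".",
                   signalValue = gr$signalValue, pValue = gr$pValue,
                   qValue = gr$qValue, peak = gr$peak)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Audit a simulation against the analysis pipeline
#'
#' Self-check that the emitted data are consistent with the planted truth:
#' for every condition, builds the replicate consensus, removes blacklist /
#' repeat decoys, assigns features, matches each consensus peak to the
#' planted peak it overlaps most, and compares categories.
#'
#' @param sim Simulation object from [generate_peaks()] or later.
#' @param params The `SimulationParams` used to build it.
#' @return A list with `category_agreement` (fraction over all matched
#'   consensus peaks), `n_matched`, `n_consensus`, and `n_unmatched`.
#' @export
audit_simulation <- function(sim, params) {
  idx <- build_feature_index(sim$models)
  planted <- GenomicRanges::GRanges(sim$truth_peaks$chrom,
                                    IRanges::IRanges(sim$truth_peaks$start,
                                                     sim$truth_peaks$end))
  excl <- c(sim$blacklist, sim$repeats)
  agree <- 0L; total <- 0L; n_cons <- 0L; unmatched <- 0L
  for (key in names(sim$replicate_peaks)) {
    cons <- consensus_peaks(sim$replicate_peaks[[key]])
    cons <- exclude_regions(cons, excl)
    n_cons <- n_cons + length(cons)
    asn <- assign_peaks(cons, idx)
    ov <- GenomicRanges::findOverlaps(cons, planted)
    if (length(ov) == 0L) { unmatched <- unmatched + length(cons); next }
    w <- IRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(cons)[S4Vectors::queryHits(ov)],
      GenomicRanges::ranges(planted)[S4Vectors::subjectHits(ov)]))
    best <- tapply(seq_along(ov), S4Vectors::queryHits(ov),
                   function(ii) S4Vectors::subjectHits(ov)[ii[which.max(w[ii])]])
    qh <- as.integer(names(best))
    truth_cat <- sim$truth_peaks$category[as.integer(best)]
    agree <- agree + sum(asn$category[qh] == truth_cat)
    total <- total + length(qh)
    unmatched <- unmatched + (length(cons) - length(qh))
  }
  list(category_agreement = agree / total, n_matched = total,
       n_consensus = n_cons, n_unmatched = unmatched)
}
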