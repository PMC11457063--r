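test_that("annotation generation: counts, disjoint spans, determinism", {
  p <- small_params(seed = 31L)
  sim <- generate_annotation(p)
  expect_equal(nrow(sim$truth_genes), 80L)
  expect_equal(length(sim$models$genes), 80L)
  # all gene spans disjoint
  ov <- GenomicRanges::findOverlaps(sim$models$genes, ignore.strand = TRUE,
                                    drop.self = TRUE)
  expect_equal(length(ov), 0L)
  # exons inside their gene, sorted and non-overlapping
  for (g in sample(sim$truth_genes$gene_id, 10)) {
    ex <- sim$models$exons[[g]]
    row <- sim$truth_genes[sim$truth_genes$gene_id == g, ]
    expect_true(all(GenomicRanges::start(ex) >= row$start))
    expect_true(all(GenomicRanges::end(ex) <= row$end))
    expect_true(all(diff(GenomicRanges::start(ex)) > 0))
  }
  sim2 <- generate_annotation(p)
  expect_identical(sim$truth_genes, sim2$truth_genes)
  # infeasible genome is rejected with advice
  tiny <- small_params(seed = 1L)
  tiny$chrom_length <- 5e4
  expect_error(generate_annotation(tiny), "chrom_length")
})

test_that("noise-free peaks: consensus recovers the planted set exactly", {
  p <- small_params(seed = 32L, jitter_sd = 0, dropout_prob = 0)
  sim <- generate_peaks(generate_annotation(p), p)
  for (key in names(sim$replicate_peaks)[c(1, 4)]) {
    cons <- consensus_peaks(sim$replicate_peaks[[key]])
    planted <- sim$truth_peaks[sim$presence[, key], ]
    planted <- planted[order(planted$chrom, planted$start), ]
    expect_equal(as.character(GenomeInfoDb::seqnames(cons)), planted$chrom)
    expect_equal(GenomicRanges::start(cons), planted$start)
    expect_equal(GenomicRanges::end(cons), planted$end)
  }
})

test_that("decommissioning removes distal peaks at the final time point", {
  p <- small_params(seed = 33L, decommission_prob = 1)
  sim <- generate_peaks(generate_annotation(p), p)
  last_keys <- grep("APF44", colnames(sim$presence), value = TRUE)
  distal <- sim$truth_peaks$kind == "distal"
  expect_true(all(sim$truth_peaks$decommissioned[distal]))
  for (key in last_keys) expect_false(any(sim$presence[distal, key]))
  early_keys <- grep("L3", colnames(sim$presence), value = TRUE)
  for (key in early_keys) expect_true(all(sim$presence[distal, key]))
})

test_that("planted categories survive the pipeline at the default jitter", {
  p <- small_params(seed = 34L)
  sim <- generate_peaks(generate_annotation(p), p)
  aud <- audit_simulation(sim, p)
  expect_gte(aud$category_agreement, 0.98)
  expect_equal(aud$n_unmatched, 0L)
})

test_that("planted distal peaks are nearest their host gene", {
  p <- small_params(seed = 35L)
  sim <- generate_peaks(generate_annotation(p), p)
  distal <- sim$truth_peaks[sim$truth_peaks$kind == "distal", ]
  expect_true(all(distal$nearest_gene == distal$host_gene))
})

test_that("counts follow the planted classes and the classifier recovers them", {
  p <- small_params(seed = 36L)
  sim <- generate_counts(generate_annotation(p), p)
  # noise-free limit: repressed means strictly decrease at tiny dispersion
  p0 <- small_params(seed = 36L, dispersion = 1e-4)
  sim0 <- generate_counts(generate_annotation(p0), p0)
  lcpm0 <- log_cpm(sim0$counts)
  sheet0 <- sim0$sample_sheet[sim0$sample_sheet$tissue == "wing", ]
  calls0 <- classify_repressed(lcpm0[, sheet0$sample_id], sheet0)
  planted0 <- sim0$truth_genes$expr_class == "repressed"
  expect_true(all(calls0$is_repressed[planted0]))
  # at the study dispersion, recovery of planted repressed genes >= 90%
  lcpm <- log_cpm(sim$counts)
  sheet <- sim$sample_sheet[sim$sample_sheet$tissue == "wing", ]
  calls <- classify_repressed(lcpm[, sheet$sample_id], sheet)
  planted <- sim$truth_genes$expr_class == "repressed"
  expect_gte(mean(calls$is_repressed[planted]), 0.9)
  # repressed calls are always a subset of expressed calls
  expect_true(all(calls$is_expressed[calls$is_repressed]))
  # determinism
  sim2 <- generate_counts(generate_annotation(p), p)
  expect_identical(sim$counts, sim2$counts)
})

test_that("enhancers sit on the intended peak kinds and coverage marks peaks", {
  p <- small_params(seed = 37L)
  sim <- generate_enhancers_and_coverage(
    generate_peaks(generate_annotation(p), p), p)
  prom_pk <- with(sim$truth_peaks[sim$truth_peaks$kind == "promoter", ],
                  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end)))
  # every HK region overlaps a promoter-kind planted peak
  expect_true(all(IRanges::overlapsAny(sim$hk_enhancers, prom_pk)))
  key <- colnames(sim$presence)[1]
  cov <- sim$coverage[[key]]
  present <- sim$truth_peaks[sim$presence[, key], ][1:5, ]
  for (i in 1:5) {
    inside <- mean(as.numeric(cov[[present$chrom[i]]][
      present$start[i]:present$end[i]]))
    flank <- mean(as.numeric(cov[[present$chrom[i]]][
      (present$end[i] + 600):(present$end[i] + 800)]))
    expect_gt(inside, flank)
  }
  # metaprofile at planted peak centers peaks at offset 0
  anchors <- GenomicRanges::GRanges(
    present$chrom, IRanges::IRanges(present$center, present$center))
  prof <- metaprofile(cov, anchors, flank = 1000, bin_size = 50)
  central <- abs(prof$offset) <= 50
  expect_gt(min(prof$mean_signal[central]), max(prof$mean_signal[abs(prof$offset) > 900]))
})

test_that("the emitted file set is byte-identical for identical seeds", {
  p <- small_params(seed = 38L)
  d1 <- file.path(tempdir(), "det_sim_a")
  d2 <- file.path(tempdir(), "det_sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  simulate_dataset(p, d1)
  simulate_dataset(p, d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  f2 <- sort(list.files(d2, recursive = TRUE))
  expect_identical(f1, f2)
  for (f in setdiff(f1, "config.yaml")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed changes the data
  d3 <- file.path(tempdir(), "det_sim_c")
  unlink(d3, recursive = TRUE)
  simulate_dataset(small_params(seed = 39L), d3)
  expect_false(identical(readLines(file.path(d1, "counts.tsv")),
                         readLines(file.path(d3, "counts.tsv"))))
})
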