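flat_track <- function(level, len = 10000, chrom = "chrT") {
  out <- IRanges::RleList(S4Vectors::Rle(level, len))
  names(out) <- chrom
  out
}

test_that("uniform coverage gives a flat profile at the coverage level", {
  prof <- metaprofile(flat_track(5), df_to_granges(
    data.frame(start = 5000, end = 5000)), flank = 1000, bin_size = 10)
  expect_equal(nrow(prof), 200L)
  expect_true(all(prof$mean_signal == 5))
  expect_equal(prof$offset[1], -995)
  expect_equal(prof$offset[200], 995)
})

test_that("a narrow block of signal lands in the two central bins", {
  # coverage 10 over the 20 bases centred on the anchor, else 0
  center <- 5000L
  v <- S4Vectors::Rle(c(0, 10, 0), c(center - 11, 20, 10000 - center - 9))
  track <- IRanges::RleList(v); names(track) <- "chrT"
  anchors <- GenomicRanges::GRanges("chrT", IRanges::IRanges(center, center))
  prof <- metaprofile(track, anchors, flank = 1000, bin_size = 10)
  hot <- prof$mean_signal > 0
  expect_equal(which(hot), c(100L, 101L))
  expect_equal(prof$mean_signal[hot], c(10, 10))
})

test_that("minus-strand windows are reversed and averaged with forward ones", {
  # asymmetric ramp track
  L <- 4000L
  v <- S4Vectors::Rle(as.numeric(seq_len(L)))
  track <- IRanges::RleList(v); names(track) <- "chrT"
  plus <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2000, 2000), strand = "+")
  minus <- GenomicRanges::GRanges("chrT", IRanges::IRanges(2000, 2000), strand = "-")
  both <- c(plus, minus)
  pf <- metaprofile(track, plus, flank = 100, bin_size = 10)
  pr <- metaprofile(track, minus, flank = 100, bin_size = 10)
  pb <- metaprofile(track, both, flank = 100, bin_size = 10)
  # reversal oracle: the minus profile is the flipped plus profile
  expect_equal(pr$mean_signal, rev(pf$mean_signal))
  expect_equal(pb$mean_signal, (pf$mean_signal + pr$mean_signal) / 2)
  # a forward ramp + its reverse is symmetric about offset 0
  expect_equal(pb$mean_signal, rev(pb$mean_signal))
})

test_that("profile equals the brute-force per-anchor window mean", {
  set.seed(21)
  L <- 6000L
  vals <- round(runif(L) * 10)
  track <- IRanges::RleList(S4Vectors::Rle(vals)); names(track) <- "chrT"
  pos <- sample(300:(L - 300), 7)
  anchors <- GenomicRanges::GRanges("chrT", IRanges::IRanges(pos, pos))
  prof <- metaprofile(track, anchors, flank = 200, bin_size = 20)
  brute <- rowMeans(vapply(pos, function(p) vals[(p - 200):(p + 199)],
                           numeric(400)))
  brute_binned <- colMeans(matrix(brute, nrow = 20))
  expect_equal(prof$mean_signal, brute_binned)
  expect_equal(unique(prof$n_anchors), 7L)
})

test_that("windows truncated at chromosome ends are padded with zeros", {
  prof <- metaprofile(flat_track(3, len = 1000),
                      df_to_granges(data.frame(start = 50, end = 50)),
                      flank = 100, bin_size = 100)
  # left half is mostly off-chromosome: mean < right half
  expect_lt(prof$mean_signal[1], prof$mean_signal[2])
  # missing chromosome contributes zeros rather than an error
  far <- GenomicRanges::GRanges("chrMissing", IRanges::IRanges(500, 500))
  prof2 <- metaprofile(flat_track(3), far, flank = 100, bin_size = 10)
  expect_true(all(prof2$mean_signal == 0))
  expect_error(metaprofile(flat_track(3), GenomicRanges::GRanges()), "anchors")
  expect_error(metaprofile(flat_track(3), far, flank = 100, bin_size = 30),
               "divisible")
})

test_that("anchors derive from peak centers, summits, and gene TSSs", {
  pk <- GenomicRanges::GRanges("chrT", IRanges::IRanges(101, 200))
  a <- anchors_from(pk, "peak_center")
  expect_equal(GenomicRanges::start(a), 151L)  # midpoint of [100,200) is 150 (0-based)
  expect_equal(as.character(GenomicRanges::strand(a)), "*")
  pk$summit_offset <- 10L
  expect_equal(GenomicRanges::start(anchors_from(pk, "peak_center")), 111L)
  genes <- list(list(gene_id = "g1", start = 1001, end = 2000, strand = "-",
                     exons = list(c(1001, 2000))))
  tssa <- anchors_from(toy_genes_to_models(genes), "tss")
  expect_equal(GenomicRanges::start(tssa), 2000L)
  expect_equal(as.character(GenomicRanges::strand(tssa)), "-")
})

test_that("bedGraph round trip and CPM scaling", {
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(c(1, 501), c(500, 900)),
                               score = c(2, 6))
  f <- tempfile(fileext = ".bedGraph")
  rtracklayer::export(gr, f, format = "bedGraph")
  cov <- read_coverage(f)
  expect_equal(as.numeric(cov[["chrT"]][c(1, 500, 501, 900)]), c(2, 2, 6, 6))
  scaled <- cpm_scale_track(cov)
  expect_equal(sum(as.numeric(sum(scaled))), 1e6)
})
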