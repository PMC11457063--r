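toy_index <- function(genes, ...) build_feature_index(toy_genes_to_models(genes), ...)

test_that("anchor classification follows the feature precedence", {
  genes <- list(list(gene_id = "G", start = 5001, end = 8000, strand = "+",
                     exons = list(c(5001, 5200), c(7801, 8000))))
  idx <- toy_index(genes)
  pk <- function(s, e) df_to_granges(data.frame(start = s, end = e))
  # anchor at 4500 sits in the promoter [4001, 5100]
  a1 <- assign_peaks(pk(4401, 4600), idx)
  expect_equal(a1$category, "promoter")
  expect_equal(a1$nearest_gene_id, "G")
  # anchor at 6000 sits in the intron [5201, 7800]
  expect_equal(assign_peaks(pk(5901, 6100), idx)$category, "intron")
  # distant anchor is intergenic with a signed TSS distance of +15000
  a3 <- assign_peaks(pk(19901, 20100), idx)
  expect_equal(a3$category, "intergenic")
  expect_equal(a3$tss_distance, 15000L)
})

test_that("summit overrides the midpoint anchor and minus strands sign distances", {
  genes <- list(list(gene_id = "G", start = 5001, end = 8000, strand = "-",
                     exons = list(c(5001, 5200), c(7801, 8000))))
  idx <- toy_index(genes)
  # summit moves the anchor from the midpoint (8100, intergenic-ward) into
  # the exon [7801, 8000]; the minus-strand promoter [7901, 9000] does not
  # reach 7850, so exon wins
  pk <- GenomicRanges::GRanges("chrT", IRanges::IRanges(7801, 8400))
  pk$summit_offset <- 49L
  a <- assign_peaks(pk, idx)
  expect_equal(a$anchor, 7850L)
  expect_equal(a$category, "exon")
  # TSS at 8000 on minus strand: anchor 7850 lies downstream of the TSS in
  # transcription orientation -> positive distance
  expect_equal(a$tss_distance, 150L)
  # without the summit the midpoint anchor (8100) falls in the promoter
  pk2 <- GenomicRanges::GRanges("chrT", IRanges::IRanges(7801, 8400))
  expect_equal(assign_peaks(pk2, idx)$category, "promoter")
})

test_that("nearest-gene ties break to the lexicographically smallest id", {
  genes <- list(
    list(gene_id = "gB", start = 1001, end = 2000, strand = "+",
         exons = list(c(1001, 2000))),
    list(gene_id = "gA", start = 3001, end = 4000, strand = "+",
         exons = list(c(3001, 4000))))
  idx <- toy_index(genes)
  # anchor equidistant (1000 bp) from both TSSs at 1001 and 3001
  a <- assign_peaks(df_to_granges(data.frame(start = 2001, end = 2001)), idx)
  expect_equal(a$nearest_gene_id, "gA")
})

test_that("assignment matches the per-base oracle on random toy genomes", {
  L <- 50000L
  for (trial in 1:100) {
    genes <- random_toy_genes(sample(2:12, 1), L, seed = 5000 + trial)
    if (!length(genes)) next
    idx <- toy_index(genes)
    truth <- oracle_labels(genes, L)
    set.seed(6000 + trial)
    n_pk <- 12L
    anchors <- sample(1100:(L - 1100), n_pk)
    pk <- df_to_granges(data.frame(start = anchors - 50, end = anchors + 49))
    # midpoint of [a-50, a+49] is a
    asn <- assign_peaks(pk, idx)
    expect_equal(asn$anchor, anchors)
    expect_equal(asn$category, truth[anchors], info = paste("trial", trial))
    for (j in seq_len(n_pk)) {
      o <- oracle_nearest(genes, anchors[j])
      expect_equal(asn$nearest_gene_id[j], o$gene_id)
      expect_equal(asn$tss_distance[j], o$distance)
    }
    # every peak gets exactly one category and proportions sum to 1
    d <- category_distribution(asn)
    expect_equal(sum(d$proportion), 1)
    expect_equal(sum(d$count), n_pk)
  }
})

test_that("peaks with no annotated chromosome raise an informative error", {
  genes <- list(list(gene_id = "G", start = 1001, end = 2000, strand = "+",
                     exons = list(c(1001, 2000))))
  idx <- toy_index(genes)
  pk <- GenomicRanges::GRanges("chrZ", IRanges::IRanges(100, 200))
  expect_error(assign_peaks(pk, idx), "chrZ")
})

test_that("peaks-per-gene tallies, bins, and the >=10 scheme", {
  asn <- data.frame(nearest_gene_id = c("g1", "g2", "g2"))
  ppg <- peaks_per_gene(asn)
  expect_equal(ppg$counts, c(g1 = 1L, g2 = 2L))
  # counts {1, 1, 2, 7} under bins 1,2,3,4,>=5 -> 0.5 / 0.25 / 0 / 0 / 0.25
  asn2 <- data.frame(nearest_gene_id = c("a", "b", rep("c", 2), rep("d", 7)))
  bins <- peaks_per_gene(asn2, bin_edges = 1:5)$bins
  expect_equal(bins$proportion, c(0.5, 0.25, 0, 0, 0.25))
  expect_equal(sum(bins$proportion), 1)
  # the >=10 top bin used for mammalian-style complexity analysis
  asn3 <- data.frame(nearest_gene_id = c(rep("x", 11), "y"))
  bins10 <- peaks_per_gene(asn3, bin_edges = 1:10)$bins
  expect_equal(bins10$bin[10], ">=10")
  expect_equal(bins10$proportion[bins10$bin == ">=10"], 0.5)
  expect_error(peaks_per_gene(asn, bin_edges = c(2, 3)), "start at 1")
})

test_that("gene-set subsetting retains matches and warns on unknown ids", {
  asn <- data.frame(nearest_gene_id = c("g1", "g2", "g3", "g2", "g4"),
                    chrom = "chrT", start = 1:5, end = 2:6)
  expect_equal(nrow(suppressWarnings(
    subset_by_gene_set(asn, c("g2", "g9"), known_genes = paste0("g", 1:4)))), 2L)
  expect_warning(subset_by_gene_set(asn, c("g2", "g9"),
                                    known_genes = paste0("g", 1:4)), "g9")
  expect_equal(nrow(subset_by_gene_set(asn, paste0("g", 1:4))), 5L)
  expect_error(subset_by_gene_set(asn, character(0)), "non-empty")
})

test_that("union peak set merges across datasets and ignores dataset order", {
  mk <- function(start, end, gene) data.frame(
    chrom = "chrT", start = start, end = end, nearest_gene_id = gene)
  wing <- mk(101, 200, "cc1")
  eye <- mk(121, 220, "cc1")
  u <- union_gene_set_peaks(list(wing, eye), "cc1")
  expect_equal(c(GenomicRanges::start(u), GenomicRanges::end(u)), c(101L, 220L))
  # disjoint peaks from two tissues stay separate
  u2 <- union_gene_set_peaks(list(mk(101, 200, "cc1"), mk(1001, 1100, "cc1")), "cc1")
  expect_equal(length(u2), 2L)
  # single dataset: merged subset of that dataset
  u3 <- union_gene_set_peaks(list(rbind(wing, eye)), "cc1")
  expect_equal(GenomicRanges::start(u3), 101L)
  # order invariance
  u_ab <- union_gene_set_peaks(list(wing, eye), "cc1")
  u_ba <- union_gene_set_peaks(list(eye, wing), "cc1")
  expect_identical(as.data.frame(u_ab), as.data.frame(u_ba))
})
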