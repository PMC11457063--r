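gff3_text <- function(lines) {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), f)
  f
}

test_that("GFF coordinates, strand-aware TSS, and exon union across transcripts", {
  f <- gff3_text(c(
    "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=gA",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.t1;Parent=gA",
    "chr1\tsrc\texon\t1001\t1200\t.\t+\t.\tParent=gA.t1",
    "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=gA.t2;Parent=gA",
    "chr1\tsrc\texon\t1101\t1300\t.\t+\t.\tParent=gA.t2",
    "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=gB",
    "chr1\tsrc\tmRNA\t5001\t6000\t.\t-\t.\tID=gB.t1;Parent=gB",
    "chr1\tsrc\texon\t5001\t6000\t.\t-\t.\tParent=gB.t1"))
  m <- read_gene_models(f)
  expect_equal(m$genes$gene_id, c("gA", "gB"))
  expect_equal(GenomicRanges::start(m$genes), c(1001L, 5001L))
  expect_equal(GenomicRanges::end(m$genes), c(2000L, 6000L))
  tss <- gene_tss(m$genes)
  # plus-strand TSS at gene start, minus-strand at gene end
  expect_equal(GenomicRanges::start(tss), c(1001L, 6000L))
  # exon union across the two transcripts of gA
  exA <- m$exons[["gA"]]
  expect_equal(length(exA), 1L)
  expect_equal(GenomicRanges::start(exA), 1001L)
  expect_equal(GenomicRanges::end(exA), 1300L)
  # per-base union oracle agrees
  base_union <- sort(unique(c(1001:1200, 1101:1300)))
  got <- unlist(lapply(seq_along(exA), function(i)
    GenomicRanges::start(exA)[i]:GenomicRanges::end(exA)[i]))
  expect_equal(got, base_union)
})

test_that("feature index windows match hand-computed regions on both strands", {
  genes <- list(list(gene_id = "g1", start = 5001, end = 8000, strand = "+",
                     exons = list(c(5001, 5200), c(7801, 8000))))
  idx <- build_feature_index(toy_genes_to_models(genes),
                             promoter_up = 1000, promoter_down = 100,
                             downstream_len = 1000)
  expect_equal(c(GenomicRanges::start(idx$promoter),
                 GenomicRanges::end(idx$promoter)), c(4001, 5100))
  expect_equal(c(GenomicRanges::start(idx$intron),
                 GenomicRanges::end(idx$intron)), c(5201, 7800))
  expect_equal(c(GenomicRanges::start(idx$downstream),
                 GenomicRanges::end(idx$downstream)), c(8001, 9000))

  genes[[1]]$strand <- "-"
  idx2 <- build_feature_index(toy_genes_to_models(genes),
                              promoter_up = 1000, promoter_down = 100,
                              downstream_len = 1000)
  expect_equal(c(GenomicRanges::start(idx2$promoter),
                 GenomicRanges::end(idx2$promoter)), c(7901, 9000))
  expect_equal(c(GenomicRanges::start(idx2$downstream),
                 GenomicRanges::end(idx2$downstream)), c(4001, 5000))
})

test_that("intronless genes produce no intron regions", {
  genes <- list(list(gene_id = "g1", start = 1000, end = 1500, strand = "+",
                     exons = list(c(1000, 1500))))
  idx <- build_feature_index(toy_genes_to_models(genes))
  expect_equal(length(idx$intron), 0L)
})

test_that("feature index equals per-base labelling on random gene structures", {
  L <- 50000L
  for (trial in 1:100) {
    genes <- random_toy_genes(n_genes = sample(2:8, 1), L = L, seed = 4000 + trial)
    if (!length(genes)) next
    idx <- build_feature_index(toy_genes_to_models(genes))
    truth <- oracle_labels(genes, L)
    # rebuild a per-base labelling from the index regions under the same
    # precedence and compare everywhere
    got <- rep("intergenic", L)
    for (cat in c("downstream", "intron", "exon", "promoter")) {
      gr <- idx[[cat]]
      for (i in seq_along(gr)) {
        a <- max(1L, GenomicRanges::start(gr)[i])
        b <- min(L, GenomicRanges::end(gr)[i])
        if (a <= b) got[a:b] <- cat
      }
    }
    expect_identical(got, truth)
  }
})

test_that("gene models round-trip through the canonical GFF3 export", {
  genes <- random_toy_genes(6, 30000L, seed = 99)
  m <- toy_genes_to_models(genes)
  f <- tempfile(fileext = ".gff3")
  write_gene_models(m, f)
  m2 <- read_gene_models(f)
  expect_equal(m2$genes$gene_id, m$genes$gene_id)
  expect_equal(GenomicRanges::start(m2$genes), GenomicRanges::start(m$genes))
  expect_equal(as.character(GenomicRanges::strand(m2$genes)),
               as.character(GenomicRanges::strand(m$genes)))
  for (g in m$genes$gene_id) {
    expect_equal(GenomicRanges::start(m2$exons[[g]]),
                 GenomicRanges::start(m$exons[[g]]))
    expect_equal(GenomicRanges::end(m2$exons[[g]]),
                 GenomicRanges::end(m$exons[[g]]))
  }
  # idempotence: a second write/read cycle changes nothing
  f2 <- tempfile(fileext = ".gff3")
  write_gene_models(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("malformed annotations and bad windows are rejected", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "chr1\tsrc\tgene\tnot_a_number\t10\t.\t+\t.\tID=g1"), f)
  expect_error(read_gene_models(f), "parse")
  genes <- list(list(gene_id = "g1", start = 1000, end = 1500, strand = "+",
                     exons = list(c(1000, 1500))))
  expect_error(build_feature_index(toy_genes_to_models(genes),
                                   promoter_up = -5), ">= 0")
})
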