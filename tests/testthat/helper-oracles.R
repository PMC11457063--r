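# Independent brute-force oracles. Everything here works per base on small
# toy genomes and never calls the package's interval engine.

# Random toy gene structures (1-based closed coordinates), non-overlapping
# spans, 1-4 exons each. Returns a list of plain-R gene records.
random_toy_genes <- function(n_genes, L, seed) {
  set.seed(seed)
  genes <- list()
  cursor <- sample(1200:2000, 1)
  for (i in seq_len(n_genes)) {
    n_ex <- sample(1:4, 1)
    w <- sample(50:300, n_ex, replace = TRUE)
    g <- if (n_ex > 1) sample(30:500, n_ex - 1, replace = TRUE) else integer(0)
    span <- sum(w) + sum(g)
    start <- cursor + sample(60:600, 1)
    end <- start + span - 1
    if (end > L - 1200) break
    ex_st <- start + cumsum(c(0L, utils::head(w, -1) + g))
    genes[[length(genes) + 1]] <- list(
      gene_id = sprintf("t%03d", i), start = start, end = end,
      strand = sample(c("+", "-"), 1),
      exons = Map(c, ex_st, ex_st + w - 1))
    cursor <- end
  }
  genes
}

toy_genes_to_models <- function(genes, chrom = "chrT") {
  gr <- GenomicRanges::GRanges(
    chrom,
    IRanges::IRanges(vapply(genes, `[[`, 1, "start"),
                     vapply(genes, `[[`, 1, "end")),
    strand = vapply(genes, `[[`, "", "strand"))
  gr$gene_id <- vapply(genes, `[[`, "", "gene_id")
  ex <- lapply(genes, function(g) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(
      vapply(g$exons, `[[`, 1, 1), vapply(g$exons, `[[`, 1, 2)))
  })
  exl <- as(ex, "GRangesList")
  names(exl) <- gr$gene_id
  list(genes = gr, exons = exl)
}

# Per-base category labelling by precedence, computed independently.
oracle_labels <- function(genes, L, up = 1000, down = 100, dlen = 1000) {
  prom <- ex <- intr <- dwn <- rep(FALSE, L)
  mark <- function(v, a, b) {
    a <- max(1, a); b <- min(L, b)
    if (a <= b) v[a:b] <- TRUE
    v
  }
  for (g in genes) {
    if (g$strand == "+") {
      tss <- g$start
      prom <- mark(prom, tss - up, tss + down - 1)
      dwn <- mark(dwn, g$end + 1, g$end + dlen)
    } else {
      tss <- g$end
      prom <- mark(prom, tss - down + 1, tss + up)
      dwn <- mark(dwn, g$start - dlen, g$start - 1)
    }
    exmask <- rep(FALSE, L)
    for (e in g$exons) exmask[e[1]:e[2]] <- TRUE
    ex <- ex | exmask
    body <- rep(FALSE, L)
    body[g$start:g$end] <- TRUE
    intr <- intr | (body & !exmask)
  }
  out <- rep("intergenic", L)
  out[dwn] <- "downstream"
  out[intr] <- "intron"
  out[ex] <- "exon"
  out[prom] <- "promoter"
  out
}

# Nearest gene by |anchor - TSS|, lexicographic tie-break, signed distance
# in transcription orientation.
oracle_nearest <- function(genes, anchor) {
  tss <- vapply(genes, function(g) if (g$strand == "+") g$start else g$end, 1)
  ids <- vapply(genes, `[[`, "", "gene_id")
  strands <- vapply(genes, `[[`, "", "strand")
  d <- abs(anchor - tss)
  cand <- which(d == min(d))
  pick <- cand[order(ids[cand])][1]
  signed <- anchor - tss[pick]
  if (strands[pick] == "-") signed <- -signed
  list(gene_id = ids[pick], distance = signed)
}

# Consensus oracle: per-base occupancy matrix, union runs, retained iff
# every replicate covers at least one base of the run.
oracle_consensus <- function(rep_sets, L) {
  occ <- vapply(rep_sets, function(s) {
    v <- rep(FALSE, L)
    for (i in seq_len(nrow(s))) v[s$start[i]:s$end[i]] <- TRUE
    v
  }, logical(L))
  any_cov <- rowSums(occ) > 0
  r <- rle(any_cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    if (all(colSums(occ[run, , drop = FALSE]) > 0))
      out[[length(out) + 1]] <- c(starts[k], ends[k])
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

random_replicate_sets <- function(n_reps, L, seed) {
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    n <- sample(0:8, 1)
    if (n == 0) return(data.frame(start = integer(), end = integer()))
    st <- sort(sample(seq_len(L - 300), n))
    data.frame(start = st, end = pmin(st + sample(20:250, n, replace = TRUE), L))
  })
}

df_to_granges <- function(df, chrom = "chrT") {
  GenomicRanges::GRanges(rep(chrom, nrow(df)),
                         IRanges::IRanges(df$start, df$end))
}
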