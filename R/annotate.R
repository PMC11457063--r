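#' Assign peaks to genomic features and nearest genes
#'
#' Each peak is represented by a single anchor base — the called summit when
#' available, otherwise the interval midpoint — and classified by the first
#' feature containing that base in the precedence
#' promoter > exon > intron > downstream > intergenic. The nearest gene is
#' the gene minimizing the absolute distance between the anchor and its TSS;
#' ties are broken by the lexicographically smallest gene id so assignment is
#' deterministic. The signed TSS distance is reported in transcription
#' orientation (positive = anchor downstream of the TSS).
#'
#' @param peaks `GRanges` of peaks, optionally with a `summit_offset` column
#'   (0-based offset from peak start).
#' @param index A `FeatureIndex` from [build_feature_index()].
#' @param assign_by `"anchor"` (default; classify the anchor base) or
#'   `"overlap"` (classify by any >= 1 bp overlap of the whole peak interval,
#'   same precedence).
#' @return A `data.frame` with one row per peak: `chrom`, `start`, `end`
#'   (1-based closed peak coordinates), `peak` (stable key), `anchor`
#'   (1-based anchor position), `category`, `nearest_gene_id`,
#'   `tss_distance`.
#' @export
assign_peaks <- function(peaks, index, assign_by = c("anchor", "overlap")) {
  assign_by <- match.arg(assign_by)
  stopifnot(inherits(index, "FeatureIndex"))
  if (length(peaks) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      peak = character(), anchor = integer(),
                      category = character(), nearest_gene_id = character(),
                      tss_distance = integer(), stringsAsFactors = FALSE))
  }
  pk_chrom <- as.character(GenomeInfoDb::seqnames(peaks))
  gene_chroms <- unique(as.character(GenomeInfoDb::seqnames(index$genes)))
  missing_chrom <- setdiff(unique(pk_chrom), gene_chroms)
  if (length(missing_chrom))
    stop("no genes annotated on chromosome(s): ",
         paste(missing_chrom, collapse = ", "))

  anchor <- peak_anchor(peaks)
  query <- if (assign_by == "anchor") {
    GenomicRanges::GRanges(pk_chrom, IRanges::IRanges(anchor, width = 1L))
  } else {
    GenomicRanges::granges(peaks)
  }

  category <- rep("intergenic", length(peaks))
  for (cat in rev(c("promoter", "exon", "intron", "downstream"))) {
    hit <- IRanges::overlapsAny(query, index[[cat]], ignore.strand = TRUE)
    category[hit] <- cat
  }

  nn <- nearest_tss(pk_chrom, anchor, index$tss)

  data.frame(chrom = pk_chrom,
             start = GenomicRanges::start(peaks),
             end = GenomicRanges::end(peaks),
             peak = peak_key(peaks),
             anchor = anchor,
             category = category,
             nearest_gene_id = nn$gene_id,
             tss_distance = nn$distance,
             stringsAsFactors = FALSE)
}

# Anchor base (1-based): summit position when recorded, else interval
# midpoint (lower of the two central bases for even widths).
peak_anchor <- function(peaks) {
  st <- GenomicRanges::start(peaks)
  en <- GenomicRanges::end(peaks)
  anchor <- (st + en - 1L) %/% 2L + 1L
  so <- S4Vectors::mcols(peaks)$summit_offset
  if (!is.null(so)) {
    use <- !is.na(so)
    anchor[use] <- st[use] + as.integer(so[use])
  }
  anchor
}

# Nearest gene by |anchor - TSS| with lexicographic gene-id tie-break;
# signed distance in transcription orientation.
nearest_tss <- function(chrom, anchor, tss) {
  gene_id <- rep(NA_character_, length(anchor))
  distance <- rep(NA_integer_, length(anchor))
  t_chrom <- as.character(GenomeInfoDb::seqnames(tss))
  for (ch in unique(chrom)) {
    sel <- which(t_chrom == ch)
    tpos <- GenomicRanges::start(tss)[sel]
    tid <- tss$gene_id[sel]
    tstr <- as.character(GenomicRanges::strand(tss))[sel]
    o <- order(tpos, tid)
    tpos <- tpos[o]; tid <- tid[o]; tstr <- tstr[o]
    upos <- unique(tpos)
    first_idx <- match(upos, tpos)
    qi <- which(chrom == ch)
    k <- findInterval(anchor[qi], upos)
    for (j in seq_along(qi)) {
      a <- anchor[qi[j]]
      kl <- k[j]; kr <- kl + 1L
      dl <- if (kl >= 1L) a - upos[kl] else NA_integer_
      dr <- if (kr <= length(upos)) upos[kr] - a else NA_integer_
      dmin <- min(dl, dr, na.rm = TRUE)
      cand <- integer(0)
      if (!is.na(dl) && dl == dmin) cand <- c(cand, first_idx[kl])
      if (!is.na(dr) && dr == dmin) cand <- c(cand, first_idx[kr])
      pick <- cand[order(tid[cand])][1L]
      gene_id[qi[j]] <- tid[pick]
      d <- a - tpos[pick]
      distance[qi[j]] <- if (tstr[pick] == "-") -d else d
    }
  }
  list(gene_id = gene_id, distance = distance)
}

#' Peaks-per-gene counts and binned proportions
#'
#' Tallies the number of peaks assigned (by nearest gene, regardless of
#' category) to each gene, then bins genes by that count. Bin proportions
#' are over genes with at least one peak and sum to 1. The per-gene peak
#' count is the package's measure of regulatory-architecture complexity:
#' simple genes sit in bin 1, complex loci in the open-ended top bin.
#'
#' @param assignments Assignment table from [assign_peaks()].
#' @param bin_edges Increasing integer vector of bin lower edges starting at
#'   1; the last edge opens an unbounded `>=` bin. Default `1:5` gives bins
#'   1, 2, 3, 4, >=5; use `1:10` for a >=10 top bin.
#' @return A list with `counts` (named integer vector, gene id -> peak
#'   count) and `bins` (`data.frame` with `bin`, `n_genes`, `proportion`).
#' @export
peaks_per_gene <- function(assignments, bin_edges = 1:5) {
  stopifnot(is.data.frame(assignments))
  if (nrow(assignments) == 0L)
    return(list(counts = setNames(integer(0), character(0)),
                bins = data.frame(bin = character(), n_genes = integer(),
                                  proportion = numeric())))
  if (length(bin_edges) < 2L || bin_edges[1] != 1L || any(diff(bin_edges) <= 0))
    stop("'bin_edges' must be increasing and start at 1")
  tab <- table(assignments$nearest_gene_id)
  counts <- setNames(as.integer(tab), names(tab))
  bins <- bin_gene_counts(counts, bin_edges)
  list(counts = counts, bins = bins)
}

bin_gene_counts <- function(counts, bin_edges = 1:5) {
  labels <- c(as.character(bin_edges[-length(bin_edges)]),
              paste0(">=", bin_edges[length(bin_edges)]))
  f <- cut(counts, breaks = c(bin_edges - 0.5, Inf), labels = labels)
  n <- as.integer(table(f))
  data.frame(bin = labels, n_genes = n, proportion = n / sum(n),
             stringsAsFactors = FALSE)
}

#' Subset assignments to a gene set
#'
#' Retains assignments whose nearest gene is in the set. Gene ids in the set
#' that are absent from the annotation raise a warning (the set file may use
#' a different id universe) but never an error.
#'
#' @param assignments Assignment table from [assign_peaks()].
#' @param gene_set Character vector of gene ids (non-empty).
#' @param known_genes Optional character vector of annotated gene ids used
#'   for the missing-id warning.
#' @return The retained assignment rows.
#' @export
subset_by_gene_set <- function(assignments, gene_set, known_genes = NULL) {
  if (length(gene_set) == 0L) stop("'gene_set' must be non-empty")
  gene_set <- unique(as.character(gene_set))
  if (!is.null(known_genes)) {
    missing <- setdiff(gene_set, known_genes)
    if (length(missing))
      warning(length(missing), " gene-set id(s) absent from annotation: ",
              paste(utils::head(missing, 5), collapse = ", "),
              if (length(missing) > 5) ", ...")
  }
  assignments[assignments$nearest_gene_id %in% gene_set, , drop = FALSE]
}

#' Union peak set for a gene set across datasets
#'
#' Subsets every dataset's assignments to the gene set, pools the peak
#' intervals across tissues and time points, and merges overlapping
#' (>= 1 bp) or book-ended intervals into single union peaks.
#'
#' @param per_dataset_assignments List (length >= 1) of assignment tables.
#' @param gene_set Character vector of gene ids.
#' @param known_genes Optional annotated gene ids (see
#'   [subset_by_gene_set()]).
#' @return Sorted `GRanges` of union peaks.
#' @export
union_gene_set_peaks <- function(per_dataset_assignments, gene_set,
                                 known_genes = NULL) {
  if (!is.list(per_dataset_assignments) || length(per_dataset_assignments) < 1L)
    stop("'per_dataset_assignments' must be a non-empty list")
  subs <- lapply(per_dataset_assignments, subset_by_gene_set,
                 gene_set = gene_set, known_genes = known_genes)
  grs <- lapply(subs, assignments_to_granges)
  pooled <- do.call(c, unname(grs))
  GenomicRanges::sort(GenomicRanges::reduce(pooled, ignore.strand = TRUE))
}

#' Convert an assignment table back to peak intervals
#' @param assignments Assignment table.
#' @return `GRanges` of the peak intervals.
#' @export
assignments_to_granges <- function(assignments) {
  GenomicRanges::GRanges(assignments$chrom,
                         IRanges::IRanges(assignments$start, assignments$end))
}
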