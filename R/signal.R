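#' Read a per-base coverage track
#'
#' Imports a bedGraph or bigWig coverage track as a per-chromosome run-length
#' coverage vector. Positions not covered by any bedGraph record are 0.
#'
#' @param path Path to a `.bedGraph`/`.bg` or `.bw`/`.bigWig` file.
#' @return `RleList` of per-base coverage.
#' @export
read_coverage <- function(path) {
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "bigWig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  GenomicRanges::coverage(gr, weight = "score")
}

#' Scale a coverage track to counts per million
#'
#' Divides by the total signal mass and multiplies by 1e6; a helper for
#' synthetic tracks so their magnitudes resemble depth-normalized tracks.
#' @param cov `RleList` coverage.
#' @return Scaled `RleList`.
#' @export
cpm_scale_track <- function(cov) {
  total <- sum(as.numeric(sum(cov)))
  if (total <= 0) stop("track has no signal")
  cov * (1e6 / total)
}

#' Anchor points for metaprofiles
#'
#' Builds width-1 anchor positions either at peak centers (summit when
#' recorded, else midpoint; strand `*`, windows never reversed) or at gene
#' TSSs (carrying the gene strand, so minus-strand windows are reversed into
#' transcription orientation).
#'
#' @param x For `kind = "peak_center"`: a `GRanges` of peaks or an
#'   assignment table from [assign_peaks()]. For `kind = "tss"`: gene models
#'   from [read_gene_models()] or a gene `GRanges` with `gene_id`.
#' @param kind `"peak_center"` or `"tss"`.
#' @return `GRanges` of width-1 anchors.
#' @export
anchors_from <- function(x, kind = c("peak_center", "tss")) {
  kind <- match.arg(kind)
  if (kind == "peak_center") {
    if (is.data.frame(x)) {
      pos <- if ("anchor" %in% names(x)) x$anchor
             else (x$start + x$end - 1L) %/% 2L + 1L
      return(GenomicRanges::GRanges(x$chrom, IRanges::IRanges(pos, width = 1L),
                                    strand = "*"))
    }
    pos <- peak_anchor(x)
    gr <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(x),
                                 IRanges::IRanges(pos, width = 1L), strand = "*")
    return(gr)
  }
  genes <- if (is.list(x) && !is.null(x$genes)) x$genes else x
  gene_tss(genes)
}

#' Average signal metaprofile around anchor points
#'
#' Extracts a fixed window of `flank` bp either side of every anchor,
#' reverses windows of minus-strand anchors, bins each window by the mean
#' within consecutive `bin_size` bp bins, and averages across anchors.
#' Windows extending past chromosome ends are padded with 0 coverage, and
#' chromosomes absent from the track contribute all-zero windows.
#'
#' @param track Coverage as an `RleList` (see [read_coverage()]) or a path
#'   to a bedGraph/bigWig file.
#' @param anchors `GRanges` of width-1 anchor positions (non-empty); strand
#'   `-` anchors have their windows reversed.
#' @param flank Half-window size in bp (default 1000).
#' @param bin_size Bin width in bp; must divide `2 * flank` (default 10).
#' @param label Optional condition label stored in the output.
#' @return A `data.frame` with `offset` (bin center relative to the anchor),
#'   `mean_signal`, `n_anchors`, and `label`.
#' @export
metaprofile <- function(track, anchors, flank = 1000L, bin_size = 10L,
                        label = NA_character_) {
  if (length(anchors) == 0L) stop("no anchors supplied")
  if (flank <= 0 || bin_size <= 0 || (2L * flank) %% bin_size != 0L)
    stop("'flank' must be positive and 2*flank divisible by 'bin_size'")
  cov <- if (is.character(track)) read_coverage(track) else track
  width <- 2L * as.integer(flank)
  pos <- GenomicRanges::start(anchors)
  chrom <- as.character(GenomeInfoDb::seqnames(anchors))
  strand <- as.character(GenomicRanges::strand(anchors))
  acc <- numeric(width)
  for (i in seq_along(anchors)) {
    w <- extract_window(cov, chrom[i], pos[i], flank)
    if (strand[i] == "-") w <- rev(w)
    acc <- acc + w
  }
  prof <- acc / length(anchors)
  nbin <- width %/% as.integer(bin_size)
  binned <- colMeans(matrix(prof, nrow = bin_size, ncol = nbin))
  offsets <- -flank + (seq_len(nbin) - 0.5) * bin_size
  data.frame(offset = offsets, mean_signal = binned,
             n_anchors = length(anchors), label = label,
             stringsAsFactors = FALSE)
}

# Per-base window [pos - flank, pos + flank - 1] (1-based), zero-padded
# outside [1, chrom length] and for chromosomes missing from the track.
extract_window <- function(cov, chrom, pos, flank) {
  width <- 2L * as.integer(flank)
  from <- pos - as.integer(flank)
  to <- pos + as.integer(flank) - 1L
  out <- numeric(width)
  if (!(chrom %in% names(cov))) return(out)
  v <- cov[[chrom]]
  len <- length(v)
  lo <- max(from, 1L)
  hi <- min(to, len)
  if (lo > hi) return(out)
  out[(lo - from + 1L):(hi - from + 1L)] <- as.numeric(v[lo:hi])
  out
}
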