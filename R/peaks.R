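#' Read a narrowPeak (BED6+4) peak file
#'
#' @param path Path to a narrowPeak file.
#' @param tissue,timepoint,replicate Optional dataset labels attached as
#'   metadata columns.
#' @return `GRanges` with columns `name`, `signal` (signalValue), and
#'   `summit_offset` (0-based bp from peak start; `NA` where the file stores
#'   the `-1` sentinel).
#' @export
read_narrowpeak <- function(path, tissue = NA_character_,
                            timepoint = NA_character_, replicate = NA_integer_) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "narrowPeak"),
    error = function(e) stop("failed to parse narrowPeak '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  mc <- S4Vectors::mcols(gr)
  out <- GenomicRanges::granges(gr)
  out$name <- if (!is.null(mc$name)) as.character(mc$name)
              else rep(NA_character_, length(out))
  out$signal <- if (!is.null(mc$signalValue)) as.numeric(mc$signalValue)
                else rep(NA_real_, length(out))
  so <- if (!is.null(mc$peak)) as.integer(mc$peak) else rep(-1L, length(gr))
  so[so < 0L] <- NA_integer_
  bad <- !is.na(so) & so >= GenomicRanges::width(out)
  if (any(bad))
    stop("summit offset outside peak span at record(s) ",
         paste(which(bad), collapse = ", "))
  out$summit_offset <- so
  out$tissue <- rep(tissue, length(out))
  out$timepoint <- rep(timepoint, length(out))
  out$replicate <- rep(replicate, length(out))
  out
}

#' Read a BED interval file
#'
#' Thin wrapper over rtracklayer for BED3/BED6 region files (blacklists,
#' repeat regions, enhancer sets).
#' @param path Path to a BED file.
#' @return `GRanges`.
#' @export
read_bed <- function(path) {
  tryCatch(rtracklayer::import(path, format = "bed"),
           error = function(e) stop("failed to parse BED '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
}

#' Write intervals to BED
#' @param gr `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  out <- GenomicRanges::granges(gr)
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Filter fragments to the sub-nucleosomal size class
#'
#' Retains fragments spanning strictly less than `max_span` bp, the
#' sub-nucleosomal size class conventionally used to enrich ATAC-seq signal
#' for transcription-factor-bound open chromatin over nucleosomal fragments.
#'
#' @param fragments `GRanges` of fragments.
#' @param max_span Size cutoff in bp; fragments with span `< max_span` are
#'   kept. Default 120.
#' @return The retained fragments, input order preserved.
#' @export
filter_fragments <- function(fragments, max_span = 120L) {
  if (!is.numeric(max_span) || length(max_span) != 1L || max_span <= 0)
    stop("'max_span' must be a single positive number")
  fragments[GenomicRanges::width(fragments) < max_span]
}

#' Replicate-consensus peak set
#'
#' Merges the union of all replicate peaks into maximal overlapping (or
#' book-ended) intervals and keeps a merged interval only when every
#' replicate contributes at least one peak overlapping it by >= 1 bp —
#' i.e. only regions identified in all replicates survive. Summit and signal
#' columns are dropped: a consensus interval no longer belongs to any single
#' replicate's peak call.
#'
#' @param replicate_sets List (length >= 1) of `GRanges`, one per replicate.
#' @return Sorted `GRanges` of consensus peaks.
#' @export
consensus_peaks <- function(replicate_sets) {
  if (!is.list(replicate_sets) || length(replicate_sets) < 1L)
    stop("'replicate_sets' must be a non-empty list of GRanges")
  sets <- lapply(replicate_sets, GenomicRanges::granges)
  pooled <- do.call(c, unname(sets))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(pooled), ignore.strand = TRUE)
  if (length(merged) == 0L) return(merged)
  keep <- rep(TRUE, length(merged))
  for (s in sets) {
    keep <- keep & (GenomicRanges::countOverlaps(merged, s, ignore.strand = TRUE) > 0L)
  }
  GenomicRanges::sort(merged[keep])
}

#' Exclude peaks overlapping blacklist or repeat regions
#'
#' Removes every peak that overlaps any exclusion interval by at least 1 bp;
#' all other peaks pass through unchanged. Used for genome blacklist regions
#' and LINE/LTR repeat annotations.
#'
#' @param peaks `GRanges` of peaks.
#' @param exclusion `GRanges` of regions to exclude (may be empty).
#' @return The retained peaks.
#' @export
exclude_regions <- function(peaks, exclusion) {
  if (length(exclusion) == 0L) return(peaks)
  hit <- IRanges::overlapsAny(peaks, exclusion, ignore.strand = TRUE)
  peaks[!hit]
}
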