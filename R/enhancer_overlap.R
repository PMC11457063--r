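#' Classify peaks by housekeeping/developmental enhancer overlap
#'
#' Intersects each peak independently with a housekeeping (HK) and a
#' developmental (DEV) enhancer set — e.g. the two STARR-seq core-promoter
#' classes — and assigns exactly one class: `HK` (housekeeping only), `DEV`
#' (developmental only), `BOTH`, or `NONE`. Overlap requires at least
#' `min_overlap` shared bp with the respective set.
#'
#' @param peaks `GRanges` of peaks (typically a union peak set).
#' @param hk_regions,dev_regions `GRanges` of enhancer regions.
#' @param min_overlap Minimum shared bp (default 1).
#' @return A `data.frame` with `chrom`, `start`, `end`, `peak` (key) and
#'   `class`; attribute `fractions` = named per-class fractions
#'   (HK/DEV/BOTH/NONE summing to 1).
#' @export
classify_enhancer_overlap <- function(peaks, hk_regions, dev_regions,
                                      min_overlap = 1L) {
  if (!is.numeric(min_overlap) || min_overlap < 1L)
    stop("'min_overlap' must be >= 1")
  hk <- IRanges::overlapsAny(peaks, hk_regions,
                                   minoverlap = as.integer(min_overlap),
                                   ignore.strand = TRUE)
  dev <- IRanges::overlapsAny(peaks, dev_regions,
                                    minoverlap = as.integer(min_overlap),
                                    ignore.strand = TRUE)
  cls <- ifelse(hk & dev, "BOTH", ifelse(hk, "HK", ifelse(dev, "DEV", "NONE")))
  out <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(peaks)),
                    start = GenomicRanges::start(peaks),
                    end = GenomicRanges::end(peaks),
                    peak = peak_key(peaks),
                    class = factor(cls, levels = c("HK", "DEV", "BOTH", "NONE")),
                    stringsAsFactors = FALSE)
  tab <- table(out$class)
  attr(out, "fractions") <-
    if (nrow(out)) setNames(as.numeric(tab) / nrow(out), names(tab))
    else setNames(rep(NA_real_, 4), c("HK", "DEV", "BOTH", "NONE"))
  out
}

#' Genomic-feature distribution per enhancer class
#'
#' For each enhancer class, the genomic-feature distribution of its peaks
#' (via [category_distribution()]). Classes with no peaks are omitted with a
#' message. Calls and assignments must describe the same peak set.
#'
#' @param calls Output of [classify_enhancer_overlap()].
#' @param assignments Assignment table from [assign_peaks()] for the same
#'   peaks.
#' @return Named list of `category_distribution()` tables, one per
#'   non-empty class.
#' @export
per_class_distribution <- function(calls, assignments) {
  orphans <- setdiff(calls$peak, assignments$peak)
  if (length(orphans))
    stop("peak(s) in calls without an assignment: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) ", ...")
  cat_by_peak <- setNames(assignments$category, assignments$peak)
  out <- list()
  for (cl in levels(calls$class)) {
    pk <- calls$peak[calls$class == cl]
    if (!length(pk)) {
      message("enhancer class ", cl, " has no peaks; distribution omitted")
      next
    }
    out[[cl]] <- category_distribution(
      data.frame(category = unname(cat_by_peak[pk]), stringsAsFactors = FALSE))
  }
  out
}
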