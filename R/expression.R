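#' Read and validate a sample sheet
#'
#' @param path TSV with columns `sample_id`, `tissue`, `timepoint`,
#'   `timepoint_rank` (integer giving the temporal order), `replicate`.
#' @return Validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv(path)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet `data.frame` to validate in place.
#' @export
validate_sample_sheet <- function(sheet) {
  need <- c("sample_id", "tissue", "timepoint", "timepoint_rank", "replicate")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(sheet$sample_id)) stop("duplicate sample_id in sheet")
  key <- paste(sheet$tissue, sheet$timepoint, sheet$replicate)
  if (anyDuplicated(key)) stop("duplicate (tissue, timepoint, replicate)")
  if (anyNA(sheet$timepoint_rank)) stop("every timepoint needs a rank")
  rk <- unique(sheet[, c("timepoint", "timepoint_rank")])
  if (anyDuplicated(rk$timepoint)) stop("inconsistent timepoint ranks")
  sheet
}

#' logCPM normalization of a count matrix
#'
#' Library-size normalization to log2 counts per million with an additive
#' prior: `log2((count + prior) / (libsize + 2 * prior) * 1e6)`. This is the
#' standard logCPM transform; it preserves within-gene trends across
#' samples, which is all the downstream monotonicity classifier uses.
#'
#' @param counts Numeric matrix of raw counts, genes x samples (non-negative
#'   integers).
#' @param prior Additive prior count (default 0.5).
#' @return Matrix of logCPM values with a `"normalized"` attribute set.
#' @export
log_cpm <- function(counts, prior = 0.5) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("raw counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- log2(sweep(counts + prior, 2L, lib + 2 * prior, "/") * 1e6)
  attr(out, "normalized") <- TRUE
  out
}

#' Row-wise Z-score scaling
#'
#' Scales each gene to mean 0 and unit standard deviation (sample sd, n - 1
#' denominator) across samples, the usual display scaling for expression
#' heatmaps. Constant rows, where the sd is 0, are mapped to all zeros
#' rather than NaN.
#'
#' @param mat Numeric matrix (normalized expression), genes x samples.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  sdev <- apply(mat, 1L, sd)
  out <- (mat - mu) / ifelse(sdev > 0, sdev, 1)
  out[sdev == 0, ] <- 0
  out
}

#' Classify genes as expressed
#'
#' A gene is expressed when its normalized value exceeds `threshold` in at
#' least one sample (strictly: a maximum exactly at the threshold does not
#' qualify).
#'
#' @param mat Normalized (logCPM) matrix, genes x samples.
#' @param threshold logCPM cutoff (default 0).
#' @return Named logical vector per gene.
#' @export
classify_expressed <- function(mat, threshold = 0) {
  mat <- as.matrix(mat)
  setNames(apply(mat, 1L, function(x) any(x > threshold)), rownames(mat))
}

#' Classify transcriptionally repressed genes over a time course
#'
#' A gene is called repressed when its mean expression over replicates
#' strictly decreases between every pair of consecutive time points of the
#' course (a continual decrease; any tie or uptick disqualifies) and the
#' gene is expressed in at least one sample. Means are computed within one
#' tissue.
#'
#' @param mat Normalized (logCPM) matrix, genes x samples; column names must
#'   match `sheet$sample_id`.
#' @param sheet Sample sheet (see [read_sample_sheet()]).
#' @param tissue Tissue to analyse; may be omitted when the sheet contains a
#'   single tissue.
#' @param threshold Expression cutoff passed to [classify_expressed()].
#' @return A `data.frame` with `gene_id`, `is_expressed`, `is_repressed` and
#'   one `mean_<timepoint>` column per time point in rank order.
#' @export
classify_repressed <- function(mat, sheet, tissue = NULL, threshold = 0) {
  mat <- as.matrix(mat)
  sheet <- validate_sample_sheet(sheet)
  if (is.null(tissue)) {
    tis <- unique(sheet$tissue)
    if (length(tis) != 1L)
      stop("sheet contains several tissues; pass 'tissue'")
    tissue <- tis
  }
  sub <- sheet[sheet$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0L) stop("tissue '", tissue, "' not in sample sheet")
  miss <- setdiff(sub$sample_id, colnames(mat))
  if (length(miss)) stop("samples missing from matrix: ",
                         paste(miss, collapse = ", "))
  tps <- unique(sub[order(sub$timepoint_rank), "timepoint"])
  if (length(tps) < 2L) stop("need >= 2 ranked timepoints")
  means <- vapply(tps, function(tp) {
    cols <- sub$sample_id[sub$timepoint == tp]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  means <- matrix(means, nrow = nrow(mat), dimnames = list(rownames(mat), tps))
  expressed <- classify_expressed(mat[, sub$sample_id, drop = FALSE], threshold)
  dec <- apply(means, 1L, function(x) all(diff(x) < 0))
  out <- data.frame(gene_id = rownames(mat),
                    is_expressed = unname(expressed),
                    is_repressed = unname(dec & expressed),
                    stringsAsFactors = FALSE)
  colnames(means) <- paste0("mean_", tps)
  cbind(out, as.data.frame(means, row.names = NULL))
}

#' Read a counts matrix from TSV
#' @param path TSV, first column gene ids, remaining columns samples.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  m
}
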