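#' @importFrom methods is
#' @importFrom stats quantile rnbinom rnorm runif setNames sd
#' @importFrom utils read.table write.table packageVersion
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. All stochastic operations in the package go
# through this so that a seed argument fully determines the result without
# clobbering the global stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single non-missing number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic child seed for a named pipeline stage, so stages can be
# regenerated independently from one master seed. Kept below 2^31.
child_seed <- function(seed, stage) {
  offs <- c(annotation = 11L, peaks = 23L, counts = 37L, enhancers = 53L,
            coverage = 71L, geneset = 89L, bootstrap = 101L)
  off <- offs[[stage]]
  as.integer((as.numeric(seed) * 131L + off) %% 2147483647)
}

# Tab-separated writer with optional '# key=value' header comments recording
# parameters. Deterministic formatting (no scientific notation drift).
write_tsv <- function(df, path, params = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(params)) {
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","), "")),
               con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

# Stable string key identifying a peak interval; used to join peak-level
# tables (assignments, enhancer class calls).
peak_key <- function(gr) {
  sprintf("%s:%d-%d", as.character(GenomeInfoDb::seqnames(gr)),
          GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Genomic feature categories
#'
#' The ordered vocabulary used for peak classification. Order encodes the
#' assignment precedence: an anchor base falling in several features gets the
#' first matching category.
#' @return Character vector of category names.
#' @export
feature_categories <- function() {
  c("promoter", "exon", "intron", "downstream", "intergenic")
}
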