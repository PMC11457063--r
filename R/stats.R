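#' Genomic feature distribution of an assignment set
#'
#' Exact tally of peak categories. Categories with zero count are retained
#' with proportion 0 so distributions from different peak sets are always
#' comparable column-for-column.
#'
#' @param assignments Assignment table from [assign_peaks()] (non-empty).
#' @param categories Ordered category vocabulary; defaults to
#'   [feature_categories()].
#' @return A `data.frame` with `category`, `count`, `proportion`; attribute
#'   `n` = total peaks.
#' @export
category_distribution <- function(assignments, categories = feature_categories()) {
  if (nrow(assignments) == 0L) stop("no assignments to tally")
  f <- factor(assignments$category, levels = categories)
  if (anyNA(f))
    stop("assignment categories outside the vocabulary: ",
         paste(unique(assignments$category[is.na(f)]), collapse = ", "))
  counts <- as.integer(table(f))
  out <- data.frame(category = categories, count = counts,
                    proportion = counts / sum(counts), stringsAsFactors = FALSE)
  attr(out, "n") <- sum(counts)
  out
}

# Percentile bootstrap CIs for a vector of multinomial proportions.
# Resampling n units with replacement and recomputing the k category
# proportions is distributionally identical to drawing the k resampled
# counts from Multinomial(n, observed proportions); we draw the counts
# directly, which keeps 1,000 replications at n in the tens of thousands
# instantaneous. Deterministic given `seed`.
boot_proportion_ci <- function(counts, n_reps = 1000L, conf = 0.95, seed = 1729L) {
  if (!is.numeric(n_reps) || n_reps < 1L) stop("'n_reps' must be >= 1")
  if (!is.numeric(conf) || conf <= 0 || conf >= 1)
    stop("'conf' must be in (0, 1)")
  n <- sum(counts)
  if (n < 1L) stop("need at least one observation to bootstrap")
  est <- counts / n
  reps <- with_seed(seed, stats::rmultinom(n_reps, size = n, prob = est) / n)
  alpha <- (1 - conf) / 2
  lo <- apply(reps, 1L, quantile, probs = alpha, names = FALSE)
  hi <- apply(reps, 1L, quantile, probs = 1 - alpha, names = FALSE)
  data.frame(estimate = unname(est), lower = lo, upper = hi,
             n = n, n_reps = as.integer(n_reps), conf = conf, seed = seed)
}

#' Bootstrap confidence intervals for category proportions
#'
#' Non-parametric percentile bootstrap of the genomic-feature distribution.
#' The resampling unit is the peak assignment: each replication redraws n
#' assignments with replacement and recomputes the category proportions; the
#' CI is the percentile interval of the replicate values at
#' `(1 - conf) / 2` and `1 - (1 - conf) / 2`. The point estimate is the
#' observed proportion.
#'
#' @param assignments Assignment table (non-empty).
#' @param n_reps Number of bootstrap replications (default 1000).
#' @param conf Confidence level in (0, 1) (default 0.95).
#' @param seed Integer seed; identical seeds give identical intervals.
#' @param categories Ordered category vocabulary.
#' @return `data.frame` with one row per category: `category`, `estimate`,
#'   `lower`, `upper`, `n`, `n_reps`, `conf`, `seed`.
#' @export
bootstrap_category_ci <- function(assignments, n_reps = 1000L, conf = 0.95,
                                  seed = 1729L,
                                  categories = feature_categories()) {
  dist <- category_distribution(assignments, categories)
  ci <- boot_proportion_ci(setNames(dist$count, dist$category),
                           n_reps = n_reps, conf = conf, seed = seed)
  cbind(data.frame(category = dist$category, stringsAsFactors = FALSE), ci)
}

#' Bootstrap confidence intervals for peaks-per-gene bin proportions
#'
#' As [bootstrap_category_ci()] but the resampling unit is the gene (carrying
#' its peak count): each replication redraws the genes with replacement and
#' recomputes the bin proportions. Genes and peaks are different sampling
#' units, so the two figure panels get their own bootstrap.
#'
#' @param gene_counts Named integer vector, gene id -> peak count (the
#'   `counts` element of [peaks_per_gene()]).
#' @param bin_edges Bin lower edges (see [peaks_per_gene()]).
#' @inheritParams bootstrap_category_ci
#' @return `data.frame` with one row per bin: `bin`, `estimate`, `lower`,
#'   `upper`, `n`, `n_reps`, `conf`, `seed`.
#' @export
bootstrap_bin_ci <- function(gene_counts, bin_edges = 1:5, n_reps = 1000L,
                             conf = 0.95, seed = 1729L) {
  if (length(gene_counts) < 1L) stop("need at least one gene")
  bins <- bin_gene_counts(gene_counts, bin_edges)
  ci <- boot_proportion_ci(setNames(bins$n_genes, bins$bin),
                           n_reps = n_reps, conf = conf, seed = seed)
  cbind(data.frame(bin = bins$bin, stringsAsFactors = FALSE), ci)
}

#' Flag significant differences by confidence-interval non-overlap
#'
#' Two proportions are flagged as significantly different when their
#' bootstrap confidence intervals are disjoint; intervals sharing an
#' endpoint count as overlapping (not significant). This mirrors the
#' asterisks-on-non-overlapping-CIs convention of the bar-plot comparisons;
#' it is conservative relative to a direct test of the difference and no
#' multiple-testing correction is applied.
#'
#' @param ci_a,ci_b Single-row data frames (or lists) with `lower`, `upper`,
#'   `conf`.
#' @return `TRUE` iff the intervals are disjoint.
#' @export
flag_significant <- function(ci_a, ci_b) {
  if (!isTRUE(all.equal(ci_a$conf, ci_b$conf)))
    stop("confidence levels differ between the intervals")
  isTRUE(ci_a$upper < ci_b$lower || ci_b$upper < ci_a$lower)
}

#' Compare two bootstrapped distributions row by row
#'
#' Convenience wrapper joining two CI tables (same `category` or `bin`
#' column) and flagging each row by CI non-overlap.
#'
#' @param ci_set CI table for the focal set (e.g. gene-set peaks).
#' @param ci_background CI table for the background set (e.g. genome-wide).
#' @param by Join column, `"category"` or `"bin"`.
#' @return Merged `data.frame` with `_set`/`_background` suffixed estimate
#'   columns and a logical `significant` column.
#' @export
compare_ci_tables <- function(ci_set, ci_background, by = intersect(
  c("category", "bin"), names(ci_set))[1]) {
  stopifnot(by %in% names(ci_set), by %in% names(ci_background))
  m <- merge(ci_set[, c(by, "estimate", "lower", "upper", "conf")],
             ci_background[, c(by, "estimate", "lower", "upper", "conf")],
             by = by, suffixes = c("_set", "_background"), sort = FALSE)
  m <- m[match(ci_set[[by]], m[[by]]), , drop = FALSE]
  m$significant <- mapply(function(l1, u1, l2, u2, c1, c2)
    flag_significant(list(lower = l1, upper = u1, conf = c1),
                     list(lower = l2, upper = u2, conf = c2)),
    m$lower_set, m$upper_set, m$lower_background, m$upper_background,
    m$conf_set, m$conf_background)
  m$conf_set <- NULL
  names(m)[names(m) == "conf_background"] <- "conf"
  rownames(m) <- NULL
  m
}
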