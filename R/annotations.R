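#' Read gene models from a GFF3 or GTF annotation
#'
#' Parses a gene annotation into gene-level models: one record per gene id
#' with the gene span, strand, and the union of exons across all transcripts
#' of the gene. Transcript isoforms are deliberately collapsed — the analyses
#' in this package (feature assignment, peaks-per-gene) are gene-resolution.
#'
#' @param path Path to a GFF3 or GTF file (1-based inclusive coordinates, as
#'   per the format specifications; conversion is handled by rtracklayer).
#' @param format `"auto"` (by file extension), `"gff3"` or `"gtf"`.
#' @return A named list with elements
#'   \describe{
#'     \item{genes}{`GRanges` of gene spans with a `gene_id` metadata column,
#'       sorted by position, strand `+` or `-`.}
#'     \item{exons}{`GRangesList` of merged (unioned) exons, one element per
#'       gene, named by `gene_id`, parallel to `genes`.}
#'   }
#'   Genes with no exon records get a single exon covering the full span.
#' @details The TSS of a `+` strand gene is its start; of a `-` strand gene
#'   its end. Exons are resolved to genes through `gene_id` attributes when
#'   present (GTF, and GFF3 files that carry them) or through the
#'   `Parent`/`ID` chain (exon -> transcript -> gene) otherwise.
#' @export
read_gene_models <- function(path, format = c("auto", "gff3", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = format),
    error = function(e) stop("failed to parse annotation '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!("type" %in% names(S4Vectors::mcols(gr))))
    stop("annotation has no 'type' column; not a valid GFF/GTF")
  gene_models_from_granges(gr)
}

# Build gene models from an already-imported annotation GRanges.
gene_models_from_granges <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  is_gene <- as.character(mc$type) == "gene"
  genes <- gr[is_gene]
  gid <- annotation_gene_id(genes)
  if (anyNA(gid) || any(gid == ""))
    stop("gene record(s) without a gene id")
  if (anyDuplicated(gid)) {
    # several records per gene id: take the enclosing span
    sp <- split(genes, gid)
    genes <- unlist(range(sp, ignore.strand = FALSE))
    gid <- names(genes)
  }
  S4Vectors::mcols(genes) <- NULL
  genes$gene_id <- unname(gid)
  names(genes) <- NULL
  bad <- !(as.character(GenomicRanges::strand(genes)) %in% c("+", "-"))
  if (any(bad))
    stop("gene(s) without explicit strand: ",
         paste(genes$gene_id[bad], collapse = ", "))
  o <- order(as.character(GenomeInfoDb::seqnames(genes)),
             GenomicRanges::start(genes), genes$gene_id)
  genes <- genes[o]

  exon_rec <- gr[as.character(mc$type) == "exon"]
  exon_gene <- exon_gene_ids(gr, exon_rec)
  keep <- !is.na(exon_gene) & exon_gene %in% genes$gene_id
  exon_rec <- exon_rec[keep]
  exon_gene <- exon_gene[keep]
  S4Vectors::mcols(exon_rec) <- NULL
  ex <- GenomicRanges::reduce(GenomicRanges::split(
    exon_rec, factor(exon_gene, levels = genes$gene_id)))
  # genes without exon records: single exon over the whole span
  empty <- S4Vectors::elementNROWS(ex) == 0L
  if (any(empty)) {
    fill <- GenomicRanges::granges(genes[match(names(ex)[empty], genes$gene_id)])
    ex[empty] <- GenomicRanges::split(fill, seq_along(fill))
  }
  list(genes = genes, exons = ex)
}

annotation_gene_id <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  if (!is.null(mc$gene_id)) as.character(mc$gene_id)
  else if (!is.null(mc$ID)) as.character(mc$ID)
  else if (!is.null(mc$Name)) as.character(mc$Name)
  else rep(NA_character_, length(gr))
}

# Resolve each exon record to a gene id: gene_id attribute if present, else
# follow Parent (exon -> transcript -> gene) through the ID attributes.
exon_gene_ids <- function(gr, exon_rec) {
  mc <- S4Vectors::mcols(exon_rec)
  if (!is.null(mc$gene_id) && !all(is.na(mc$gene_id)))
    return(as.character(mc$gene_id))
  if (is.null(mc$Parent))
    return(rep(NA_character_, length(exon_rec)))
  parent <- vapply(as.list(mc$Parent),
                   function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                   NA_character_)
  allmc <- S4Vectors::mcols(gr)
  ids <- if (!is.null(allmc$ID)) as.character(allmc$ID) else rep(NA_character_, length(gr))
  types <- as.character(allmc$type)
  # map transcript ID -> gene id (the transcript's Parent, or itself if the
  # Parent is already a gene)
  tx <- which(!is.na(ids))
  tx_parent <- rep(NA_character_, length(gr))
  if (!is.null(allmc$Parent)) {
    tx_parent <- vapply(as.list(allmc$Parent),
                        function(p) if (length(p)) as.character(p[[1]]) else NA_character_,
                        NA_character_)
  }
  gene_ids <- ids
  gene_ids[types != "gene"] <- NA_character_
  resolve <- function(id) {
    i <- match(id, ids)
    if (is.na(i)) return(NA_character_)
    if (types[i] == "gene") return(ids[i])
    resolve(tx_parent[i])
  }
  vapply(parent, resolve, NA_character_)
}

#' Transcription start sites of gene models
#'
#' @param genes `GRanges` of gene spans with strand `+` or `-`.
#' @return `GRanges` of width-1 TSS positions (gene start on `+`, gene end on
#'   `-`), carrying over metadata columns.
#' @export
gene_tss <- function(genes) {
  GenomicRanges::resize(genes, width = 1L, fix = "start")
}

#' Build the genomic feature index used for peak assignment
#'
#' Derives per-gene promoter, exon, intron and downstream regions from gene
#' models. Intron regions are the gene span minus the merged exons. The
#' promoter covers `promoter_up` bp upstream through `promoter_down` bp
#' downstream of the TSS, in transcription orientation; the downstream region
#' covers `downstream_len` bp past the transcription end site.
#'
#' @param models Gene models from [read_gene_models()].
#' @param promoter_up,promoter_down,downstream_len Window sizes in bp
#'   (non-negative).
#' @return An object of class `FeatureIndex`: a list with `GRanges` elements
#'   `promoter`, `exon`, `intron`, `downstream` (each with a `gene_id`
#'   column), the `tss` positions, the `genes`, and the window parameters.
#' @export
build_feature_index <- function(models, promoter_up = 1000L,
                                promoter_down = 100L, downstream_len = 1000L) {
  stopifnot(is.list(models), !is.null(models$genes), !is.null(models$exons))
  if (promoter_up < 0 || promoter_down < 0 || downstream_len < 0)
    stop("window parameters must be >= 0")
  genes <- models$genes
  exons <- models$exons[match(genes$gene_id, names(models$exons))]

  prom <- GenomicRanges::promoters(genes, upstream = as.integer(promoter_up),
                                   downstream = as.integer(promoter_down))
  prom <- GenomicRanges::trim(restrict_start(prom))
  down <- GenomicRanges::flank(genes, width = as.integer(downstream_len),
                               start = FALSE)
  down <- restrict_start(down)

  ex_flat <- unlist(exons, use.names = TRUE)
  ex_gr <- GenomicRanges::granges(ex_flat)
  ex_gr$gene_id <- names(ex_flat)
  names(ex_gr) <- NULL

  # intron = gene span minus merged exons, strand-agnostic per-gene setdiff
  g0 <- GenomicRanges::granges(genes)
  GenomicRanges::strand(g0) <- "*"
  ex_us <- GenomicRanges::granges(ex_flat)
  GenomicRanges::strand(ex_us) <- "*"
  names(ex_us) <- NULL
  ex_by_gene <- GenomicRanges::reduce(GenomicRanges::split(
    ex_us, factor(names(ex_flat), levels = genes$gene_id)))
  intr <- GenomicRanges::psetdiff(g0, ex_by_gene)
  intr_flat <- unlist(intr, use.names = FALSE)
  intr_gene <- rep(genes$gene_id, S4Vectors::elementNROWS(intr))
  intr_gr <- GenomicRanges::granges(intr_flat)
  intr_gr$gene_id <- intr_gene

  tag <- function(gr) { gr2 <- GenomicRanges::granges(gr); gr2$gene_id <- gr$gene_id; gr2 }
  prom$gene_id <- genes$gene_id
  down$gene_id <- genes$gene_id
  idx <- list(promoter = tag(prom), exon = ex_gr, intron = intr_gr,
              downstream = tag(down), tss = gene_tss(genes), genes = genes,
              params = list(promoter_up = promoter_up,
                            promoter_down = promoter_down,
                            downstream_len = downstream_len))
  class(idx) <- "FeatureIndex"
  idx
}

# Clip ranges that would extend below position 1 (no seqlengths needed).
restrict_start <- function(gr) {
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  st <- pmax(st, 1L)
  keep <- en >= st
  GenomicRanges::ranges(gr) <- IRanges::IRanges(st, pmax(en, st))
  gr[keep]
}

#' @export
print.FeatureIndex <- function(x, ...) {
  cat("FeatureIndex:", length(x$genes), "genes;",
      "windows up/down/downstream =", x$params$promoter_up, "/",
      x$params$promoter_down, "/", x$params$downstream_len, "bp\n")
  invisible(x)
}

#' Export gene models to GFF3
#'
#' Canonical gene-level export: one `gene` record and one `exon` record per
#' merged exon, each exon carrying its `gene_id`. Round-trips through
#' [read_gene_models()].
#'
#' @param models Gene models.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  genes <- models$genes
  exons <- models$exons[match(genes$gene_id, names(models$exons))]
  g <- GenomicRanges::granges(genes)
  g$type <- "gene"
  g$ID <- genes$gene_id
  g$gene_id <- genes$gene_id
  ex <- unlist(exons, use.names = TRUE)
  e <- GenomicRanges::granges(ex)
  GenomicRanges::strand(e) <- GenomicRanges::strand(genes)[match(names(ex), genes$gene_id)]
  e$type <- "exon"
  e$ID <- NA_character_
  e$gene_id <- names(ex)
  names(e) <- NULL
  out <- c(g, e)
  out <- out[order(as.character(GenomeInfoDb::seqnames(out)),
                   GenomicRanges::start(out),
                   match(out$type, c("gene", "exon")))]
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}
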