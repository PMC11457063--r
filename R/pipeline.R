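#' Read a pipeline run configuration
#'
#' @param path YAML config file (see [validate_config()] for the schema; the
#'   generator's [simulate_dataset()] writes a ready-to-run example).
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse config '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  cfg
}

default_run_params <- function() {
  list(promoter_up = 1000L, promoter_down = 100L, downstream_len = 1000L,
       n_reps = 1000L, conf = 0.95, seed = 1729L, expression_threshold = 0,
       bin_edges = 1:5, flank = 1000L, bin_size = 10L, assign_by = "anchor")
}

#' Validate a run configuration
#'
#' Checks the configuration without running anything: required keys present,
#' referenced files exist, every condition has at least one replicate, and —
#' when expression is configured — every time point of the peak map appears
#' in the sample sheet.
#'
#' @param config Configuration list (see [read_run_config()]).
#' @return Character vector of problems; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  need_file <- function(key, path) {
    if (is.null(path)) problems <<- c(problems, paste0("missing key: ", key))
    else if (!file.exists(path))
      problems <<- c(problems, paste0(key, ": file not found: ", path))
  }
  need_file("annotation", config$annotation)
  need_file("gene_set", config$gene_set)
  if (!is.null(config$blacklist)) need_file("blacklist", config$blacklist)
  if (!is.null(config$repeats)) need_file("repeats", config$repeats)
  if (is.null(config$peaks) || !length(config$peaks)) {
    problems <- c(problems, "missing key: peaks")
  } else {
    for (tissue in names(config$peaks)) {
      for (tp in names(config$peaks[[tissue]])) {
        files <- config$peaks[[tissue]][[tp]]
        if (length(files) < 1L)
          problems <- c(problems,
                        sprintf("peaks.%s.%s: no replicate files", tissue, tp))
        for (f in files) need_file(sprintf("peaks.%s.%s", tissue, tp), f)
        if (!is.null(config$timepoint_ranks) &&
            is.null(config$timepoint_ranks[[tp]]))
          problems <- c(problems,
                        sprintf("timepoint_ranks: no rank for '%s'", tp))
      }
    }
  }
  if (!is.null(config$enhancers)) {
    need_file("enhancers.hk", config$enhancers$hk)
    need_file("enhancers.dev", config$enhancers$dev)
  }
  if (!is.null(config$counts) || !is.null(config$samples)) {
    need_file("counts", config$counts)
    need_file("samples", config$samples)
    if (!is.null(config$samples) && file.exists(config$samples) &&
        !is.null(config$peaks)) {
      sheet <- tryCatch(read_sample_sheet(config$samples),
                        error = function(e) {
                          problems <<- c(problems, paste0("samples: ",
                                                          conditionMessage(e)))
                          NULL
                        })
      if (!is.null(sheet)) {
        tps <- unique(unlist(lapply(config$peaks, names)))
        miss <- setdiff(tps, unique(sheet$timepoint))
        if (length(miss))
          problems <- c(problems,
                        paste0("samples: peak-map timepoint(s) absent from ",
                               "sample sheet: ", paste(miss, collapse = ", ")))
      }
    }
  }
  if (!is.null(config$coverage)) {
    for (key in names(config$coverage))
      need_file(paste0("coverage.", key), config$coverage[[key]])
  }
  problems
}

#' Run the full regulatory-architecture analysis
#'
#' Orchestrates every stage from one configuration: per-condition replicate
#' consensus and blacklist/repeat exclusion, per-tissue peak pooling,
#' feature assignment, gene-set subsetting, category and peaks-per-gene
#' distributions with bootstrap CIs and CI-non-overlap significance flags,
#' the cross-tissue union peak set, enhancer-class overlap and per-class
#' distributions, expression normalization and repressed-gene calls, and
#' accessibility metaprofiles. Stages without configured inputs (enhancers,
#' counts, coverage) are skipped with a report note. Identical config and
#' seed give byte-identical outputs.
#'
#' @param config Configuration list or path to a YAML config.
#' @param outdir Output directory for the TSV tables and `report.json`.
#' @return The run report (list), invisibly; also written as JSON.
#' @export
run_all <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("configuration invalid:\n  - ", paste(problems, collapse = "\n  - "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  par <- utils::modifyList(default_run_params(), config$params %||% list())
  par$bin_edges <- as.integer(unlist(par$bin_edges))
  seed <- as.integer(par$seed)
  report <- list(package = "peakarch",
                 version = as.character(packageVersion("peakarch")),
                 seed = seed, params = par, stages = list(), tables = list(),
                 notes = character(0))
  echo <- par[c("promoter_up", "promoter_down", "downstream_len", "n_reps",
                "conf", "seed")]
  add_table <- function(name, df, params = echo) {
    path <- file.path(outdir, paste0(name, ".tsv"))
    write_tsv(df, path, params = params)
    # paths recorded relative to the output directory so identical runs
    # into different directories stay byte-identical
    report$tables[[name]] <<- list(path = paste0(name, ".tsv"), rows = nrow(df))
  }

  models <- read_gene_models(config$annotation)
  index <- build_feature_index(models, par$promoter_up, par$promoter_down,
                               par$downstream_len)
  gene_set <- readLines(config$gene_set)
  gene_set <- gene_set[nzchar(gene_set)]
  excl <- GenomicRanges::GRanges()
  if (!is.null(config$blacklist)) excl <- c(excl, read_bed(config$blacklist))
  if (!is.null(config$repeats)) excl <- c(excl, read_bed(config$repeats))
  report$stages$annotation <- list(n_genes = length(models$genes),
                                   n_gene_set = length(gene_set),
                                   n_exclusion_regions = length(excl))

  # consensus + exclusion per condition, then pool per tissue
  cons_rows <- list()
  tissue_peaks <- list()
  for (tissue in names(config$peaks)) {
    per_tp <- list()
    for (tp in names(config$peaks[[tissue]])) {
      reps <- lapply(config$peaks[[tissue]][[tp]], read_narrowpeak,
                     tissue = tissue, timepoint = tp)
      cons <- exclude_regions(consensus_peaks(reps), excl)
      per_tp[[tp]] <- cons
      cons_rows[[paste(tissue, tp)]] <- data.frame(
        tissue = tissue, timepoint = tp,
        chrom = as.character(GenomeInfoDb::seqnames(cons)),
        start = GenomicRanges::start(cons), end = GenomicRanges::end(cons),
        stringsAsFactors = FALSE)
    }
    tissue_peaks[[tissue]] <- GenomicRanges::sort(GenomicRanges::reduce(
      do.call(c, unname(per_tp)), ignore.strand = TRUE))
  }
  add_table("consensus_peaks", do.call(rbind, c(cons_rows, make.row.names = FALSE)))
  report$stages$consensus <- lapply(tissue_peaks, length)

  # assignment per tissue
  assignments <- list()
  for (tissue in names(tissue_peaks)) {
    a <- assign_peaks(tissue_peaks[[tissue]], index, assign_by = par$assign_by)
    a <- cbind(tissue = tissue, a, stringsAsFactors = FALSE)
    assignments[[tissue]] <- a
  }
  all_asn <- do.call(rbind, c(assignments, make.row.names = FALSE))
  add_table("assignments", all_asn)
  gs_asn <- lapply(assignments, subset_by_gene_set, gene_set = gene_set,
                   known_genes = models$genes$gene_id)
  add_table("geneset_assignments",
            do.call(rbind, c(gs_asn, make.row.names = FALSE)))

  # distributions + bootstrap CIs + significance, per tissue
  dist_rows <- list(); cat_ci_rows <- list()
  ppg_rows <- list(); bin_ci_rows <- list()
  bseed <- child_seed(seed, "bootstrap")
  i <- 0L
  for (tissue in names(assignments)) {
    for (set in c("all", "gene_set")) {
      asn <- if (set == "all") assignments[[tissue]] else gs_asn[[tissue]]
      if (nrow(asn) == 0L) {
        report$notes <- c(report$notes, sprintf(
          "tissue %s: empty %s assignment set; distribution skipped",
          tissue, set))
        next
      }
      i <- i + 1L
      d <- category_distribution(asn)
      dist_rows[[paste(tissue, set)]] <-
        cbind(tissue = tissue, set = set, d, n = attr(d, "n"))
      ci <- bootstrap_category_ci(asn, n_reps = par$n_reps, conf = par$conf,
                                  seed = bseed + i)
      cat_ci_rows[[paste(tissue, set)]] <- cbind(tissue = tissue, set = set, ci)
      ppg <- peaks_per_gene(asn, bin_edges = par$bin_edges)
      ppg_rows[[paste(tissue, set)]] <-
        cbind(tissue = tissue, set = set, ppg$bins,
              n_genes_total = length(ppg$counts))
      bci <- bootstrap_bin_ci(ppg$counts, bin_edges = par$bin_edges,
                              n_reps = par$n_reps, conf = par$conf,
                              seed = bseed + 500L + i)
      bin_ci_rows[[paste(tissue, set)]] <- cbind(tissue = tissue, set = set, bci)
    }
  }
  add_table("category_distribution",
            do.call(rbind, c(dist_rows, make.row.names = FALSE)))
  add_table("peaks_per_gene",
            do.call(rbind, c(ppg_rows, make.row.names = FALSE)))
  cat_ci <- do.call(rbind, c(cat_ci_rows, make.row.names = FALSE))
  bin_ci <- do.call(rbind, c(bin_ci_rows, make.row.names = FALSE))
  flag_tables <- function(ci, by) {
    out <- list()
    for (tissue in unique(ci$tissue)) {
      a <- ci[ci$tissue == tissue & ci$set == "gene_set", , drop = FALSE]
      b <- ci[ci$tissue == tissue & ci$set == "all", , drop = FALSE]
      if (!nrow(a) || !nrow(b)) next
      cmp <- compare_ci_tables(a, b, by = by)
      out[[tissue]] <- cbind(tissue = tissue, cmp)
    }
    do.call(rbind, c(out, make.row.names = FALSE))
  }
  add_table("category_ci", cat_ci)
  add_table("category_significance", flag_tables(cat_ci, "category"))
  add_table("bin_ci", bin_ci)
  add_table("bin_significance", flag_tables(bin_ci, "bin"))

  # union peak set across tissues for the gene set
  union_pk <- union_gene_set_peaks(assignments, gene_set,
                                   known_genes = models$genes$gene_id)
  add_table("union_peaks", data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(union_pk)),
    start = GenomicRanges::start(union_pk),
    end = GenomicRanges::end(union_pk), stringsAsFactors = FALSE))
  report$stages$union <- list(n_peaks = length(union_pk))

  # enhancer-class overlap on the union set
  if (!is.null(config$enhancers)) {
    hk <- read_bed(config$enhancers$hk)
    dev <- read_bed(config$enhancers$dev)
    calls <- classify_enhancer_overlap(union_pk, hk, dev)
    add_table("enhancer_classes", calls)
    fr <- attr(calls, "fractions")
    report$stages$enhancer_overlap <- as.list(fr)
    union_asn <- assign_peaks(union_pk, index, assign_by = par$assign_by)
    pcd <- per_class_distribution(calls, union_asn)
    pcd_rows <- lapply(names(pcd), function(cl)
      cbind(class = cl, pcd[[cl]], n = attr(pcd[[cl]], "n")))
    add_table("enhancer_class_distribution",
              do.call(rbind, c(pcd_rows, make.row.names = FALSE)))
  } else {
    report$notes <- c(report$notes, "enhancers not configured; overlap stage skipped")
  }

  # expression normalization + repression calls
  if (!is.null(config$counts)) {
    counts <- read_counts(config$counts)
    sheet <- read_sample_sheet(config$samples)
    lcpm <- log_cpm(counts)
    add_table("expression_logcpm",
              data.frame(gene_id = rownames(lcpm), round(lcpm, 4),
                         check.names = FALSE))
    calls_rows <- list()
    for (tissue in unique(sheet$tissue)) {
      sub <- sheet[sheet$tissue == tissue, , drop = FALSE]
      if (length(unique(sub$timepoint)) < 2L) {
        report$notes <- c(report$notes, sprintf(
          "tissue %s: <2 timepoints; repression call skipped", tissue))
        next
      }
      gc <- classify_repressed(lcpm[, sub$sample_id, drop = FALSE], sub,
                               tissue = tissue,
                               threshold = par$expression_threshold)
      calls_rows[[tissue]] <- cbind(tissue = tissue,
                                    gc[, c("gene_id", "is_expressed",
                                           "is_repressed")])
    }
    add_table("gene_calls", do.call(rbind, c(calls_rows, make.row.names = FALSE)))
  } else {
    report$notes <- c(report$notes, "counts not configured; expression stage skipped")
  }

  # accessibility metaprofiles at union gene-set peak centers
  if (!is.null(config$coverage) && length(union_pk)) {
    anchors <- anchors_from(union_pk, kind = "peak_center")
    prof_rows <- list()
    for (key in names(config$coverage)) {
      prof <- metaprofile(config$coverage[[key]], anchors,
                          flank = par$flank, bin_size = par$bin_size,
                          label = key)
      prof_rows[[key]] <- prof
    }
    add_table("metaprofiles", do.call(rbind, c(prof_rows, make.row.names = FALSE)))
  } else if (is.null(config$coverage)) {
    report$notes <- c(report$notes, "coverage not configured; profile stage skipped")
  }

  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
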