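#' Run the typing pipeline for a set of samples
#'
#' FASTQ to call, end to end: read, length/quality filter, local alignment
#' to both exon references, pileup, diagnostic-position quantification,
#' rule-table classification.
#'
#' @param mapping data.frame with columns `sample_id` and one or more FASTQ
#'   path columns (`exon6_fastq`, `exon7_fastq`, or a single `fastq`); all
#'   FASTQs of a sample are pooled before alignment. See
#'   [read_sample_mapping()] / [discover_samples()].
#' @param references An `abo_references` object.
#' @param mode,het_threshold,min_depth Classifier settings, see
#'   [classify_profile()].
#' @param min_length,min_mean_q Read filter, see [filter_reads()].
#' @param min_identity,min_ref_cover Alignment filters, see
#'   [align_reads()].
#' @return A list of class `abo_run`: `calls` (list of `abo_call`),
#'   `profiles` (list of `abo_profile`), `pileups` (per sample, per exon).
#' @export
type_samples <- function(mapping, references, mode = "5snv",
                         het_threshold = 0.20, min_depth = 20L,
                         min_length = 50L, min_mean_q = 7,
                         min_identity = 0.7, min_ref_cover = 0.9) {
  stopifnot(is.data.frame(mapping), "sample_id" %in% names(mapping))
  path_cols <- setdiff(names(mapping), "sample_id")
  mapping <- mapping[order(mapping$sample_id), , drop = FALSE]
  calls <- list(); profiles <- list(); pileups <- list()
  for (i in seq_len(nrow(mapping))) {
    sid <- mapping$sample_id[i]
    paths <- unlist(mapping[i, path_cols])
    paths <- paths[!is.na(paths) & nzchar(paths)]
    reads <- do.call(rbind, lapply(paths, read_fastq))
    reads <- suppressMessages(
      filter_reads(reads, min_length = min_length, min_mean_q = min_mean_q))
    aln <- align_reads(reads, references, min_identity = min_identity,
                       min_ref_cover = min_ref_cover)
    pu <- list(
      exon6 = build_pileup(aln[aln$reference == "exon6", , drop = FALSE],
                           references$exon6),
      exon7 = build_pileup(aln[aln$reference == "exon7", , drop = FALSE],
                           references$exon7))
    total <- c(exon6 = sum(aln$reference == "exon6"),
               exon7 = sum(aln$reference == "exon7"))
    prof <- variant_profile(pu, sample_id = sid, total_reads = total)
    calls[[sid]] <- classify_profile(prof, mode = mode,
                                     het_threshold = het_threshold,
                                     min_depth = min_depth)
    profiles[[sid]] <- prof
    pileups[[sid]] <- pu
  }
  structure(list(calls = calls, profiles = profiles, pileups = pileups),
            class = "abo_run")
}

#' Read a sample-to-FASTQ mapping file
#'
#' CSV with a `sample_id` column and FASTQ path columns; relative paths are
#' resolved against the mapping file's directory.
#'
#' @param path Mapping CSV path.
#' @return data.frame suitable for [type_samples()].
#' @export
read_sample_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(m))
    stop("mapping file needs a sample_id column", call. = FALSE)
  base <- dirname(normalizePath(path))
  for (col in setdiff(names(m), "sample_id")) {
    rel <- !is.na(m[[col]]) & nzchar(m[[col]]) &
      !grepl("^(/|[A-Za-z]:)", m[[col]])
    m[[col]][rel] <- file.path(base, m[[col]][rel])
  }
  m
}

#' Discover samples in a directory by naming convention
#'
#' Collects files named `<sample_id>.exon6.fastq[.gz]` /
#' `<sample_id>.exon7.fastq[.gz]`.
#'
#' @param dir Directory to scan.
#' @return Mapping data.frame for [type_samples()].
#' @export
discover_samples <- function(dir) {
  if (!dir.exists(dir)) stop("input directory not found: ", dir, call. = FALSE)
  f <- list.files(dir, pattern = "\\.exon[67]\\.fastq(\\.gz)?$")
  if (!length(f)) stop("no *.exon6/7.fastq files in ", dir, call. = FALSE)
  sid <- sub("\\.exon[67]\\.fastq(\\.gz)?$", "", f)
  exon <- sub("^.*\\.(exon[67])\\.fastq(\\.gz)?$", "\\1", f)
  m <- data.frame(sample_id = unique(sid), exon6_fastq = NA_character_,
                  exon7_fastq = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(f)) {
    r <- match(sid[i], m$sample_id)
    m[[paste0(exon[i], "_fastq")]][r] <- file.path(dir, f[i])
  }
  m
}

#' Per-sample summary blocks
#'
#' Two text blocks per sample: a polymorphism block (the five diagnostic
#' positions with symbol fractions and depth) and a phenotype block
#' (status, phenotype, genotype, extended genotype, reliability tier).
#' Field order is stable.
#'
#' @param call An `abo_call`.
#' @param profile The matching `abo_profile`.
#' @return Character vector of lines.
#' @export
summarize_sample <- function(call, profile) {
  df <- as.data.frame(profile)
  poly <- c("## ABO read polymorphisms",
            paste0("sample: ", call$sample_id),
            "position\trsid\tfractions\tdepth")
  for (i in seq_len(nrow(df))) {
    fr <- unlist(df[i, .ABO_SYMBOLS])
    fr <- fr[!is.na(fr) & fr > 0]
    fr_str <- if (length(fr))
      paste(sprintf("%s=%.3f", names(fr), fr), collapse = ",") else "-"
    poly <- c(poly, paste(paste0("c.", df$cdna[i]), df$rsid[i], fr_str,
                          df$depth[i], sep = "\t"))
  }
  pheno <- c("## ABO phenotype",
             paste0("sample: ", call$sample_id),
             paste0("status: ", call$status),
             paste0("mode: ", call$mode))
  if (call$status == "ok") {
    pheno <- c(pheno,
               paste0("phenotype: ", call$phenotype),
               paste0("genotype: ", call$genotype),
               paste0("extended_genotype: ", call$extended_genotype))
  }
  pheno <- c(pheno, paste0("reads: ", call$reads),
             paste0("tier: ", call$tier))
  c(poly, "", pheno)
}

#' Write per-sample summary files
#'
#' @param call An `abo_call`.
#' @param profile The matching `abo_profile`.
#' @param dir Output directory for
#'   `<sample>.ABOReadPolymorphisms.txt` and `<sample>.ABOPhenotype.txt`.
#' @return Invisibly, the two paths.
#' @export
write_sample_summary <- function(call, profile, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lines <- summarize_sample(call, profile)
  brk <- which(lines == "")[1]
  p1 <- file.path(dir, paste0(call$sample_id, ".ABOReadPolymorphisms.txt"))
  p2 <- file.path(dir, paste0(call$sample_id, ".ABOPhenotype.txt"))
  writeLines(lines[seq_len(brk - 1L)], p1)
  writeLines(lines[(brk + 1L):length(lines)], p2)
  invisible(c(p1, p2))
}

.calls_table <- function(calls) {
  rows <- lapply(calls, function(cl) data.frame(
    sample_id = cl$sample_id, status = cl$status,
    phenotype = ifelse(is.na(cl$phenotype), "", cl$phenotype),
    genotype = ifelse(is.na(cl$genotype), "", cl$genotype),
    extended_genotype = ifelse(is.na(cl$extended_genotype), "",
                               cl$extended_genotype),
    reads = cl$reads, tier = cl$tier, mode = cl$mode,
    stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate calls into run-level report files
#'
#' The full results table lists every sample with its status; the export
#' table (`final_export.csv`) contains only samples whose call passed the
#' depth gate and matched a rule — flagged samples are excluded and left
#' for repeat testing. A run log and a versions file are written alongside.
#'
#' @param calls List of `abo_call` objects (at least one).
#' @param out_dir Output directory; created if missing.
#' @param run_id Run identifier echoed into the files.
#' @param config Optional named list echoed into the run log.
#' @param timestamps Set `FALSE` to omit timestamps (byte-stable outputs
#'   for regression comparison).
#' @return Object of class `abo_run_report`: list with `results`, `export`,
#'   `counts`, `paths`.
#' @export
aggregate_run <- function(calls, out_dir = NULL, run_id = "run1",
                          config = NULL, timestamps = TRUE) {
  stopifnot(length(calls) >= 1L)
  results <- .calls_table(calls)
  export <- results[results$status == "ok",
                    c("sample_id", "phenotype", "genotype",
                      "extended_genotype", "reads", "tier"), drop = FALSE]
  counts <- c(ok = sum(results$status == "ok"),
              low_coverage = sum(results$status == "low_coverage"),
              unknown = sum(results$status == "unknown"))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("ABO_result.csv", "final_export.csv",
                                  "ABO_result.log", "versions.yml"))
    write.csv(results, paths[1], row.names = FALSE, quote = FALSE)
    write.csv(export, paths[2], row.names = FALSE, quote = FALSE)
    log <- c(paste0("run_id: ", run_id),
             paste0("tool: abolong ", as.character(packageVersion("abolong"))),
             if (timestamps) paste0("time: ", format(Sys.time())),
             paste0("samples: ", nrow(results)),
             paste0("ok: ", counts[["ok"]]),
             paste0("low_coverage: ", counts[["low_coverage"]]),
             paste0("unknown: ", counts[["unknown"]]))
    if (!is.null(config))
      log <- c(log, paste0("config.", names(config), ": ",
                           vapply(config, function(x)
                             paste(format(x), collapse = ","), character(1))))
    writeLines(log, paths[3])
    yaml::write_yaml(list(
      abolong = as.character(packageVersion("abolong")),
      R = paste(R.version$major, R.version$minor, sep = "."),
      Biostrings = as.character(packageVersion("Biostrings"))), paths[4])
  }
  structure(list(results = results, export = export, counts = counts,
                 run_id = run_id, paths = paths),
            class = "abo_run_report")
}

#' @export
print.abo_run_report <- function(x, ...) {
  cat("ABO run report", x$run_id, "-", nrow(x$results), "samples (",
      x$counts[["ok"]], "ok,", x$counts[["low_coverage"]], "low coverage,",
      x$counts[["unknown"]], "unknown)\n")
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' Concordance of calls against known phenotypes
#'
#' One-vs-rest performance per phenotype over the samples that produced a
#' passing call; samples flagged `low_coverage`/`unknown`, or missing from
#' the truth table, are excluded and counted.
#'
#' @param calls List of `abo_call` objects.
#' @param truth data.frame with columns `sample_id` and `phenotype`.
#' @return Object of class `abo_concordance`: list with `accuracy`,
#'   `confusion` (truth rows x called columns over A/B/AB/O), `per_class`
#'   (sensitivity, specificity, precision), `n_evaluated`, `n_excluded`.
#' @export
concordance_report <- function(calls, truth) {
  stopifnot(is.data.frame(truth),
            all(c("sample_id", "phenotype") %in% names(truth)))
  tab <- .calls_table(calls)
  eval_tab <- tab[tab$status == "ok", , drop = FALSE]
  n_excluded <- nrow(tab) - nrow(eval_tab)
  idx <- match(eval_tab$sample_id, truth$sample_id)
  if (anyNA(idx)) {
    warning("truth table missing sample(s): ",
            paste(eval_tab$sample_id[is.na(idx)], collapse = ", "),
            "; excluded from concordance", call. = FALSE)
    n_excluded <- n_excluded + sum(is.na(idx))
    eval_tab <- eval_tab[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  classes <- c("A", "B", "AB", "O")
  if (nrow(eval_tab) == 0L) {
    conf <- matrix(0L, 4, 4, dimnames = list(truth = classes,
                                             called = classes))
    per <- data.frame(phenotype = classes, sensitivity = NA_real_,
                      specificity = NA_real_, precision = NA_real_)
    return(structure(list(accuracy = NA_real_, confusion = conf,
                          per_class = per, n_evaluated = 0L,
                          n_excluded = n_excluded),
                     class = "abo_concordance"))
  }
  truth_ph <- factor(truth$phenotype[idx], levels = classes)
  called_ph <- factor(eval_tab$phenotype, levels = classes)
  conf <- table(truth = truth_ph, called = called_ph)
  acc <- sum(diag(conf)) / sum(conf)
  per <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- sum(conf) - tp - fn - fp
    data.frame(phenotype = cl,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = acc, confusion = conf, per_class = per,
                 n_evaluated = nrow(eval_tab), n_excluded = n_excluded),
            class = "abo_concordance")
}

#' @export
print.abo_concordance <- function(x, ...) {
  cat("ABO concordance:", x$n_evaluated, "evaluated,", x$n_excluded,
      "excluded\n")
  cat("overall accuracy:",
      if (is.na(x$accuracy)) "NA" else sprintf("%.4f", x$accuracy), "\n")
  print(x$confusion)
  print(x$per_class, row.names = FALSE)
  invisible(x)
}
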