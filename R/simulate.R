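#' Simulation configuration
#'
#' Parameters for the nanopore-like amplicon read simulator. Reads from the
#' two alleles are assigned deterministically: `round(n_reads *
#' allele_ratio)` reads come from the first allele, the rest from the
#' second, so expected allele fractions are exact rather than binomially
#' sampled. Errors are applied i.i.d. per base: a deletion drops the base,
#' an insertion duplicates it (a homopolymer-biased indel model), a
#' substitution replaces it with one of the three alternatives drawn
#' uniformly.
#'
#' @param genotype Character vector of two allele labels.
#' @param n_reads Reads per exon (non-negative integer).
#' @param allele_ratio Fraction of reads drawn from `genotype[1]`, in
#'   `[0, 1]`.
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities, each in
#'   `[0, 0.3]`.
#' @param min_span,max_span Fraction of the exon covered per read, in
#'   `(0, 1]`; read spans are drawn uniformly between the two. The default
#'   1.0 models full-length amplicon reads.
#' @param seed Integer seed.
#' @return An object of class `abo_sim_config`.
#' @examples
#' simulation_config(c("A", "O1"), n_reads = 50, seed = 3)
#' @export
simulation_config <- function(genotype, n_reads = 100L, allele_ratio = 0.5,
                              sub_rate = 0, ins_rate = 0, del_rate = 0,
                              min_span = 1, max_span = 1, seed = 1L) {
  .check_alleles(genotype)
  stopifnot(length(n_reads) == 1L, n_reads >= 0)
  if (allele_ratio < 0 || allele_ratio > 1)
    stop("allele_ratio must be in [0, 1]", call. = FALSE)
  for (r in c(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate))
    if (r < 0 || r > 0.3)
      stop("error rates must be in [0, 0.3]", call. = FALSE)
  if (min_span <= 0 || max_span > 1 || min_span > max_span)
    stop("need 0 < min_span <= max_span <= 1", call. = FALSE)
  structure(list(genotype = genotype, n_reads = as.integer(n_reads),
                 allele_ratio = allele_ratio, sub_rate = sub_rate,
                 ins_rate = ins_rate, del_rate = del_rate,
                 min_span = min_span, max_span = max_span,
                 seed = as.integer(seed)),
            class = "abo_sim_config")
}

# apply the per-base error model to one sequence (character scalar)
.mutate_seq <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate + ins_rate + del_rate == 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  u <- runif(length(b))
  keep_del <- u >= del_rate
  is_ins <- u >= del_rate & u < del_rate + ins_rate
  is_sub <- u >= del_rate + ins_rate & u < del_rate + ins_rate + sub_rate
  if (any(is_sub)) {
    alt <- c("A", "C", "G", "T")
    for (i in which(is_sub)) b[i] <- sample(setdiff(alt, b[i]), 1L)
  }
  out <- b
  out[is_ins] <- paste0(b[is_ins], b[is_ins])  # duplicate = homopolymer-like
  out[!keep_del] <- ""
  paste(out, collapse = "")
}

#' Simulate amplicon reads for a diploid ABO genotype
#'
#' Generates `n_reads` reads per exon, split between the two alleles by
#' `allele_ratio` (deterministic rounding), each read a contiguous
#' substring of its allele's exon sequence. At `span = 1` every read covers
#' the whole exon and hence all diagnostic positions. Read names encode the
#' allele of origin (`read0001|O1|exon6`) for truth tracking; base
#' qualities are a constant Q20 placeholder.
#'
#' @param config An `abo_sim_config`.
#' @param references An `abo_references` object.
#' @return A list of class `abo_reads_set` with elements `exon6` and
#'   `exon7`, each a data.frame with columns `id`, `seq`, `qual`, plus a
#'   `truth` element (genotype, simple genotype, phenotype).
#' @examples
#' refs <- build_synthetic_references()
#' cfg <- simulation_config(c("O1", "O1"), n_reads = 2, seed = 1)
#' simulate_reads(cfg, refs)$exon6
#' @export
simulate_reads <- function(config, references) {
  stopifnot(inherits(config, "abo_sim_config"))
  n1 <- as.integer(round(config$n_reads * config$allele_ratio))
  n2 <- config$n_reads - n1
  origin <- c(rep(config$genotype[1], n1), rep(config$genotype[2], n2))
  seqs <- lapply(config$genotype, allele_sequence, references = references)
  names(seqs) <- NULL
  pos <- abo_positions()

  out <- .with_seed(config$seed, {
    per_exon <- lapply(c(exon6 = "exon6", exon7 = "exon7"), function(exon) {
      exon_no <- as.integer(sub("exon", "", exon))
      diag_min <- min(pos$exon_offset[pos$exon == exon_no])
      diag_max <- max(pos$exon_offset[pos$exon == exon_no])
      ids <- character(0); reads <- character(0)
      alle <- c(rep(1L, n1), rep(2L, n2))
      n_miss <- 0L
      for (k in seq_along(alle)) {
        full <- seqs[[alle[k]]][[exon]]
        L <- nchar(full)
        span <- runif(1, config$min_span, config$max_span)
        rl <- max(1L, as.integer(ceiling(span * L)))
        start <- if (rl >= L) 1L else sample.int(L - rl + 1L, 1L)
        if (start > diag_min || start + rl - 1L < diag_max)
          n_miss <- n_miss + 1L  # short spans may miss diagnostic sites
        raw <- substr(full, start, start + rl - 1L)
        reads[k] <- .mutate_seq(raw, config$sub_rate, config$ins_rate,
                                config$del_rate)
        ids[k] <- sprintf("read%04d|%s|%s", k, origin[k], exon)
      }
      if (n_miss > 0L)
        warning(n_miss, " ", exon,
                " read(s) do not span all diagnostic positions",
                call. = FALSE)
      keep <- nchar(reads) > 0L
      data.frame(id = ids[keep], seq = reads[keep],
                 qual = strrep("5", nchar(reads[keep])),  # Q20 placeholder
                 stringsAsFactors = FALSE)
    })
    per_exon
  })

  structure(list(exon6 = out$exon6, exon7 = out$exon7,
                 truth = list(genotype = .sort_alleles(config$genotype),
                              simple_genotype = .simple_genotype(config$genotype),
                              extended_genotype =
                                .extended_genotype(.sort_alleles(config$genotype)),
                              phenotype = .phenotype_of_pair(config$genotype))),
            class = "abo_read_set")
}

#' Write reads to FASTQ
#'
#' Standard 4-line-per-record FASTQ, optionally gzip-compressed; output
#' round-trips through [read_fastq()].
#'
#' @param records data.frame with columns `id`, `seq`, `qual` (as produced
#'   by [simulate_reads()]).
#' @param path Output path.
#' @param gzip Compress with gzip.
#' @return The path, invisibly.
#' @export
write_fastq <- function(records, path, gzip = FALSE) {
  seqs <- Biostrings::DNAStringSet(records$seq)
  names(seqs) <- records$id
  qual <- Biostrings::BStringSet(records$qual)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = qual,
                              compress = if (gzip) "gzip" else FALSE)
  invisible(path)
}

#' Simulate a set of samples to FASTQ files plus a truth table
#'
#' Convenience wrapper used by the `simulate` command: one pair of per-exon
#' FASTQ files per sample (named `<sample>.exon6.fastq[.gz]`), plus
#' `truth.csv` with the simulated genotype and phenotype of each sample.
#'
#' @param genotypes List (or single vector) of allele pairs.
#' @param out_dir Output directory (created if missing).
#' @param n_reads,allele_ratio,sub_rate,ins_rate,del_rate,seed See
#'   [simulation_config()]; each sample uses `seed + i - 1`.
#' @param gzip Write gzip-compressed FASTQ.
#' @param references Optional `abo_references`; defaults to
#'   [build_synthetic_references()] with seed 1.
#' @return Invisibly, the truth table data.frame.
#' @export
simulate_samples <- function(genotypes, out_dir, n_reads = 100L,
                             allele_ratio = 0.5, sub_rate = 0, ins_rate = 0,
                             del_rate = 0, seed = 1L, gzip = FALSE,
                             references = NULL) {
  if (!is.list(genotypes)) genotypes <- list(genotypes)
  if (is.null(references)) references <- build_synthetic_references(seed = 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_references(references, file.path(out_dir, "references.fasta"))
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  truth <- data.frame(sample_id = character(0), genotype = character(0),
                      phenotype = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(genotypes)) {
    sid <- sprintf("sample%03d", i)
    cfg <- simulation_config(genotypes[[i]], n_reads = n_reads,
                             allele_ratio = allele_ratio, sub_rate = sub_rate,
                             ins_rate = ins_rate, del_rate = del_rate,
                             seed = seed + i - 1L)
    rs <- simulate_reads(cfg, references)
    write_fastq(rs$exon6, file.path(out_dir, paste0(sid, ".exon6", ext)),
                gzip = gzip)
    write_fastq(rs$exon7, file.path(out_dir, paste0(sid, ".exon7", ext)),
                gzip = gzip)
    truth <- rbind(truth, data.frame(
      sample_id = sid, genotype = paste(rs$truth$genotype, collapse = "/"),
      phenotype = rs$truth$phenotype, stringsAsFactors = FALSE))
  }
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(truth)
}
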