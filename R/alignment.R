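#' Read a FASTQ file
#'
#' Plain or gzip-compressed FASTQ; order, names, sequences and qualities
#' are preserved.
#'
#' @param path FASTQ(.gz) path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path, call. = FALSE)
  # structural pre-check so a truncated/malformed record is reported with
  # its read index (gzfile() transparently reads plain files too)
  con <- gzfile(path, "r")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ in ", path, ": truncated record at read index ",
         length(lines) %/% 4L + 1L, call. = FALSE)
  for (r in seq_len(length(lines) %/% 4L)) {
    blk <- lines[(4L * r - 3L):(4L * r)]
    if (!startsWith(blk[1], "@") || !startsWith(blk[3], "+") ||
        nchar(blk[2]) != nchar(blk[4]))
      stop("malformed FASTQ in ", path, ": bad record at read index ", r,
           call. = FALSE)
  }
  recs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed FASTQ in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (length(recs) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  data.frame(id = names(recs), seq = as.character(recs),
             qual = as.character(S4Vectors::mcols(recs)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

# mean Phred quality of each quality string (Phred+33)
.mean_qual <- function(qual) {
  vapply(qual, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Length/quality read filter
#'
#' Keeps reads with `length >= min_length` and mean base quality
#' `>= min_mean_q`; kept/discarded counts are attached as attributes and
#' reported via `message()`.
#'
#' @param records data.frame from [read_fastq()].
#' @param min_length Minimum read length (bp).
#' @param min_mean_q Minimum mean Phred quality.
#' @return Filtered data.frame with attributes `n_kept` and `n_discarded`.
#' @export
filter_reads <- function(records, min_length = 50L, min_mean_q = 7) {
  stopifnot(min_length >= 0, min_mean_q >= 0)
  keep <- nchar(records$seq) >= min_length &
    .mean_qual(records$qual) >= min_mean_q
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_discarded") <- sum(!keep)
  message("filter_reads: kept ", sum(keep), "/", length(keep), " reads")
  out
}

#' Align one read to one reference
#'
#' Best local alignment under affine-gap scoring (match +2, mismatch -4,
#' gap of length L costs 4 + 2L). Traceback tie-breaking is fixed
#' (diagonal over deletion over insertion) and single gaps are left-aligned
#' within homopolymer runs, so alignments are fully deterministic.
#'
#' @param read,reference Character scalars (DNA).
#' @return A list with `score`, 1-based `read_start`/`read_end`/
#'   `ref_start`/`ref_end`, gapped `aligned_read`/`aligned_ref` strings and
#'   `identity` (matches / aligned columns); or `NULL` when no positive-
#'   scoring local alignment exists.
#' @examples
#' align_read("ACGTACGT", "ACGTACGT")$identity
#' @export
align_read <- function(read, reference) {
  stopifnot(nzchar(read), nzchar(reference))
  a <- .sw_align_cpp(read, reference)
  if (a$score <= 0) return(NULL)
  a$identity <- a$matches / a$columns
  a
}

#' Align reads against both exon references
#'
#' Every read is aligned to both references; an assignment is kept when it
#' passes the identity filter and its aligned span covers enough of that
#' exon reference (the amplicon target region). A read may thus contribute
#' to both exons if it genuinely aligns to both; spurious short
#' micro-alignments of a read against the other exon fail the coverage
#' filter.
#'
#' @param records data.frame from [read_fastq()] / [simulate_reads()].
#' @param references An `abo_references` object.
#' @param min_identity Minimum alignment identity (default 0.7, tolerant of
#'   nanopore error while rejecting junk).
#' @param min_ref_cover Minimum fraction of the exon reference the aligned
#'   span must cover (default 0.9).
#' @return data.frame of class `abo_alignments`: one row per accepted
#'   read-reference assignment with columns `read_id`, `reference`,
#'   `score`, `identity`, `ref_start`, `ref_end`, `aligned_read`,
#'   `aligned_ref`.
#' @export
align_reads <- function(records, references, min_identity = 0.7,
                        min_ref_cover = 0.9) {
  rows <- vector("list", nrow(records) * 2L)
  n <- 0L
  for (ref_name in c("exon6", "exon7")) {
    ref_seq <- references[[ref_name]]
    ref_len <- nchar(ref_seq)
    for (i in seq_len(nrow(records))) {
      a <- align_read(records$seq[i], ref_seq)
      if (is.null(a)) next
      if (a$identity < min_identity) next
      cover <- a$ref_end - a$ref_start + 1L
      if (cover < min_ref_cover * ref_len) next
      n <- n + 1L
      rows[[n]] <- data.frame(
        read_id = records$id[i], reference = ref_name, score = a$score,
        identity = a$identity, ref_start = a$ref_start, ref_end = a$ref_end,
        aligned_read = a$aligned_read, aligned_ref = a$aligned_ref,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (n > 0L) do.call(rbind, rows[seq_len(n)]) else
    data.frame(read_id = character(0), reference = character(0),
               score = numeric(0), identity = numeric(0),
               ref_start = integer(0), ref_end = integer(0),
               aligned_read = character(0), aligned_ref = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("abo_alignments", "data.frame")
  out
}

#' Build a per-position pileup from alignments
#'
#' Each aligned read contributes exactly one symbol per covered reference
#' position: its base, or `DEL` where its alignment skips the reference
#' base. Insertions between reference positions do not create columns.
#'
#' @param alignments `abo_alignments` rows for one reference.
#' @param reference The reference sequence (character scalar).
#' @return data.frame with one row per reference position: `pos`, counts
#'   `A`, `C`, `G`, `T`, `DEL`, and `depth`.
#' @export
build_pileup <- function(alignments, reference) {
  ref_len <- nchar(reference)
  counts <- matrix(0L, nrow = ref_len, ncol = 5L,
                   dimnames = list(NULL, .ABO_SYMBOLS))
  for (i in seq_len(nrow(alignments))) {
    pa <- strsplit(alignments$aligned_read[i], "", fixed = TRUE)[[1]]
    sa <- strsplit(alignments$aligned_ref[i], "", fixed = TRUE)[[1]]
    is_ref <- sa != "-"                       # columns consuming a ref base
    pos <- alignments$ref_start[i] + cumsum(is_ref) - 1L
    sym <- ifelse(pa == "-", "DEL", pa)
    pos <- pos[is_ref]
    sym <- sym[is_ref]
    idx <- cbind(pos, match(sym, .ABO_SYMBOLS))
    ok <- !is.na(idx[, 2])                    # ignore ambiguity codes
    idx <- idx[ok, , drop = FALSE]
    if (nrow(idx)) {
      tab <- table(factor(idx[, 1], levels = seq_len(ref_len)),
                   factor(idx[, 2], levels = 1:5))
      counts <- counts + as.integer(tab)
    }
  }
  out <- as.data.frame(counts)
  out$pos <- seq_len(ref_len)
  out$depth <- rowSums(counts)
  out[, c("pos", .ABO_SYMBOLS, "depth")]
}

#' Quantify allele fractions at the diagnostic positions
#'
#' The per-sample "match-mismatch" profile: at each diagnostic position the
#' fraction of covering reads showing each symbol, with the covering depth.
#' Fractions at a position sum to 1 when depth > 0; zero-depth positions
#' carry `NA` fractions and are flagged by their depth.
#'
#' @param pileups Named list with `exon6` and `exon7` pileup data.frames
#'   from [build_pileup()].
#' @param sample_id Sample identifier.
#' @param total_reads Optional named vector of aligned-read counts per exon
#'   (for reporting).
#' @return Object of class `abo_profile`: data.frame with one row per
#'   diagnostic position (`exon`, `exon_offset`, `cdna`, `rsid`, fraction
#'   columns `A`, `C`, `G`, `T`, `DEL`, and `depth`), with attributes
#'   `sample_id` and `total_reads`.
#' @export
variant_profile <- function(pileups, sample_id = "sample",
                            total_reads = NULL) {
  pos <- abo_positions()
  rows <- lapply(seq_len(nrow(pos)), function(i) {
    exon <- paste0("exon", pos$exon[i])
    pp <- pileups[[exon]]
    row <- pos[i, , drop = FALSE]
    if (is.null(pp) || !pos$exon_offset[i] %in% pp$pos) {
      cnt <- setNames(rep(0L, 5L), .ABO_SYMBOLS)
    } else {
      cnt <- unlist(pp[pp$pos == pos$exon_offset[i], .ABO_SYMBOLS])
    }
    depth <- sum(cnt)
    fr <- if (depth > 0) cnt / depth else setNames(rep(NA_real_, 5L),
                                                   .ABO_SYMBOLS)
    for (s in .ABO_SYMBOLS) row[[s]] <- unname(fr[s])
    row$depth <- depth
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "sample_id") <- sample_id
  attr(out, "total_reads") <- total_reads
  class(out) <- c("abo_profile", "data.frame")
  out
}

#' @export
print.abo_profile <- function(x, ...) {
  cat("ABO variant profile for sample", attr(x, "sample_id"), "\n")
  df <- as.data.frame(x)
  df[.ABO_SYMBOLS] <- lapply(df[.ABO_SYMBOLS], round, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a pileup as CSV
#'
#' One row per reference position with symbol counts and depth (the
#' whole-exon variant-calling spreadsheet).
#'
#' @param pileup data.frame from [build_pileup()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_pileup_csv <- function(pileup, path) {
  write.csv(pileup, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# CIGAR string (M/I/D, no clipping ops needed for local alignment records)
.cigar_of <- function(aligned_read, aligned_ref) {
  pa <- strsplit(aligned_read, "", fixed = TRUE)[[1]]
  sa <- strsplit(aligned_ref, "", fixed = TRUE)[[1]]
  op <- ifelse(pa == "-", "D", ifelse(sa == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Export accepted alignments as SAM
#'
#' Minimal valid SAM: `@HD`/`@SQ` header plus one record per accepted
#' read-reference assignment (soft-clipping of unaligned read ends is
#' represented in the CIGAR).
#'
#' @param alignments `abo_alignments` data.frame.
#' @param records The read data.frame the alignments were built from (for
#'   full sequences).
#' @param references An `abo_references` object.
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
write_sam <- function(alignments, records, references, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:ABO_exon6\tLN:", nchar(references$exon6)),
           paste0("@SQ\tSN:ABO_exon7\tLN:", nchar(references$exon7)))
  lines <- hdr
  for (i in seq_len(nrow(alignments))) {
    rid <- alignments$read_id[i]
    seq <- records$seq[match(rid, records$id)]
    aligned <- gsub("-", "", alignments$aligned_read[i], fixed = TRUE)
    # soft clips from unaligned read ends
    start_in_read <- regexpr(aligned, seq, fixed = TRUE)[1]
    lead <- max(0L, start_in_read - 1L)
    trail <- nchar(seq) - lead - nchar(aligned)
    cig <- .cigar_of(alignments$aligned_read[i], alignments$aligned_ref[i])
    if (lead > 0) cig <- paste0(lead, "S", cig)
    if (trail > 0) cig <- paste0(cig, trail, "S")
    lines <- c(lines, paste(
      rid, 0L, paste0("ABO_", alignments$reference[i]),
      alignments$ref_start[i], 60L, cig, "*", 0L, 0L, seq,
      strrep("I", nchar(seq)), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
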