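#' Diagnostic positions of the ABO typing panel
#'
#' The five exon 6/7 sites whose base (or deletion) state separates the
#' common A, B and O1/O2/O3 allele classes. Coordinates are given both as
#' 1-based offsets within each exon sequence and as coding-sequence (cDNA)
#' positions; the two are linked by fixed offsets (+239 for exon 6, +374
#' for exon 7).
#'
#' @param mode `"5snv"` for the full five-position panel, `"3snv"` for the
#'   classical three-position panel (c.261, c.796, c.803) that cannot
#'   separate O2/O3 alleles from A.
#' @return A data.frame with one row per diagnostic position and columns
#'   `exon`, `exon_offset`, `cdna`, `rsid`, `consequence`.
#' @examples
#' abo_positions()
#' abo_positions("3snv")
#' @export
abo_positions <- function(mode = c("5snv", "3snv")) {
  mode <- match.arg(mode)
  pos <- data.frame(
    exon        = c(6L, 7L, 7L, 7L, 7L),
    exon_offset = c(22L, 422L, 428L, 429L, 431L),
    cdna        = c(261L, 796L, 802L, 803L, 805L),
    rsid        = c("rs8176719", "rs8176746", "rs41302905", "rs8176747",
                    "rs782782485"),
    consequence = c("frameshift", "missense", "missense", "missense",
                    "frameshift"),
    stringsAsFactors = FALSE
  )
  if (mode == "3snv") pos <- pos[pos$cdna %in% c(261L, 796L, 803L), ]
  rownames(pos) <- NULL
  pos
}

#' Expected symbol of each allele class at each diagnostic position
#'
#' O1 carries the c.261delG frameshift; O2 carries c.802G>A; O3 carries
#' c.804dupG, which is read out as G instead of T at position c.805; B
#' carries c.796C>A together with c.803G>C; A matches the reference at all
#' five sites.
#'
#' @return A 5 x 5 character matrix, rows named by allele (`O1`, `O2`,
#'   `O3`, `A`, `B`), columns named by cDNA position.
#' @examples
#' allele_patterns()["O1", ]
#' @export
allele_patterns <- function() {
  m <- matrix(
    c("DEL", "C", "G", "G", "T",   # O1
      "G",   "C", "A", "G", "T",   # O2
      "G",   "C", "G", "G", "G",   # O3
      "G",   "C", "G", "G", "T",   # A
      "G",   "A", "G", "C", "T"),  # B
    nrow = 5, byrow = TRUE,
    dimnames = list(.ALLELE_ORDER, as.character(abo_positions()$cdna))
  )
  m
}

.check_alleles <- function(alleles) {
  if (!is.character(alleles) || length(alleles) != 2L)
    stop("a genotype is an unordered pair of two allele labels", call. = FALSE)
  bad <- setdiff(alleles, .ALLELE_ORDER)
  if (length(bad))
    stop("unknown allele label(s): ", paste(bad, collapse = ", "),
         "; valid labels are ", paste(.ALLELE_ORDER, collapse = ", "),
         call. = FALSE)
  invisible(alleles)
}

#' Expected diploid state vector for a genotype
#'
#' Per diagnostic position, the union of the two alleles' expected symbols:
#' a single symbol where the genotype is homozygous, two where it is
#' heterozygous. Symmetric in the argument order.
#'
#' @param alleles Character vector of two allele labels from
#'   `O1, O2, O3, A, B` (order irrelevant).
#' @param mode Panel, see [abo_positions()].
#' @return Named list (by cDNA position) of sorted character vectors.
#' @examples
#' expected_profile(c("O1", "A"))
#' @export
expected_profile <- function(alleles, mode = c("5snv", "3snv")) {
  mode <- match.arg(mode)
  .check_alleles(alleles)
  pat <- allele_patterns()
  keys <- as.character(abo_positions(mode)$cdna)
  out <- lapply(keys, function(k)
    sort(unique(c(pat[alleles[1], k], pat[alleles[2], k]))))
  names(out) <- keys
  out
}

# canonical sorted pair and label helpers -----------------------------------

.sort_alleles <- function(alleles) {
  alleles[order(match(alleles, .ALLELE_ORDER))]
}

# collapsed one-letter genotype, Table-4 style ordering: AO, BO, AB, OO
.simple_genotype <- function(alleles) {
  letters1 <- sub("^O[123]$", "O", alleles)
  letters1 <- letters1[order(match(letters1, c("A", "B", "O")))]
  paste(letters1, collapse = "")
}

# extended genotype label: non-O letter first, then O subtype (AO1, BO2);
# two O subtypes in numeric order (O1O2); AA / BB / AB unchanged
.extended_genotype <- function(alleles) {
  is_o <- grepl("^O[123]$", alleles)
  if (sum(is_o) == 1L) paste0(alleles[!is_o], alleles[is_o])
  else paste(.sort_alleles(alleles), collapse = "")
}

.phenotype_of_pair <- function(alleles) {
  phenotype_from_genotype(.simple_genotype(alleles))
}

# encode a state vector (named list of symbol vectors) as a matching key
.state_key <- function(states) {
  paste(vapply(states, function(s) paste(sort(s), collapse = "/"),
               character(1)), collapse = ";")
}

#' Genotype rule table
#'
#' All diploid classification rules: the expected per-position state vector
#' of every genotype, with its collapsed genotype, extended genotype and
#' predicted phenotype. The five-position panel has 15 rules (all unordered
#' pairs over the five allele classes) with pairwise-distinct state
#' vectors; the three-position panel collapses O1/O2/O3 to a single O
#' allele (taking the classical O1 pattern) and has 6 rules.
#'
#' @param mode `"5snv"` or `"3snv"`.
#' @return A data.frame with columns `genotype` (extended label),
#'   `allele1`, `allele2`, `simple_genotype`, `phenotype`, one column per
#'   panel position (`c261`, `c796`, ... holding `"G"`, `"DEL/G"`, ...)
#'   and a hidden matching key in column `state_key`.
#' @examples
#' rule_table("5snv")
#' rule_table("3snv")
#' @export
rule_table <- function(mode = c("5snv", "3snv")) {
  mode <- match.arg(mode)
  alleles <- if (mode == "5snv") .ALLELE_ORDER else c("O1", "A", "B")
  pairs <- expand.grid(i = seq_along(alleles), j = seq_along(alleles))
  pairs <- pairs[pairs$i <= pairs$j, ]
  keys <- as.character(abo_positions(mode)$cdna)

  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- alleles[pairs$i[r]]
    b <- alleles[pairs$j[r]]
    states <- expected_profile(c(a, b), mode = mode)
    state_str <- vapply(states, function(s) paste(sort(s), collapse = "/"),
                        character(1))
    if (mode == "3snv") {
      # O subtype not resolvable on three positions: report plain O
      a2 <- sub("^O1$", "O", a); b2 <- sub("^O1$", "O", b)
      simple <- .simple_genotype(c(a, b))
      ext <- simple
      out <- data.frame(genotype = simple, allele1 = a2, allele2 = b2,
                        stringsAsFactors = FALSE)
    } else {
      simple <- .simple_genotype(c(a, b))
      ext <- .extended_genotype(.sort_alleles(c(a, b)))
      out <- data.frame(genotype = ext, allele1 = .sort_alleles(c(a, b))[1],
                        allele2 = .sort_alleles(c(a, b))[2],
                        stringsAsFactors = FALSE)
    }
    out$simple_genotype <- simple
    out$phenotype <- .phenotype_of_pair(c(a, b))
    for (k in seq_along(keys)) out[[paste0("c", keys[k])]] <- state_str[k]
    out$state_key <- .state_key(states)
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Export a rule table as CSV
#'
#' @param mode `"5snv"` or `"3snv"`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_rule_table <- function(mode, path) {
  tab <- rule_table(mode)
  tab$state_key <- NULL
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# synthetic references -------------------------------------------------------

#' Build synthetic ABO exon 6/7 reference sequences
#'
#' Generates a pair of reference sequences that stand in for the exon 6 and
#' exon 7 regions of an ABO*A1-type reference allele: every diagnostic
#' position carries the A-allele symbol, and all other positions are drawn
#' uniformly at random. The bases flanking the exon-6 deletion site (offsets
#' 21 and 23) are constrained to differ from the base at offset 22, so a
#' single-base deletion there cannot be shifted away from the diagnostic
#' column by gap left-alignment. Real NG_006669.2-derived exon sequences may
#' be substituted via [read_references()].
#'
#' @param seed Integer seed; the same seed always yields the same pair.
#' @param exon6_length,exon7_length Sequence lengths (defaults mimic the
#'   real exon sizes, 135 and 691 bp).
#' @return An object of class `abo_references`: a list with character
#'   elements `exon6` and `exon7`.
#' @examples
#' refs <- build_synthetic_references(seed = 7)
#' substr(refs$exon6, 22, 22)  # "G", the A-allele symbol at c.261
#' @export
build_synthetic_references <- function(seed = 1L, exon6_length = 135L,
                                       exon7_length = 691L) {
  if (exon6_length < 40L)
    stop("exon6_length must be at least 40 to contain the diagnostic site",
         call. = FALSE)
  if (exon7_length < 450L)
    stop("exon7_length must be at least 450 to contain all diagnostic sites",
         call. = FALSE)
  bases <- c("A", "C", "G", "T")
  refs <- .with_seed(seed, {
    e6 <- sample(bases, exon6_length, replace = TRUE)
    e7 <- sample(bases, exon7_length, replace = TRUE)
    # A-allele symbols at the diagnostic offsets
    e6[22] <- "G"
    e7[c(422, 428, 429, 431)] <- c("C", "G", "G", "T")
    # non-homopolymeric guard around the deletion site
    for (i in c(21, 23)) {
      while (e6[i] == "G") e6[i] <- sample(bases, 1)
    }
    list(exon6 = paste(e6, collapse = ""), exon7 = paste(e7, collapse = ""))
  })
  structure(refs, class = "abo_references", seed = seed)
}

#' Apply an allele's variants to the reference sequences
#'
#' @param allele One of `O1`, `O2`, `O3`, `A`, `B`. O1 deletes exon-6 base
#'   22 (c.261delG, sequence one base shorter); O2 substitutes exon-7 base
#'   428 G>A (c.802G>A); O3 sets exon-7 base 431 to G (the readout of
#'   c.804dupG); B substitutes exon-7 bases 422 C>A and 429 G>C; A returns
#'   the references unchanged.
#' @param references An `abo_references` object.
#' @return A list with character elements `exon6` and `exon7`.
#' @examples
#' refs <- build_synthetic_references()
#' nchar(allele_sequence("O1", refs)$exon6) == nchar(refs$exon6) - 1
#' @export
allele_sequence <- function(allele, references) {
  if (!is.character(allele) || length(allele) != 1L ||
      !allele %in% .ALLELE_ORDER)
    stop("unknown allele label: ", paste(allele, collapse = ","),
         "; valid labels are ", paste(.ALLELE_ORDER, collapse = ", "),
         call. = FALSE)
  e6 <- references$exon6
  e7 <- references$exon7
  sub_at <- function(s, i, b) {
    substr(s, i, i) <- b
    s
  }
  switch(allele,
    A  = list(exon6 = e6, exon7 = e7),
    O1 = list(exon6 = paste0(substr(e6, 1, 21), substr(e6, 23, nchar(e6))),
              exon7 = e7),
    O2 = list(exon6 = e6, exon7 = sub_at(e7, 428, "A")),
    O3 = list(exon6 = e6, exon7 = sub_at(e7, 431, "G")),
    B  = list(exon6 = e6, exon7 = sub_at(sub_at(e7, 422, "A"), 429, "C"))
  )
}

#' Write reference sequences to FASTA
#'
#' Records are named `ABO_exon6` and `ABO_exon7`.
#'
#' @param references An `abo_references` object (or any list with `exon6`
#'   and `exon7` character elements).
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_references <- function(references, path) {
  seqs <- Biostrings::DNAStringSet(c(ABO_exon6 = references$exon6,
                                     ABO_exon7 = references$exon7))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read reference sequences from FASTA
#'
#' Expects two records whose names contain `exon6` and `exon7`.
#'
#' @param path FASTA path.
#' @return An `abo_references` object.
#' @export
read_references <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  i6 <- grep("exon6", names(seqs))
  i7 <- grep("exon7", names(seqs))
  if (length(i6) != 1L || length(i7) != 1L)
    stop("reference FASTA must contain exactly one exon6 and one exon7 record",
         call. = FALSE)
  structure(list(exon6 = as.character(seqs[[i6]]),
                 exon7 = as.character(seqs[[i7]])),
            class = "abo_references")
}

#' @export
print.abo_references <- function(x, ...) {
  cat("ABO exon references: exon6", nchar(x$exon6), "bp, exon7",
      nchar(x$exon7), "bp\n")
  invisible(x)
}
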