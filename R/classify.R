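#' Call the diploid state of one diagnostic position
#'
#' Applies the allele-balance rule: with depth at or above `min_depth`,
#' every symbol whose fraction reaches `het_threshold` is called. One
#' called symbol means homozygous, two heterozygous; the boundary is
#' inclusive, so an exact 80:20 split is still called heterozygous. Three
#' or more symbols above threshold make the position ambiguous.
#'
#' @param fractions Named numeric vector over `A`, `C`, `G`, `T`, `DEL`
#'   summing to 1 (when depth > 0).
#' @param depth Covering-read count at the position.
#' @param het_threshold Minor-symbol fraction at or above which a symbol is
#'   called (default 0.20, the 80:20 rule).
#' @param min_depth Depth below which the position is flagged
#'   `low_coverage` (default 20).
#' @return A list with `symbols` (sorted character vector, empty unless
#'   status is `"ok"`) and `status` (`"ok"`, `"low_coverage"` or
#'   `"ambiguous"`).
#' @examples
#' call_position_state(c(G = 0.8, A = 0.2, C = 0, T = 0, DEL = 0), 100)
#' @export
call_position_state <- function(fractions, depth, het_threshold = 0.20,
                                min_depth = 20L) {
  if (depth < min_depth)
    return(list(symbols = character(0), status = "low_coverage"))
  fr <- fractions[!is.na(fractions)]
  # the boundary is inclusive; the epsilon keeps an exact 80:20 split
  # heterozygous when the minor fraction (e.g. 1 - 0.8) is one ulp short
  called <- names(fr)[fr >= het_threshold - 1e-9]
  if (length(called) == 0L || length(called) > 2L)
    return(list(symbols = character(0), status = "ambiguous"))
  list(symbols = sort(called), status = "ok")
}

#' Reliability tier of a call from its read count
#'
#' Read-count bands: fewer than 20 reads is `VeryLow`, 20-49 `Low`, 50-499
#' `Moderate`, 500 or more `Robust`.
#'
#' @param read_count Non-negative integer.
#' @return Tier label.
#' @examples
#' reliability_tier(732)
#' @export
reliability_tier <- function(read_count) {
  stopifnot(read_count >= 0)
  if (read_count < 20) "VeryLow"
  else if (read_count < 50) "Low"
  else if (read_count < 500) "Moderate"
  else "Robust"
}

#' Predicted phenotype of a collapsed genotype
#'
#' @param genotype One of `OO`, `AO`, `AA`, `BO`, `BB`, `AB` (allele order
#'   irrelevant).
#' @return `"O"`, `"A"`, `"B"` or `"AB"`.
#' @examples
#' phenotype_from_genotype("AO")
#' @export
phenotype_from_genotype <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  key <- paste(sort(strsplit(genotype, "", fixed = TRUE)[[1]]), collapse = "")
  out <- c(OO = "O", AO = "A", AA = "A", BO = "B", BB = "B", AB = "AB")[key]
  if (is.na(out)) stop("unknown genotype label: ", genotype, call. = FALSE)
  unname(out)
}

#' Classify a variant profile into an ABO call
#'
#' Converts the per-position allele fractions into diploid position states
#' (allele-balance rule) and matches the state vector against the rule
#' table by exact per-position set equality. Any position below the depth
#' gate makes the sample `low_coverage` (the remedy is repeat testing, so
#' this outranks `unknown`); an ambiguous position or an
#' unmatched state vector makes it `unknown`. The per-position fractions
#' and states are retained in the call for audit.
#'
#' @param profile An `abo_profile` from [variant_profile()] (or
#'   [make_profile()] for directly specified fractions).
#' @param mode `"5snv"` (default) or `"3snv"`.
#' @param het_threshold,min_depth See [call_position_state()].
#' @return Object of class `abo_call`: list with `sample_id`, `status`
#'   (`ok`/`low_coverage`/`unknown`), `phenotype`, `genotype` (collapsed,
#'   e.g. `AO`), `extended_genotype` (e.g. `AO1`), `alleles`, `mode`,
#'   `reads` (gating depth: minimum across the panel), `tier`, and
#'   `positions` (audit data.frame).
#' @examples
#' p <- make_profile(list(`261` = c(G = 1), `796` = c(C = 1),
#'                        `802` = c(G = 1), `803` = c(G = 1),
#'                        `805` = c(T = 1)), depth = 100)
#' classify_profile(p)$genotype  # "AA"
#' @export
classify_profile <- function(profile, mode = c("5snv", "3snv"),
                             het_threshold = 0.20, min_depth = 20L) {
  mode <- match.arg(mode)
  pos <- abo_positions(mode)
  prof <- as.data.frame(profile)
  audit <- prof[match(pos$cdna, prof$cdna), , drop = FALSE]

  states <- vector("list", nrow(audit))
  names(states) <- as.character(pos$cdna)
  stat <- character(nrow(audit))
  for (i in seq_len(nrow(audit))) {
    fr <- unlist(audit[i, .ABO_SYMBOLS])
    st <- call_position_state(fr, audit$depth[i], het_threshold, min_depth)
    states[[i]] <- st$symbols
    stat[i] <- st$status
  }
  audit$state <- vapply(states, function(s)
    if (length(s)) paste(s, collapse = "/") else NA_character_, character(1))
  audit$state_status <- stat

  reads <- min(audit$depth)
  call <- list(sample_id = attr(profile, "sample_id"), status = "ok",
               phenotype = NA_character_, genotype = NA_character_,
               extended_genotype = NA_character_, alleles = NULL,
               mode = mode, reads = reads, tier = reliability_tier(reads),
               het_threshold = het_threshold, min_depth = min_depth,
               positions = audit)
  class(call) <- "abo_call"

  if (any(stat == "low_coverage")) {
    call$status <- "low_coverage"
    return(call)
  }
  if (any(stat == "ambiguous")) {
    call$status <- "unknown"
    return(call)
  }
  key <- .state_key(states)
  rules <- rule_table(mode)
  hit <- which(rules$state_key == key)
  if (length(hit) != 1L) {
    call$status <- "unknown"
    return(call)
  }
  call$phenotype <- rules$phenotype[hit]
  call$genotype <- rules$simple_genotype[hit]
  call$extended_genotype <- rules$genotype[hit]
  call$alleles <- c(rules$allele1[hit], rules$allele2[hit])
  call
}

#' @export
print.abo_call <- function(x, ...) {
  cat("ABO call for sample ", x$sample_id, " [", x$mode, "]\n", sep = "")
  cat("  status:   ", x$status, "\n")
  if (x$status == "ok") {
    cat("  phenotype:", x$phenotype, "\n")
    cat("  genotype: ", x$genotype, " (", x$extended_genotype, ")\n",
        sep = "")
  }
  cat("  reads:    ", x$reads, " (", x$tier, ")\n", sep = "")
  invisible(x)
}

#' Build a variant profile from explicit fractions
#'
#' Constructs an `abo_profile` directly from per-position symbol fractions
#' (e.g. a published fraction table), bypassing alignment.
#'
#' @param fractions Named list: one element per cDNA position (`"261"`,
#'   `"796"`, `"802"`, `"803"`, `"805"`), each a named numeric vector of
#'   symbol fractions (unnamed symbols default to 0).
#' @param depth Single depth for all positions, or named vector per
#'   position.
#' @param sample_id Sample identifier.
#' @return An `abo_profile`.
#' @examples
#' make_profile(list(`261` = c(G = 0.5, DEL = 0.5), `796` = c(C = 1),
#'                   `802` = c(G = 0.5, A = 0.5), `803` = c(G = 1),
#'                   `805` = c(T = 1)), depth = 824)
#' @export
make_profile <- function(fractions, depth, sample_id = "sample") {
  pos <- abo_positions()
  keys <- as.character(pos$cdna)
  if (!all(keys %in% names(fractions)))
    stop("fractions must name all five cDNA positions: ",
         paste(keys, collapse = ", "), call. = FALSE)
  if (length(depth) == 1L) depth <- setNames(rep(depth, 5L), keys)
  out <- pos
  for (s in .ABO_SYMBOLS) out[[s]] <- 0
  for (k in keys) {
    fr <- fractions[[k]]
    bad <- setdiff(names(fr), .ABO_SYMBOLS)
    if (length(bad))
      stop("unknown symbols at position ", k, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    for (s in names(fr)) out[out$cdna == as.integer(k), s] <- fr[[s]]
  }
  out$depth <- as.integer(depth[keys])
  attr(out, "sample_id") <- sample_id
  attr(out, "total_reads") <- NULL
  class(out) <- c("abo_profile", "data.frame")
  out
}
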