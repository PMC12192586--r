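# shared fixtures and independent oracles

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force Smith-Waterman-Gotoh score oracle, written independently of
# the package's aligner: plain R matrices, gap of length L costs
# open + L * ext. Returns only the optimal local score.
sw_score_oracle <- function(read, ref, match = 2, mismatch = -4,
                            open = 4, ext = 2) {
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  m <- length(a); n <- length(b)
  H <- matrix(0, m + 1, n + 1)
  D <- matrix(-Inf, m + 1, n + 1)
  I <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      D[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, D[i + 1, j] - ext)
      I[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, I[i, j + 1] - ext)
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, D[i + 1, j + 1], I[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# the six published fraction profiles used to demonstrate O-subtype
# resolution (read counts 824, 1684, 432, 117, 575, 529)
table5_profiles <- function() {
  het <- function(a, b) setNames(c(0.5, 0.5), c(a, b))
  o1o2 <- list(`261` = het("G", "DEL"), `796` = c(C = 1),
               `802` = het("G", "A"), `803` = c(G = 1), `805` = c(T = 1))
  o2b <- list(`261` = c(G = 1), `796` = het("C", "A"),
              `802` = het("G", "A"), `803` = het("G", "C"), `805` = c(T = 1))
  list(
    Sample0054 = list(fractions = o1o2, depth = 824, expected = "O",
                      p3 = "A", g3 = "AO", p5 = "O", g5 = "OO",
                      ext5 = c("O1", "O2")),
    Sample0061 = list(fractions = o1o2, depth = 1684, expected = "O",
                      p3 = "A", g3 = "AO", p5 = "O", g5 = "OO",
                      ext5 = c("O1", "O2")),
    Sample0071 = list(fractions = o2b, depth = 432, expected = "B",
                      p3 = "AB", g3 = "AB", p5 = "B", g5 = "OB",
                      ext5 = c("O2", "B")),
    Sample0081 = list(fractions = o1o2, depth = 117, expected = "O",
                      p3 = "A", g3 = "AO", p5 = "O", g5 = "OO",
                      ext5 = c("O1", "O2")),
    Sample0101 = list(fractions = o1o2, depth = 575, expected = "O",
                      p3 = "A", g3 = "AO", p5 = "O", g5 = "OO",
                      ext5 = c("O1", "O2")),
    Sample0105 = list(fractions = o1o2, depth = 529, expected = "O",
                      p3 = "A", g3 = "AO", p5 = "O", g5 = "OO",
                      ext5 = c("O1", "O2"))
  )
}

# genotype comparison that ignores allele order and O-subtype label style
same_genotype <- function(x, y) {
  norm <- function(g) paste(sort(strsplit(g, "", fixed = TRUE)[[1]]),
                            collapse = "")
  norm(x) == norm(y)
}

all_allele_pairs <- function(alleles = c("O1", "O2", "O3", "A", "B")) {
  out <- list()
  for (i in seq_along(alleles))
    for (j in i:length(alleles))
      out[[length(out) + 1L]] <- c(alleles[i], alleles[j])
  out
}

# run the full FASTQ-free pipeline (simulate -> align -> pileup -> profile)
simulate_profile <- function(genotype, n_reads, seed, refs,
                             sub_rate = 0, ins_rate = 0, del_rate = 0,
                             allele_ratio = 0.5) {
  cfg <- simulation_config(genotype, n_reads = n_reads,
                           allele_ratio = allele_ratio, sub_rate = sub_rate,
                           ins_rate = ins_rate, del_rate = del_rate,
                           seed = seed)
  rs <- simulate_reads(cfg, refs)
  aln <- align_reads(rbind(rs$exon6, rs$exon7), refs)
  pu <- list(
    exon6 = build_pileup(aln[aln$reference == "exon6", , drop = FALSE],
                         refs$exon6),
    exon7 = build_pileup(aln[aln$reference == "exon7", , drop = FALSE],
                         refs$exon7))
  variant_profile(pu, sample_id = paste(genotype, collapse = ""))
}
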