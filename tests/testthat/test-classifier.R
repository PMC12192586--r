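test_that("allele-balance position calling follows the 80:20 rule with inclusive boundary", {
  fr <- function(...) {
    v <- c(A = 0, C = 0, G = 0, T = 0, DEL = 0)
    x <- c(...)
    v[names(x)] <- x
    v
  }
  expect_equal(call_position_state(fr(G = 0.85, A = 0.15), 100),
               list(symbols = "G", status = "ok"))
  expect_equal(call_position_state(fr(G = 0.80, A = 0.20), 100),
               list(symbols = c("A", "G"), status = "ok"))
  expect_equal(call_position_state(fr(G = 0.5, DEL = 0.5), 19)$status,
               "low_coverage")
  expect_equal(call_position_state(fr(G = 0.4, A = 0.3, C = 0.3), 100)$status,
               "ambiguous")
  # custom threshold is honored
  expect_equal(call_position_state(fr(G = 0.85, A = 0.15), 100,
                                   het_threshold = 0.10)$symbols,
               c("A", "G"))
})

test_that("every genotype is recovered from its own expected profile", {
  # inverse-mapping oracle, exhaustive over all 15 genotypes
  for (pair in all_allele_pairs()) {
    states <- expected_profile(pair)
    fractions <- lapply(states, function(s) {
      setNames(rep(1 / length(s), length(s)), s)
    })
    prof <- make_profile(fractions, depth = 100,
                         sample_id = paste(pair, collapse = ""))
    cl <- classify_profile(prof)
    expect_equal(cl$status, "ok")
    expect_setequal(cl$alleles, unique(pair))
    expect_equal(cl$phenotype, phenotype_from_genotype(cl$genotype))
  }
})

test_that("3-SNV and 5-SNV modes agree for genotypes without O2/O3", {
  pairs <- all_allele_pairs(c("O1", "A", "B"))
  for (pair in pairs) {
    states <- expected_profile(pair)
    fractions <- lapply(states, function(s)
      setNames(rep(1 / length(s), length(s)), s))
    prof <- make_profile(fractions, depth = 100)
    c5 <- classify_profile(prof, mode = "5snv")
    c3 <- classify_profile(prof, mode = "3snv")
    expect_equal(c3$phenotype, c5$phenotype)
    expect_true(same_genotype(c3$genotype, c5$genotype))
  }
})

test_that("calls are ok at any depth above a passing depth (monotone gate)", {
  states <- expected_profile(c("O1", "B"))
  fractions <- lapply(states, function(s)
    setNames(rep(1 / length(s), length(s)), s))
  for (d in c(20, 21, 100, 10000)) {
    cl <- classify_profile(make_profile(fractions, depth = d))
    expect_equal(cl$status, "ok")
    expect_equal(cl$extended_genotype, "BO1")
  }
  expect_equal(classify_profile(make_profile(fractions, depth = 19))$status,
               "low_coverage")
})

test_that("an unmatched state vector yields status unknown with audit retained", {
  # exon-6 het deletion combined with full B-style exon-7 heterozygosity
  # matches no rule
  prof <- make_profile(list(`261` = c(DEL = 0.5, G = 0.5),
                            `796` = c(C = 1),
                            `802` = c(G = 0.5, A = 0.5),
                            `803` = c(G = 0.5, C = 0.5),
                            `805` = c(T = 1)), depth = 100)
  cl <- classify_profile(prof)
  expect_equal(cl$status, "unknown")
  expect_true(is.na(cl$phenotype))
  expect_equal(nrow(cl$positions), 5L)
  expect_equal(cl$positions$state[cl$positions$cdna == 261], "DEL/G")
})

test_that("low coverage outranks unknown when both problems co-occur", {
  prof <- make_profile(list(`261` = c(DEL = 0.5, G = 0.5),
                            `796` = c(C = 1),
                            `802` = c(G = 0.5, A = 0.5),
                            `803` = c(G = 0.5, C = 0.5),
                            `805` = c(T = 1)),
                       depth = c(`261` = 10, `796` = 100, `802` = 100,
                                 `803` = 100, `805` = 100))
  expect_equal(classify_profile(prof)$status, "low_coverage")
})

test_that("classification is total over random fraction vectors", {
  set.seed(5)
  for (k in 1:50) {
    fractions <- lapply(setNames(nm = c("261", "796", "802", "803", "805")),
                        function(p) {
                          x <- runif(5)
                          setNames(x / sum(x), c("A", "C", "G", "T", "DEL"))
                        })
    cl <- classify_profile(make_profile(fractions, depth = sample(0:200, 1)))
    expect_true(cl$status %in% c("ok", "low_coverage", "unknown"))
  }
})

test_that("the call is invariant to the order of the simulated alleles", {
  refs <- build_synthetic_references(seed = 1)
  for (pair in list(c("A", "O1"), c("O2", "B"), c("O3", "A"))) {
    p1 <- simulate_profile(pair, n_reads = 30, seed = 3, refs)
    p2 <- simulate_profile(rev(pair), n_reads = 30, seed = 3, refs)
    c1 <- classify_profile(p1)
    c2 <- classify_profile(p2)
    expect_equal(c1$status, "ok")
    expect_equal(c1$genotype, c2$genotype)
    expect_equal(c1$extended_genotype, c2$extended_genotype)
  }
})

test_that("reliability tiers follow the read-count bands", {
  expect_equal(reliability_tier(8), "VeryLow")
  expect_equal(reliability_tier(19), "VeryLow")
  expect_equal(reliability_tier(20), "Low")
  expect_equal(reliability_tier(35), "Low")
  expect_equal(reliability_tier(49), "Low")
  expect_equal(reliability_tier(50), "Moderate")
  expect_equal(reliability_tier(499), "Moderate")
  expect_equal(reliability_tier(500), "Robust")
  expect_equal(reliability_tier(732), "Robust")
})

test_that("genotype to phenotype collapse", {
  expect_equal(phenotype_from_genotype("OO"), "O")
  expect_equal(phenotype_from_genotype("AO"), "A")
  expect_equal(phenotype_from_genotype("OA"), "A")
  expect_equal(phenotype_from_genotype("AA"), "A")
  expect_equal(phenotype_from_genotype("BO"), "B")
  expect_equal(phenotype_from_genotype("BB"), "B")
  expect_equal(phenotype_from_genotype("AB"), "AB")
  expect_error(phenotype_from_genotype("XY"), "unknown genotype")
})
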