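refs <- build_synthetic_references(seed = 1)

make_call <- function(sid, status = "ok", phenotype = "A", genotype = "AO",
                      ext = "AO1", reads = 100) {
  cl <- list(sample_id = sid, status = status,
             phenotype = if (status == "ok") phenotype else NA_character_,
             genotype = if (status == "ok") genotype else NA_character_,
             extended_genotype = if (status == "ok") ext else NA_character_,
             reads = reads, tier = reliability_tier(reads), mode = "5snv")
  class(cl) <- "abo_call"
  cl
}

test_that("sample summaries contain the polymorphism and phenotype blocks", {
  t5 <- table5_profiles()$Sample0054
  prof <- make_profile(t5$fractions, depth = t5$depth,
                       sample_id = "Sample0054")
  cl <- classify_profile(prof, mode = "5snv")
  lines <- summarize_sample(cl, prof)
  expect_true(any(grepl("ABO read polymorphisms", lines)))
  expect_true(any(grepl("ABO phenotype", lines)))
  expect_true(any(grepl("^status: ok$", lines)))
  expect_true(any(grepl("^phenotype: O$", lines)))
  expect_true(any(grepl("^genotype: OO$", lines)))
  expect_true(any(grepl("c.261", lines, fixed = TRUE)))

  # a zero-depth sample is flagged and carries no phenotype fields
  zp <- make_profile(list(`261` = c(G = 1), `796` = c(C = 1),
                          `802` = c(G = 1), `803` = c(G = 1),
                          `805` = c(T = 1)), depth = 0, sample_id = "empty")
  zl <- summarize_sample(classify_profile(zp), zp)
  expect_true(any(grepl("^status: low_coverage$", zl)))
  expect_false(any(grepl("^phenotype:", zl)))

  dir <- withr::local_tempdir()
  paths <- write_sample_summary(cl, prof, dir)
  expect_true(all(file.exists(paths)))
})

test_that("run aggregation separates results from the filtered export", {
  calls <- list(make_call("s1"), make_call("s2", phenotype = "O",
                                           genotype = "OO", ext = "O1O1"),
                make_call("s3", phenotype = "B", genotype = "BO",
                          ext = "BO1"),
                make_call("s4", status = "low_coverage", reads = 5))
  dir <- withr::local_tempdir()
  rep <- aggregate_run(calls, out_dir = dir, timestamps = FALSE)
  expect_equal(nrow(rep$results), 4L)
  expect_equal(nrow(rep$export), 3L)
  expect_equal(rep$counts[["ok"]], 3L)
  # conservation: export rows + flagged = total
  expect_equal(nrow(rep$export) +
                 sum(rep$results$status != "ok"), nrow(rep$results))
  expect_true(file.exists(file.path(dir, "ABO_result.csv")))
  expect_true(file.exists(file.path(dir, "final_export.csv")))
  expect_true(file.exists(file.path(dir, "versions.yml")))
  exp_csv <- read.csv(file.path(dir, "final_export.csv"))
  expect_equal(exp_csv$sample_id, c("s1", "s2", "s3"))

  # all flagged: export is empty but keeps its header
  rep2 <- aggregate_run(list(make_call("x", status = "low_coverage",
                                       reads = 2)),
                        out_dir = dir, timestamps = FALSE)
  expect_equal(nrow(rep2$export), 0L)
  exp2 <- read.csv(file.path(dir, "final_export.csv"))
  expect_equal(names(exp2), c("sample_id", "phenotype", "genotype",
                              "extended_genotype", "reads", "tier"))

  # rows are ordered by sample id regardless of input order
  rep3 <- aggregate_run(list(make_call("b"), make_call("a")))
  expect_equal(rep3$results$sample_id, c("a", "b"))
})

test_that("concordance metrics match hand-computed values", {
  truth <- data.frame(sample_id = paste0("s", 1:10),
                      phenotype = rep(c("A", "O"), 5),
                      stringsAsFactors = FALSE)
  calls <- lapply(seq_len(10), function(i)
    make_call(paste0("s", i), phenotype = truth$phenotype[i],
              genotype = ifelse(truth$phenotype[i] == "A", "AO", "OO")))
  cc <- concordance_report(calls, truth)
  expect_equal(cc$accuracy, 1)
  expect_equal(cc$n_evaluated, 10L)
  expect_equal(cc$n_excluded, 0L)

  # confusion [[9,1],[0,10]] over {A,O}: accuracy 0.95, sensitivity(A) 0.9
  truth2 <- data.frame(sample_id = paste0("t", 1:20),
                       phenotype = c(rep("A", 10), rep("O", 10)),
                       stringsAsFactors = FALSE)
  called2 <- c(rep("A", 9), "O", rep("O", 10))
  calls2 <- lapply(seq_len(20), function(i)
    make_call(paste0("t", i), phenotype = called2[i],
              genotype = ifelse(called2[i] == "A", "AO", "OO")))
  cc2 <- concordance_report(calls2, truth2)
  expect_equal(cc2$accuracy, 0.95)
  expect_equal(cc2$per_class$sensitivity[cc2$per_class$phenotype == "A"], 0.9)
  expect_equal(cc2$per_class$precision[cc2$per_class$phenotype == "A"], 1)
  expect_equal(cc2$per_class$specificity[cc2$per_class$phenotype == "O"], 0.9)

  # nothing evaluable
  cc3 <- concordance_report(list(make_call("z", status = "low_coverage")),
                            truth)
  expect_equal(cc3$n_evaluated, 0L)
  expect_true(is.na(cc3$accuracy))

  # a call missing from the truth table is excluded with a warning
  expect_warning(
    cc4 <- concordance_report(list(make_call("notintruth"), calls[[1]]),
                              truth),
    "missing sample")
  expect_equal(cc4$n_evaluated, 1L)
  expect_equal(cc4$n_excluded, 1L)
})

test_that("typing identical inputs twice yields byte-identical result tables", {
  dir <- withr::local_tempdir()
  simulate_samples(list(c("A", "O1"), c("B", "O2")), dir, n_reads = 25,
                   sub_rate = 0.02, seed = 5)
  mapping <- discover_samples(dir)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  for (out in c(out1, out2)) {
    run <- type_samples(mapping, refs)
    aggregate_run(run$calls, out_dir = out, timestamps = FALSE)
  }
  expect_identical(readLines(file.path(out1, "ABO_result.csv")),
                   readLines(file.path(out2, "ABO_result.csv")))
  expect_identical(readLines(file.path(out1, "final_export.csv")),
                   readLines(file.path(out2, "final_export.csv")))
})

test_that("mapping files resolve relative paths and enforce sample_id", {
  dir <- withr::local_tempdir()
  simulate_samples(list(c("A", "A")), dir, n_reads = 3, seed = 1)
  map_path <- file.path(dir, "mapping.csv")
  writeLines(c("sample_id,exon6_fastq,exon7_fastq",
               "s1,sample001.exon6.fastq,sample001.exon7.fastq"), map_path)
  m <- read_sample_mapping(map_path)
  expect_true(file.exists(m$exon6_fastq[1]))
  bad <- file.path(dir, "bad.csv")
  writeLines(c("id,fastq", "x,y"), bad)
  expect_error(read_sample_mapping(bad), "sample_id")
  expect_error(discover_samples(file.path(dir, "nope")), "not found")
})
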