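test_that("abundance tables round-trip bit-exactly and reject bad cells", {
  x <- matrix(c(1.25, 2.5, 3e6, 0.001953125), 2, 2,
              dimnames = list(c("A2MG (1424) – 5402", "A2MG – AIGYLNTGYQR"),
                              c("S001", "S002")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance_table(x, path, seed = 42)
  expect_equal(readLines(path, n = 1), "# seed: 42")
  y <- read_abundance_table(path)
  expect_identical(y, x)

  # duplicate marker rows rejected by id
  writeLines(c("marker_id,S001", "m1,1", "m1,2"), path)
  expect_error(read_abundance_table(path), "duplicate marker_id.*m1")

  # missing values unsupported
  writeLines(c("marker_id,S001,S002", "m1,1,NA"), path)
  expect_error(read_abundance_table(path), "non-numeric or missing.*S002")
})

test_that("sample sheets validate columns, duplicates and phenotype vocabulary", {
  sheet <- data.frame(
    sample_id = c(sprintf("S%03d", 1:9), "REF_01"),
    phenotype = c(rep(c("control", "NASH", "HCC"), each = 3),
                  "reference_pool"),
    age = c(round(runif(9, 30, 80)), NA), sex = c(rep(c("M", "F"), len = 9), NA),
    injection_index = 1:10, is_reference = c(rep(FALSE, 9), TRUE)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_sample_sheet(sheet, path, seed = 7)
  got <- read_sample_sheet(path)
  expect_equal(got$sheet$sample_id, sheet$sample_id)
  expect_equal(got$layout$is_reference, sheet$is_reference)
  expect_equal(got$layout$injection_index[got$layout$is_reference], 10L)

  bad <- sheet; bad$injection_index[2] <- 5L
  write_sample_sheet(bad, path)
  expect_error(read_sample_sheet(path), "duplicate injection_index.*5")

  bad2 <- sheet; bad2$phenotype[1] <- "cirrhosis"
  write_sample_sheet(bad2, path)
  expect_error(read_sample_sheet(path), "cirrhosis")

  # validation-cohort vocabulary accepted
  ok <- sheet; ok$phenotype[1] <- "benign"
  write_sample_sheet(ok, path)
  expect_no_error(read_sample_sheet(path))

  write_sample_sheet(sheet[, -3], path)
  expect_error(read_sample_sheet(path), "missing column.*age")
})

test_that("manifests round-trip with dash normalization and peptide/glycan exclusivity", {
  mf <- data.frame(marker_id = c("A2MG (1424) - 5402", "A2MG - AIGYLNTGYQR"),
                   protein = "A2MG", sites = c("1424", ""),
                   glycan_code = c("5402", ""), is_peptide = c(FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_marker_manifest(mf, path)
  got <- read_marker_manifest(path)
  expect_equal(got$marker_id,
               c("A2MG (1424) – 5402", "A2MG – AIGYLNTGYQR"))

  bad <- mf; bad$glycan_code[2] <- "5402"
  write_marker_manifest(bad, path)
  expect_error(read_marker_manifest(path), "either a peptide or")
})

test_that("unknown configuration keys and partial inputs are rejected", {
  expect_error(pipeline_config(seed = 1, alpha = 0.1), "unknown configuration")
  expect_error(pipeline_config(seed = 1, abundance = "a.csv"),
               "all of abundance")
  expect_error(pipeline_config(), "seed")
})

test_that("the synthetic pipeline runs end to end and is reproducible", {
  sc <- small_config(1)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg1 <- pipeline_config(seed = 5, out_dir = out1, sim = sc)
  cfg2 <- pipeline_config(seed = 5, out_dir = out2, sim = sc)
  res1 <- suppressMessages(run_pipeline(cfg1))
  res2 <- suppressMessages(run_pipeline(cfg2))

  for (f in c("raw_abundance.csv", "normalized_abundance.csv",
              "cascade_report.json", "motif_summary.csv", "cv_report.json")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  expect_s3_class(res1$cascade, "cascade_report")
  expect_s3_class(res1$cv, "cv_report")
  expect_true(res1$cv$auc_test >= 0 && res1$cv$auc_test <= 1)

  # run manifest records seed and config hash
  rm1 <- jsonlite::read_json(file.path(out1, "run_manifest.json"))
  expect_equal(rm1$seed, 5L)
  expect_identical(rm1$config_hash,
                   jsonlite::read_json(file.path(out2,
                                                 "run_manifest.json"))$config_hash)
})

test_that("fdr_alpha = 0 empties every significant set but completes", {
  cfg <- pipeline_config(seed = 6, out_dir = withr::local_tempdir(),
                         sim = small_config(1), fdr_alpha = 0)
  res <- suppressMessages(run_pipeline(cfg))
  expect_length(res$cascade$shared_fdr, 0)
  expect_equal(res$cascade$unidirectional$n_glycopeptides, 0)
})

test_that("a tampered abundance file aborts with a stage-tagged message", {
  out <- withr::local_tempdir()
  res <- suppressMessages(run_pipeline(
    pipeline_config(seed = 7, out_dir = out, sim = small_config(2))))
  # drop one sample column from the abundance table
  x <- read_abundance_table(file.path(out, "raw_abundance.csv"))
  drop <- colnames(x)[3]
  write_abundance_table(x[, -3], file.path(out, "raw_abundance.csv"))
  cfg <- pipeline_config(seed = 7, out_dir = withr::local_tempdir(),
                         abundance = file.path(out, "raw_abundance.csv"),
                         sample_sheet = res$paths$sample_sheet,
                         manifest = res$paths$manifest)
  expect_error(suppressMessages(run_pipeline(cfg)), paste0("read abundance.*", drop))
})
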