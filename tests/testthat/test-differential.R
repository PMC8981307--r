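mk_sheet <- function(phen, age = NULL, sex = NULL) {
  n <- length(phen)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)), phenotype = phen,
    age = if (is.null(age)) seq(40, 70, length.out = n) else age,
    sex = if (is.null(sex)) rep(c("M", "F"), length.out = n) else sex,
    injection_index = seq_len(n), is_reference = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("a noise-free 2x shift gives fold change exactly 2, oriented first/second", {
  sheet <- mk_sheet(rep(c("control", "HCC"), each = 6))
  x <- matrix(rep(c(8, 4), each = 6), nrow = 1,
              dimnames = list("m1", sheet$sample_id))
  d <- adjusted_fold_change(x, sheet, c("control", "HCC"))
  expect_equal(d$fold_change, 2, tolerance = 1e-9)
  d_rev <- adjusted_fold_change(x, sheet, c("HCC", "control"))
  expect_equal(d_rev$fold_change, 0.5, tolerance = 1e-9)
})

test_that("the vectorized fit matches lm() per marker, including covariates", {
  set.seed(4)
  sheet <- mk_sheet(rep(c("control", "NASH"), each = 10),
                    age = round(runif(20, 30, 80)),
                    sex = sample(c("M", "F"), 20, replace = TRUE))
  x <- matrix(2^rnorm(5 * 20, 10, 1), nrow = 5,
              dimnames = list(paste0("m", 1:5), sheet$sample_id))
  d <- adjusted_fold_change(x, sheet, c("control", "NASH"))
  for (i in 1:5) {
    df <- data.frame(y = log2(x[i, ]),
                     g = as.numeric(sheet$phenotype == "control"),
                     age = sheet$age, sexM = sheet$sex == "M")
    fit <- summary(lm(y ~ g + age + sexM, df))$coefficients
    expect_equal(d$log2fc[i], fit["g", "Estimate"], tolerance = 1e-9)
    expect_equal(d$p_value[i], fit["g", "Pr(>|t|)"], tolerance = 1e-9)
  }
})

test_that("orientation consistency: FC(A/B) * FC(B/A) = 1", {
  sim <- simulate_cohort(small_config(12))
  norm <- drift_correct(sim$raw, sim$layout)
  a <- adjusted_fold_change(norm, sim$sheet, c("control", "HCC"))
  b <- adjusted_fold_change(norm, sim$sheet, c("HCC", "control"))
  expect_equal(a$fold_change * b$fold_change, rep(1, nrow(a)),
               tolerance = 1e-9)
})

test_that("constant sex is dropped with a warning; tiny groups are errors", {
  sheet <- mk_sheet(rep(c("control", "HCC"), each = 5), sex = rep("M", 10))
  x <- matrix(2^rnorm(10, 10), nrow = 1, dimnames = list("m1", sheet$sample_id))
  expect_warning(adjusted_fold_change(x, sheet, c("control", "HCC")),
                 "collinear")
  sheet2 <- mk_sheet(c("control", "control", "control", "HCC", "HCC"))
  x2 <- matrix(1:5 * 1.0, nrow = 1,
               dimnames = list("m1", sheet2$sample_id))
  expect_error(adjusted_fold_change(x2, sheet2, c("control", "HCC")),
               ">= 3 samples")
})

test_that("null simulation yields approximately uniform p-values", {
  pvals <- unlist(lapply(1:5, function(s) {
    cfg <- small_config(700 + s, drift_amplitude = 0, effect_nash_up = 0,
                        effect_hcc_up = 0, effect_nash_down = 0,
                        effect_hcc_down = 0, n_control = 15, n_nash = 15,
                        n_hcc = 4)
    sim <- simulate_cohort(cfg)
    adjusted_fold_change(sim$raw[, sim$layout$sample_id[!sim$layout$is_reference]],
                         sim$sheet, c("control", "NASH"))$p_value
  }))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("BH q-values reproduce hand-executed and degenerate cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("BH equals the brute-force step-up oracle and p.adjust on random vectors", {
  set.seed(11)
  for (i in 1:200) {
    p <- round(runif(sample(1:12, 1)), 3)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("cascade set logic matches exhaustive enumeration on a toy table", {
  mk_diff <- function(p, contrast) {
    d <- data.frame(marker_id = paste0("m", seq_along(p)),
                    fold_change = 1, log2fc = 0, se = 1, p_value = p,
                    q_value = bh_fdr(p), stringsAsFactors = FALSE)
    attr(d, "contrast") <- contrast
    class(d) <- c("glyco_diff", "data.frame")
    d
  }
  manifest <- data.frame(marker_id = paste0("m", 1:3),
                         protein = c("A", "A", "B"), sites = "1",
                         glycan_code = c("5402", "5401", ""),
                         is_peptide = c(FALSE, FALSE, TRUE))
  p1 <- c(0.001, 0.20, 0.010)   # q = 0.003, 0.200, 0.015
  p2 <- c(0.002, 0.030, 0.90)   # q = 0.006, 0.045, 0.900
  res <- list(control_vs_NASH = mk_diff(p1, c("control", "NASH")),
              control_vs_HCC = mk_diff(p2, c("control", "HCC")))
  casc <- significance_cascade(res, manifest, unidirectional = c("m1", "m3"))
  expect_setequal(casc$sets$control_vs_NASH$p, c("m1", "m3"))
  expect_setequal(casc$sets$control_vs_HCC$fdr, c("m1", "m2"))
  expect_setequal(casc$shared_fdr, "m1")
  expect_equal(casc$unidirectional$n_glycopeptides, 1)
  expect_equal(casc$unidirectional$n_peptides, 0)
  expect_equal(casc$unidirectional$proteins, "A")
  # FDR sets nest inside p sets at equal alpha
  for (nm in names(casc$sets)) {
    expect_true(all(casc$sets[[nm]]$fdr %in% casc$sets[[nm]]$p))
  }
})

test_that("empty significant sets and mismatched universes behave as specified", {
  d <- data.frame(marker_id = c("m1", "m2"), fold_change = 1, log2fc = 0,
                  se = 1, p_value = c(0.9, 0.8), q_value = c(0.9, 0.9))
  class(d) <- c("glyco_diff", "data.frame")
  manifest <- data.frame(marker_id = c("m1", "m2"), protein = "A",
                         sites = "1", glycan_code = "5402",
                         is_peptide = FALSE)
  casc <- significance_cascade(list(control_vs_NASH = d, control_vs_HCC = d),
                               manifest)
  expect_length(casc$shared_fdr, 0)
  expect_equal(casc$counts$control_vs_NASH$p, 0)

  d2 <- d; d2$marker_id <- c("m1", "mX")
  expect_error(significance_cascade(list(control_vs_NASH = d,
                                         control_vs_HCC = d2), manifest),
               "universes differ")
})

test_that("strict monotonicity predicate and screen toy cases", {
  expect_true(unidirectional(c(1, 2, 3)))
  expect_true(unidirectional(c(3, 2, 1)))
  expect_false(unidirectional(c(1, 3, 2)))
  expect_false(unidirectional(c(1, 1, 2)))  # tie fails

  # crafted cohort: m_up strictly increasing, m_nm non-monotone
  set.seed(2)
  phen <- rep(c("control", "NASH", "HCC"), each = 12)
  sheet <- mk_sheet(phen, age = round(runif(36, 40, 70)),
                    sex = sample(c("M", "F"), 36, replace = TRUE))
  shift_up <- c(control = 0, NASH = 1, HCC = 2)[phen]
  shift_nm <- c(control = 0, NASH = 1.5, HCC = 0.8)[phen]
  x <- rbind(m_up = 2^(10 + shift_up + rnorm(36, 0, 0.1)),
             m_nm = 2^(10 + shift_nm + rnorm(36, 0, 0.1)))
  colnames(x) <- sheet$sample_id
  scr <- progression_screen(x, sheet)
  expect_true(scr$passes[scr$marker_id == "m_up"])
  expect_false(scr$passes[scr$marker_id == "m_nm"])
  expect_true(scr$monotone[scr$marker_id == "m_up"])
  expect_false(scr$monotone[scr$marker_id == "m_nm"])
})

test_that("the screen errors when a phenotype group is missing", {
  sheet <- mk_sheet(rep(c("control", "NASH"), each = 6))
  x <- matrix(2^rnorm(12, 10), 1, dimnames = list("m1", sheet$sample_id))
  expect_error(progression_screen(x, sheet), "missing phenotype")
})
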