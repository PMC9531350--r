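rt_top <- function(entries_pct, estimates, metric = "OR") {
  tibble::tibble(
    threshold_kind = "top_pct_vs_rest",
    top_pct = entries_pct,
    estimate = estimates,
    ci_low = estimates * 0.9,
    ci_high = estimates * 1.1,
    metric_type = metric
  )
}

rt_per_sd <- function(estimate = 2.29, metric = "OR") {
  tibble::tibble(threshold_kind = "per_sd", top_pct = NA_real_,
                 estimate = estimate, ci_low = estimate * 0.8,
                 ci_high = estimate * 1.2, metric_type = metric)
}

test_that("top-tail translation assigns the published metric at the threshold", {
  crc <- tibble::tibble(threshold_kind = "top_pct_vs_rest", top_pct = 25,
                        estimate = 2.69, ci_low = 2.34, ci_high = 3.08,
                        metric_type = "OR")
  r <- translate_risk(97.42, risk_table = crc)
  expect_true(r$assigned)
  expect_equal(r$estimate, 2.69)
  expect_equal(r$threshold_used, "top_25pct_vs_rest")
})

test_that("a percentile below every threshold yields a blank assignment", {
  r <- translate_risk(17.30, risk_table = rt_top(c(20, 10, 5), c(2, 3, 4)))
  expect_false(r$assigned)
  expect_true(is.na(r$estimate))
})

test_that("the deepest containing tail wins when thresholds overlap", {
  glaucoma <- rt_top(c(20, 50), c(3.61, 2.94))
  r <- translate_risk(88.67, risk_table = glaucoma)
  expect_equal(r$estimate, 3.61)   # within top 20 and top 50: top 20 is deeper
  r <- translate_risk(65.01, risk_table = glaucoma)
  expect_equal(r$estimate, 2.94)   # only within top 50
  cad <- rt_top(c(20, 5), c(2.55, 3.34))
  expect_equal(translate_risk(96.62, risk_table = cad)$estimate, 3.34)
  expect_equal(translate_risk(89.86, risk_table = cad)$estimate, 2.55)
})

test_that("per-SD entries trigger on z > 1 only", {
  expect_true(translate_risk(92, z = 1.5, risk_table = rt_per_sd())$assigned)
  expect_false(translate_risk(92, z = 0.9, risk_table = rt_per_sd())$assigned)
  expect_false(translate_risk(92, z = NA_real_, risk_table = rt_per_sd())$assigned)
})

test_that("sex applicability flags but does not suppress the metric", {
  r <- translate_risk(92, risk_table = rt_top(10, 3.69),
                      sex = "female", sex_applicability = "male_only")
  expect_true(r$assigned)
  expect_false(r$expressible)
  r <- translate_risk(92, risk_table = rt_top(10, 3.69),
                      sex = "male", sex_applicability = "male_only")
  expect_true(r$expressible)
})

test_that("assignment is monotone: raising the percentile never loses a top-tail metric", {
  tbl <- rt_top(c(20, 10, 5, 1), c(2, 3, 4, 5))
  assigned <- vapply(seq(0, 100, by = 0.5), function(p) {
    translate_risk(p, risk_table = tbl)$assigned
  }, logical(1))
  expect_true(all(diff(assigned) >= 0))
})

test_that("mid-parent patterns match the documented family examples", {
  r <- midparent_analysis(17.30, 85.69, 53.28)
  expect_equal(r$midparent, 51.495)
  expect_equal(r$pattern, "averaging")
  r <- midparent_analysis(29.62, 96.62, 89.86)
  expect_equal(r$midparent, 63.12)
  expect_equal(round(r$delta, 2), 26.74)
  expect_equal(r$pattern, "divergent_high")
  expect_equal(midparent_analysis(40, 60, 50)$pattern, "averaging")
  expect_equal(midparent_analysis(80, 80, 30)$pattern, "divergent_low")
})

test_that("mid-parent analysis is symmetric in the parents", {
  set.seed(61)
  for (i in 1:50) {
    f <- runif(1, 0, 100); m <- runif(1, 0, 100); c <- runif(1, 0, 100)
    expect_identical(midparent_analysis(f, m, c), midparent_analysis(m, f, c))
  }
})

test_that("family report composes percentiles, bands and patterns per phenotype", {
  ped <- read_pedigree(system.file("extdata", "pedigree.tsv", package = "prspipe"))
  expect_equal(sort(ped$role), c("child", "child", "father", "mother"))

  # transcription of a four-member colorectal-style row: three above 80, one not
  asg <- tibble::tibble(
    sample_id = rep(c("FATHER", "MOTHER", "DAUGHTER", "SON"), 2),
    phenotype_id = rep(c("Colorectal cancer", "Breast cancer"), each = 4),
    percentile = c(97.42, 79.92, 97.22, 91.05,
                   17.30, 85.69, 53.28, 64.61)
  )
  fam <- family_report(asg, ped)
  expect_equal(nrow(fam), 4)  # 2 phenotypes x 2 children
  crc <- fam[fam$phenotype_id == "Colorectal cancer", ]
  expect_equal(unique(crc$father_band), "top5")
  expect_equal(unique(crc$mother_band), "mid")   # 79.92 is NOT high
  expect_equal(crc$child_band[crc$child_id == "DAUGHTER"], "top5")
  expect_equal(crc$child_band[crc$child_id == "SON"], "high")
  bca <- fam[fam$phenotype_id == "Breast cancer" & fam$child_id == "DAUGHTER", ]
  expect_equal(bca$pattern, "averaging")

  # empty input produces an empty report with the same shape
  empty <- family_report(asg[0, ], ped)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("phenotype_id", "pattern") %in% names(empty)))
})

test_that("incomplete trios warn and leave partial rows", {
  ped <- read_pedigree(system.file("extdata", "pedigree.tsv", package = "prspipe"))
  asg <- tibble::tibble(
    sample_id = c("FATHER", "DAUGHTER", "SON"),
    phenotype_id = "ph",
    percentile = c(50, 60, 70)
  )
  w <- capture_warnings(fam <- family_report(asg, ped))
  expect_length(w, 2)   # one warning per incomplete child row
  expect_match(w, "incomplete", all = TRUE)
  expect_true(all(is.na(fam$pattern)))
  expect_equal(fam$father_percentile, c(50, 50))
})

test_that("risk_report joins metadata risk tables and sexes", {
  meta <- catalogue_meta()
  asg <- tibble::tibble(
    sample_id = c("MOTHER", "MOTHER"),
    phenotype_id = c("Colorectal cancer", "Prostate cancer"),
    percentile = c(79.92, 80.91),
    z_score = c(0.8, 1.3)
  )
  rr <- risk_report(asg, meta, sexes = c(MOTHER = "female"))
  crc <- rr[rr$phenotype_id == "Colorectal cancer", ]
  expect_true(crc$assigned)          # 79.92 is inside the top 25% tail
  expect_equal(crc$estimate, 2.69)
  pca <- rr[rr$phenotype_id == "Prostate cancer", ]
  expect_true(pca$assigned)          # per-SD with z > 1
  expect_equal(pca$estimate, 2.29)
  expect_false(pca$expressible)      # male-only phenotype, female sample
})
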