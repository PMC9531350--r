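test_that("design criteria reproduce the catalogued filtering decisions", {
  meta <- catalogue_meta()
  cfg <- catalogue_curation_config()
  d <- apply_design_criteria(meta, cfg)

  pick <- function(ph, src = NULL) {
    i <- d$phenotype == ph
    if (!is.null(src)) i <- i & d$source_id == src
    d[i, ]
  }
  # below-threshold AUC
  expect_equal(pick("Pancreatic cancer")$status, "unselected")
  expect_equal(pick("Pancreatic cancer")$reasons[[1]], "performance_below_threshold")
  # unavailable performance
  expect_equal(pick("Venous thromboembolism")$status, "unselected")
  expect_equal(pick("Venous thromboembolism")$reasons[[1]], "performance_unavailable")
  # exception list admits a below-threshold C-index
  expect_equal(pick("Ischaemic stroke")$status, "selected")
  expect_length(pick("Ischaemic stroke")$reasons[[1]], 0)
  # untraceable GWAS (these composite scores also report no usable metric)
  expect_true("not_traceable_gwas" %in%
                pick("All cause mortality (female)")$reasons[[1]])
  expect_equal(pick("All cause mortality (female)")$status, "unselected")
  # R2 metrics use their own threshold
  expect_equal(pick("Body mass index")$status, "unselected")
  expect_equal(pick("Testosterone levels (male)")$status, "selected")
})

test_that("a clean high-performing entry is selected with no reasons", {
  meta <- tibble::tibble(
    phenotype = "Ideal", group = "cancer", source_id = "S1",
    gwas_traceable = TRUE, trained_with_published_method = TRUE,
    large_validation = TRUE, validation_cohort = "UKB",
    performance_type = "AUC", performance_value = 0.99,
    n_snps = 100, sex_applicability = "any", risk_table = list(NULL)
  )
  d <- apply_design_criteria(meta)
  expect_equal(d$status, "selected")
  expect_length(d$reasons[[1]], 0)
})

test_that("duplicate resolution keeps the best entry by default and honours overrides", {
  meta <- catalogue_meta()
  cfg <- catalogue_curation_config()
  d <- curate_phenotypes(meta, cfg)

  # default rule: highest performance wins (C-index 0.86 over AUC 0.71)
  prost <- d[d$phenotype == "Prostate cancer", ]
  expect_equal(prost$status[prost$source_id == "PGS000333"], "selected")
  expect_equal(prost$reasons[[which(prost$source_id == "PRSWEB_185")]],
               "lower_performance_duplicate")

  # override: UKB entry wins despite lower performance, recording judgement
  breast <- d[d$phenotype == "Breast cancer", ]
  expect_equal(breast$status[breast$source_id == "PGS000015"], "selected")
  expect_equal(breast$reasons[[which(breast$source_id == "PGS000015")]],
               "judgement_override")
  expect_equal(breast$reasons[[which(breast$source_id == "PGS000332")]],
               "validation_not_preferred_cohort")
  expect_equal(breast$reasons[[which(breast$source_id == "PRSWEB_174.1")]],
               "lower_performance_duplicate")

  # single candidates pass through unchanged
  glau <- d[d$phenotype == "Glaucoma", ]
  expect_equal(glau$status, "selected")
})

test_that("curation counts over the 43-entry catalogue are 25 discarded / 18 selected", {
  d <- curate_phenotypes(catalogue_meta(), catalogue_curation_config())
  s <- curation_summary(d)
  expect_equal(s$n_candidates, 43)
  expect_equal(s$n_discarded_design, 25)
  expect_equal(s$n_selected_design, 18)
  # conservation: every candidate in exactly one bucket
  expect_equal(s$n_candidates, s$n_discarded_design + s$n_selected_design)
})

test_that("decision invariants hold: unselected entries carry reasons, selected at most a judgement", {
  d <- curate_phenotypes(catalogue_meta(), catalogue_curation_config())
  unsel <- d[d$status == "unselected", ]
  expect_true(all(lengths(unsel$reasons) > 0))
  sel <- d[d$status == "selected", ]
  ok <- vapply(sel$reasons, function(r) {
    length(r) == 0 || identical(r, "judgement_override")
  }, logical(1))
  expect_true(all(ok))
})

test_that("curation is deterministic and monotone in the performance threshold", {
  meta <- catalogue_meta()
  cfg <- catalogue_curation_config()
  expect_identical(curate_phenotypes(meta, cfg), curate_phenotypes(meta, cfg))

  # raising the threshold never converts an unselected phenotype to selected
  # (entries may swap within a phenotype when a duplicate winner drops out)
  selected_phenos <- function(config) {
    d <- curate_phenotypes(meta, config)
    unique(d$phenotype[d$status == "selected"])
  }
  for (th in c(0.65, 0.72, 0.80)) {
    hi <- cfg
    hi$performance_threshold <- th
    expect_true(all(selected_phenos(hi) %in% selected_phenos(cfg)))
  }
})

test_that("the bioinformatic gate leaves 15 of the 18 design survivors", {
  acc <- accounting_table()
  gated <- apply_bioinformatic_gate(acc)
  expect_equal(nrow(gated), 18)
  expect_equal(sum(gated$pass_gate), 15)
  expect_equal(gated$gate_reason[gated$phenotype == "Lupus"],
               "missing_snps_above_5pct")
  expect_equal(
    gated$gate_reason[gated$phenotype == "Testosterone levels (male)"],
    "contains_xy_variants"
  )
})

test_that("subset summaries count over the subset only", {
  d <- curate_phenotypes(catalogue_meta(), catalogue_curation_config())
  meta <- catalogue_meta()
  cancer <- d[meta$group == "cancer", ]
  s <- curation_summary(cancer)
  expect_equal(s$n_candidates, nrow(cancer))
  all_sel <- d[d$status == "selected", ]
  expect_equal(curation_summary(all_sel)$n_discarded_design, 0)
})
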