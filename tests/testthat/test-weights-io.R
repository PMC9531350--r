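test_that("a small scoring file parses into the expected weighted variants", {
  path <- system.file("extdata", "example_scoring.tsv", package = "prspipe")
  sf <- read_scoring_file(path)
  expect_s3_class(sf, "prs_scoring_file")
  expect_equal(sf$n_variants, 3)
  expect_equal(sf$variants$effect_weight, c(0.1, -0.2, 0.3))
  expect_equal(sf$variants$chrom, c("1", "1", "2"))
  expect_equal(sf$variants$pos, c(100L, 200L, 50L))
  expect_equal(sf$variants$effect_allele, c("A", "C", "G"))
  expect_equal(sf$source_id, "EXAMPLE001")
  expect_equal(nrow(sf$diagnostics), 0)
})

test_that("comma-separated files and alias headers parse equivalently", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "rsID,chromosome,position,risk_allele,reference_allele,beta",
    "rs1,1,100,A,G,0.1",
    "rs2,1,200,C,T,-0.2"
  ), path)
  sf <- read_scoring_file(path, phenotype_id = "csv_fixture")
  expect_equal(sf$n_variants, 2)
  expect_equal(sf$variants$effect_weight, c(0.1, -0.2))
  expect_equal(sf$variants$other_allele, c("G", "T"))
})

test_that("writing then re-reading a scoring file round-trips variants and M", {
  sf <- fix_scoring(weights = c(0.15, -0.02, 0.3, 1.25),
                    effect = c("A", "C", "G", "T"),
                    other = c("G", "T", "A", "C"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scoring_file(sf, path)
  back <- read_scoring_file(path, phenotype_id = sf$phenotype_id)
  expect_equal(back$n_variants, sf$n_variants)
  expect_equal(tidy(back), tidy(sf))
})

test_that("malformed rows are rejected with row-numbered diagnostics, never dropped silently", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
    "rs1\t1\t100\tA\t0.1",
    "rs2\t1\t200\tN\t0.2",     # malformed allele
    "rs3\t1\t300\tC\tnot_a_number",
    "rs4\t1\t400\tG\t0.4"
  ), path)
  sf <- read_scoring_file(path, phenotype_id = "diag")
  expect_equal(sf$n_variants, 2)
  expect_equal(sf$diagnostics$row, c(2L, 3L))
  # conservation: rows in = kept + diagnosed
  expect_equal(4, sf$n_variants + nrow(sf$diagnostics))
})

test_that("structural errors are raised for bad files", {
  header_only <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
             header_only)
  expect_error(read_scoring_file(header_only), class = "prspipe_empty_error")

  wrong_build <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "#genome_build=GRCh38",
    "rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
    "rs1\t1\t100\tA\t0.1"
  ), wrong_build)
  expect_error(read_scoring_file(wrong_build), class = "prspipe_build_error")

  no_col <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsID\tchr_name\tchr_position\teffect_allele",
               "rs1\t1\t100\tA"), no_col)
  expect_error(read_scoring_file(no_col), class = "prspipe_format_error")
})

test_that("X/Y variants are parsed but flagged; duplicates split by effect allele are kept", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rsID\tchr_name\tchr_position\teffect_allele\teffect_weight",
    "rs1\tchrX\t100\tA\t0.1",
    "rs2\t1\t200\tC\t0.2",
    "rs3\t1\t200\tT\t0.3"      # same site, different effect allele: legal
  ), path)
  sf <- read_scoring_file(path, phenotype_id = "xy")
  expect_equal(sf$variants$sex_chrom, c(TRUE, FALSE, FALSE))
  expect_equal(sf$variants$chrom[1], "X")
  expect_equal(sf$n_variants, 3)
})

test_that("identical duplicate triples are an error", {
  expect_error(
    fix_scoring(weights = c(0.1, 0.2), pos = c(100, 100)),
    class = "prspipe_format_error"
  )
})

test_that("phenotype metadata parses with enumerations and risk tables validated", {
  meta <- catalogue_meta()
  expect_equal(nrow(meta), 43)
  pc <- meta[meta$phenotype == "Pancreatic cancer", ]
  expect_equal(pc$performance_value, 0.58)
  expect_equal(pc$performance_type, "AUC")
  # default sex applicability
  expect_equal(meta$sex_applicability[meta$phenotype == "Glaucoma"], "any")
  # risk table parsed as list-column tibble
  crc <- meta$risk_table[meta$phenotype == "Colorectal cancer"][[1]]
  expect_equal(crc$estimate, 2.69)
  expect_equal(crc$top_pct, 25)
})

test_that("inconsistent performance metadata is rejected", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "phenotypes:",
    "  - phenotype: Broken",
    "    performance_type: unavailable",
    "    performance_value: 0.7"
  ), path)
  expect_error(read_phenotype_meta(path), class = "prspipe_config_error")

  dup <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "phenotypes:",
    "  - phenotype: Dup",
    "    source_id: S1",
    "    performance_type: AUC",
    "    performance_value: 0.7",
    "  - phenotype: Dup",
    "    source_id: S1",
    "    performance_type: AUC",
    "    performance_value: 0.8"
  ), dup)
  expect_error(read_phenotype_meta(dup), class = "prspipe_config_error")
})

test_that("unknown metadata fields warn but do not fail", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "phenotypes:",
    "  - phenotype: Oddball",
    "    performance_type: AUC",
    "    performance_value: 0.7",
    "    made_up_field: 42"
  ), path)
  expect_warning(meta <- read_phenotype_meta(path), "made_up_field")
  expect_equal(meta$sex_applicability, "any")
})
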