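#' Read reference-panel variant sites from a VCF
#'
#' Only the site annotation (CHROM, POS, REF, ALT) is needed for allele
#' matching, so a sites-only VCF is sufficient. Chromosome labels are
#' normalised by stripping any `chr` prefix.
#'
#' @param path VCF path (plain or gzipped).
#' @return panel tibble with columns `chrom`, `pos`, `ref`, `alts`
#'   (comma-separated alternate alleles).
#' @export
read_panel_vcf <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("panel VCF not found: ", path), class = "prspipe_path_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  panel_from_fix(v@fix)
}

panel_from_fix <- function(fix) {
  tibble(
    chrom = norm_chrom(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = toupper(fix[, "REF"]),
    alts = toupper(fix[, "ALT"])
  )
}

#' Match scoring-file variants against a reference panel
#'
#' Pure positional + string-equality matching: a variant's effect allele must
#' equal the panel REF (`matched_ref`) or one of the panel ALTs
#' (`matched_alt`) at the same (chrom, pos). A site absent from the panel is
#' `missing_absent`; an allele found at neither REF nor ALT is
#' `missing_allele_mismatch`. No strand flipping or reverse-complement rescue
#' is attempted — a mismatch is taken as evidence of a strand or annotation
#' inconsistency and the variant is dropped from scoring.
#'
#' @param variants tibble of weighted variants (columns `chrom`, `pos`,
#'   `effect_allele`, ...).
#' @param panel panel tibble from [read_panel_vcf()].
#' @return `variants` with added columns `status`, `panel_ref`, `panel_alts`.
#' @export
match_variants <- function(variants, panel) {
  panel <- panel |> mutate(.key = site_key(.data$chrom, .data$pos))
  if (anyDuplicated(panel$.key) > 0) {
    panel <- panel |> distinct(.data$.key, .keep_all = TRUE)
  }
  v <- variants |> mutate(.key = site_key(.data$chrom, .data$pos))
  idx <- match(v$.key, panel$.key)
  panel_ref <- panel$ref[idx]
  panel_alts <- panel$alts[idx]
  in_alts <- !is.na(panel_alts) & stringr::str_detect(
    paste0(",", panel_alts, ","),
    stringr::fixed(paste0(",", v$effect_allele, ","))
  )
  v |>
    mutate(
      status = case_when(
        is.na(idx) ~ "missing_absent",
        .data$effect_allele == panel_ref ~ "matched_ref",
        in_alts ~ "matched_alt",
        TRUE ~ "missing_allele_mismatch"
      ),
      panel_ref = panel_ref,
      panel_alts = panel_alts
    ) |>
    select(-".key")
}

#' Match a single weighted variant (scalar convenience)
#'
#' @param wv one-row tibble (or list) with `chrom`, `pos`, `effect_allele`.
#' @param panel panel tibble.
#' @return one of `"matched_ref"`, `"matched_alt"`, `"missing_absent"`,
#'   `"missing_allele_mismatch"`.
#' @export
match_variant <- function(wv, panel) {
  match_variants(as_tibble(wv[c("chrom", "pos", "effect_allele")]), panel)$status
}

#' Harmonise a scoring file against a reference panel
#'
#' Assigns every reported variant a match status, counts retained vs missing
#' variants, and applies the retention gate: the phenotype is usable only if
#' at least 95% of its reported variants are present in the panel with a
#' consistent allele (missingness at most 5.00% after half-up rounding to two
#' decimals).
#'
#' @param sf a `prs_scoring_file`.
#' @param panel panel tibble from [read_panel_vcf()].
#' @param max_missing_pct gate threshold in percent (default 5).
#' @return a `prs_harmonization`: per-variant tibble plus counts,
#'   `missing_pct` and `pass_gate`.
#' @export
harmonize_phenotype <- function(sf, panel, max_missing_pct = 5) {
  stopifnot(inherits(sf, "prs_scoring_file"), sf$n_variants > 0)
  matched <- match_variants(sf$variants, panel)
  n_total <- nrow(matched)
  retained <- startsWith(matched$status, "matched")
  n_retained <- sum(retained)
  n_missing <- n_total - n_retained
  missing_pct <- round_half_up(100 * n_missing / n_total, 2)
  structure(
    list(
      phenotype_id = sf$phenotype_id,
      source_id = sf$source_id,
      variants = matched,
      n_total = n_total,
      n_retained = n_retained,
      n_missing = n_missing,
      missing_pct = missing_pct,
      pass_gate = missing_pct <= max_missing_pct
    ),
    class = "prs_harmonization"
  )
}

#' @exportS3Method base::print
print.prs_harmonization <- function(x, ...) {
  cat("<prs_harmonization> ", x$phenotype_id, "\n", sep = "")
  cat("  reported: ", x$n_total, "; retained: ", x$n_retained,
      "; missing: ", x$n_missing, " (", format(x$missing_pct, nsmall = 2),
      "%); gate: ", if (x$pass_gate) "pass" else "FAIL", "\n", sep = "")
  invisible(x)
}

#' Per-variant harmonisation statuses
#'
#' @param x a `prs_harmonization`.
#' @param ... unused.
#' @return tibble of variants with match status and panel alleles.
#' @export
tidy.prs_harmonization <- function(x, ...) x$variants

#' One-row harmonisation summary
#'
#' @param x a `prs_harmonization`.
#' @param ... unused.
#' @return tibble with counts, missing percentage and gate outcome.
#' @export
glance.prs_harmonization <- function(x, ...) {
  tibble(
    phenotype_id = x$phenotype_id,
    n_total = x$n_total,
    n_retained = x$n_retained,
    n_missing = x$n_missing,
    missing_pct = x$missing_pct,
    pass_gate = x$pass_gate
  )
}

#' Retained variants of a harmonisation
#'
#' @param h a `prs_harmonization`.
#' @return tibble of variants with status `matched_ref` or `matched_alt`,
#'   in scoring-file order.
#' @export
retained_variants <- function(h) {
  stopifnot(inherits(h, "prs_harmonization"))
  h$variants |> filter(startsWith(.data$status, "matched"))
}

#' Write a harmonisation report for several phenotypes
#'
#' TSV with one row per phenotype: number of reported SNPs, missing count,
#' missing percentage and gate status.
#'
#' @param harmonizations list of `prs_harmonization` objects.
#' @param path output path.
#' @return the report tibble, invisibly.
#' @export
write_harmonization_report <- function(harmonizations, path) {
  report <- purrr::map(harmonizations, glance) |> bind_rows() |>
    mutate(status = if_else(.data$pass_gate, "Selected", "Unselected"))
  readr::write_tsv(report, path)
  invisible(report)
}
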