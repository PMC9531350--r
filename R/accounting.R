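#' Read a harmonisation accounting table
#'
#' TSV with one row per design-surviving phenotype: reported SNP count,
#' missing count and/or missing percentage, and whether the score contains
#' X/Y-chromosome variants. Where both a count and a percentage are present
#' the percentage is recomputed from the counts and must agree with the
#' stored value at two decimals (half-up), guarding transcription errors.
#'
#' @param path TSV path; defaults to the accounting table shipped with the
#'   package.
#' @return tibble with `phenotype`, `source_id`, `n_snps`, `n_missing`,
#'   `missing_pct`, `contains_xy`.
#' @export
read_harmonization_accounting <- function(
    path = system.file("extdata", "harmonization_accounting.tsv",
                       package = "prspipe")) {
  acc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         na = "NA")
  stopifnot(all(c("phenotype", "n_snps", "missing_pct") %in% names(acc)))
  both <- !is.na(acc$n_missing) & !is.na(acc$missing_pct)
  if (any(both)) {
    recomputed <- round_half_up(100 * acc$n_missing[both] / acc$n_snps[both], 2)
    if (any(abs(recomputed - acc$missing_pct[both]) > 1e-9)) {
      abort("missing_pct disagrees with n_missing/n_snps",
            class = "prspipe_format_error")
    }
  }
  acc |>
    mutate(missing_pct = if_else(is.na(.data$missing_pct) & !is.na(.data$n_missing),
                                 round_half_up(100 * .data$n_missing / .data$n_snps, 2),
                                 .data$missing_pct))
}

#' SNP accounting over gate-passing phenotypes
#'
#' Applies the bioinformatic gate to an accounting table and sums reported
#' SNP counts over the passing phenotypes: the grand total, the subtotal of
#' small scores (fewer than `small_threshold` SNPs), the complementary
#' subtotal of genome-wide scores, and the total missing count.
#'
#' @param accounting tibble from [read_harmonization_accounting()].
#' @param small_threshold boundary between "small" and genome-wide scores
#'   (default 10,000 SNPs).
#' @param max_missing_pct gate threshold in percent.
#' @return one-row tibble: `n_phenotypes`, `n_pass_gate`, `total_snps`,
#'   `small_subtotal`, `large_subtotal`, `n_small`, `n_large`,
#'   `total_missing`.
#' @export
snp_accounting <- function(accounting, small_threshold = 10000,
                           max_missing_pct = 5) {
  gated <- apply_bioinformatic_gate(accounting, max_missing_pct)
  pass <- gated |> filter(.data$pass_gate)
  small <- pass$n_snps < small_threshold
  tibble(
    n_phenotypes = nrow(gated),
    n_pass_gate = nrow(pass),
    total_snps = sum(pass$n_snps),
    small_subtotal = sum(pass$n_snps[small]),
    large_subtotal = sum(pass$n_snps[!small]),
    n_small = sum(small),
    n_large = sum(!small),
    total_missing = sum(pass$n_missing, na.rm = TRUE)
  )
}
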