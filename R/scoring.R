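#' Compute a raw polygenic risk score
#'
#' The raw score is the dosage-weighted sum of effect weights over the
#' retained variants, divided by the total number of variants reported for
#' the phenotype: `sum(weight * dosage) / M`. Variants lost at harmonisation
#' contribute 0 to the numerator but remain in the denominator, so
#' missingness shrinks scores slightly rather than renormalising them. The
#' denominator convention is configurable.
#'
#' @param dosages integer vector of effect-allele dosages (0/1/2), aligned
#'   1:1 with `weights`, or a tibble from [extract_dosages()] carrying a
#'   `dosage` column.
#' @param weights numeric vector of per-allele effect weights for the
#'   retained variants (ignored if `dosages` is an [extract_dosages()] tibble
#'   with an `effect_weight` column).
#' @param M total number of variants reported for the phenotype
#'   (pre-harmonisation).
#' @param sample_id,phenotype_id identifiers carried into the result.
#' @param denominator `"reported_M"` (default), `"retained_M"` or
#'   `"two_reported_M"`.
#' @return one-row tibble: `sample_id`, `phenotype_id`, `raw_score`,
#'   `n_variants_used`, `n_missing`, `M`.
#' @export
compute_prs <- function(dosages, weights = NULL, M,
                        sample_id = NA_character_,
                        phenotype_id = NA_character_,
                        denominator = c("reported_M", "retained_M",
                                        "two_reported_M")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(dosages)) {
    if (is.null(weights) && "effect_weight" %in% names(dosages)) {
      weights <- dosages$effect_weight
    }
    dosages <- dosages$dosage
  }
  if (length(dosages) != length(weights)) {
    abort("dosages and weights are not aligned", class = "prspipe_alignment_error")
  }
  if (M < 1) {
    abort("M must be at least 1 (no reported variants: score undefined)",
          class = "prspipe_undefined_score_error")
  }
  stopifnot(all(dosages %in% 0:2), all(is.finite(weights)), length(dosages) <= M)
  denom <- switch(denominator,
    reported_M = M,
    retained_M = max(length(dosages), 1L),
    two_reported_M = 2 * M
  )
  tibble(
    sample_id = sample_id,
    phenotype_id = phenotype_id,
    raw_score = sum(weights * dosages) / denom,
    n_variants_used = length(dosages),
    n_missing = as.integer(M - length(dosages)),
    M = as.integer(M)
  )
}

#' Score every sample of a cohort for one phenotype
#'
#' One pass over a dosage matrix; equivalent to calling [compute_prs()] per
#' sample.
#'
#' @param genotypes a `prs_genotypes` holding the cohort.
#' @param harmonized a `prs_harmonization` for the phenotype.
#' @param samples sample IDs to score (default all).
#' @param denominator see [compute_prs()].
#' @return tibble with one row per sample (same columns as [compute_prs()]).
#' @export
score_cohort <- function(genotypes, harmonized,
                         samples = genotypes$samples,
                         denominator = "reported_M") {
  dm <- dosage_matrix(genotypes, harmonized, samples = samples)
  w <- retained_variants(harmonized)$effect_weight
  M <- harmonized$n_total
  denom <- switch(denominator,
    reported_M = M,
    retained_M = max(length(w), 1L),
    two_reported_M = 2 * M,
    abort("unknown denominator mode")
  )
  raw <- as.numeric(crossprod(w, dm$dosage)) / denom
  tibble(
    sample_id = samples,
    phenotype_id = harmonized$phenotype_id,
    raw_score = raw,
    n_variants_used = length(w),
    n_missing = harmonized$n_missing,
    M = M
  )
}

#' Write a score table
#'
#' @param scores score tibble from [compute_prs()]/[score_cohort()] rows.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  readr::write_tsv(scores, path)
  invisible(path)
}
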