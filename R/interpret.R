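#' Translate a percentile placement into a published risk metric
#'
#' A percentile is matched against the published threshold entries for the
#' phenotype. For top-tail entries (`top_pct_vs_rest`) the individual is
#' eligible for every tail containing them (`percentile >= 100 - top_pct`),
#' and the deepest such tail (smallest `top_pct`) supplies the metric. For
#' per-standard-deviation entries the metric applies when the individual's
#' z-score exceeds 1. A percentile below every threshold yields no
#' assignment (a blank cell). Risk metrics are carried through verbatim —
#' they are published inputs, never recomputed. A phenotype whose sex
#' applicability excludes the individual still gets its metric computed but
#' is flagged not expressible.
#'
#' @param percentile the individual's percentile in the chosen background.
#' @param z the individual's z-score in the same background (used for
#'   `per_sd` entries; may be `NA` if the table has none).
#' @param risk_table tibble of risk entries (`threshold_kind`, `top_pct`,
#'   `estimate`, `ci_low`, `ci_high`, `metric_type`) as parsed by
#'   [read_phenotype_meta()], or `NULL`.
#' @param sex `"male"` or `"female"` (or `NA`).
#' @param sex_applicability `"any"`, `"female_only"` or `"male_only"`.
#' @return one-row tibble: `assigned`, `metric_type`, `estimate`, `ci_low`,
#'   `ci_high`, `threshold_used`, `expressible`, `z_score`.
#' @export
translate_risk <- function(percentile, z = NA_real_, risk_table = NULL,
                           sex = NA_character_, sex_applicability = "any") {
  stopifnot(percentile >= 0, percentile <= 100)
  expressible <- !(
    (sex_applicability == "female_only" && identical(sex, "male")) ||
    (sex_applicability == "male_only" && identical(sex, "female"))
  )
  blank <- tibble(
    assigned = FALSE, metric_type = NA_character_, estimate = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, threshold_used = NA_character_,
    expressible = expressible, z_score = z
  )
  if (is.null(risk_table) || nrow(risk_table) == 0) return(blank)

  top <- risk_table |>
    filter(.data$threshold_kind == "top_pct_vs_rest",
           percentile >= 100 - .data$top_pct)
  if (nrow(top) > 0) {
    hit <- top |> arrange(.data$top_pct) |> dplyr::slice(1)
    return(tibble(
      assigned = TRUE, metric_type = hit$metric_type,
      estimate = hit$estimate, ci_low = hit$ci_low, ci_high = hit$ci_high,
      threshold_used = paste0("top_", hit$top_pct, "pct_vs_rest"),
      expressible = expressible, z_score = z
    ))
  }
  per_sd <- risk_table |> filter(.data$threshold_kind == "per_sd")
  if (nrow(per_sd) > 0 && isTRUE(z > 1)) {
    hit <- per_sd |> dplyr::slice(1)
    return(tibble(
      assigned = TRUE, metric_type = hit$metric_type,
      estimate = hit$estimate, ci_low = hit$ci_low, ci_high = hit$ci_high,
      threshold_used = "per_sd_gt_1",
      expressible = expressible, z_score = z
    ))
  }
  blank
}

#' Mid-parent analysis of a child's percentile
#'
#' Under additive transmission the expected offspring value is the mid-parent
#' value, the average of the two parents. A child within `tolerance`
#' percentile points of the mid-parent is classed `averaging`; otherwise
#' `divergent_high`/`divergent_low` by the sign of the departure.
#'
#' @param father,mother,child percentiles in `[0, 100]` (vectorised).
#' @param tolerance allowed departure in percentile points (default 20,
#'   matching the quintile granularity used elsewhere).
#' @return tibble: `midparent`, `delta` (child - midparent), `pattern`.
#' @export
midparent_analysis <- function(father, mother, child, tolerance = 20) {
  stopifnot(all(c(father, mother, child) >= 0),
            all(c(father, mother, child) <= 100), tolerance >= 0)
  midparent <- (father + mother) / 2
  delta <- child - midparent
  tibble(
    midparent = midparent,
    delta = delta,
    pattern = case_when(
      abs(delta) <= tolerance ~ "averaging",
      delta > 0 ~ "divergent_high",
      TRUE ~ "divergent_low"
    )
  )
}

#' Read a pedigree file
#'
#' Minimal PED-like TSV: columns `id`, `sex` (`male`/`female`), `father_id`,
#' `mother_id` (0 or empty for founders).
#'
#' @param path TSV path.
#' @return tibble with `id`, `sex`, `father_id`, `mother_id`, `role`
#'   (`father`/`mother`/`child`).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(ped) <- tolower(names(ped))
  stopifnot(all(c("id", "sex", "father_id", "mother_id") %in% names(ped)))
  ped <- ped |>
    mutate(
      father_id = if_else(.data$father_id %in% c("0", "", NA), NA_character_,
                          .data$father_id),
      mother_id = if_else(.data$mother_id %in% c("0", "", NA), NA_character_,
                          .data$mother_id)
    )
  if (any(ped$sex %not_in% c("male", "female"))) {
    abort("pedigree sex must be male/female", class = "prspipe_format_error")
  }
  ped |>
    mutate(role = case_when(
      .data$id %in% ped$father_id ~ "father",
      .data$id %in% ped$mother_id ~ "mother",
      TRUE ~ "child"
    ))
}

#' Family percentile report with bands and inheritance patterns
#'
#' One row per phenotype: each member's percentile (rounded for display) and
#' band, plus the mid-parent pattern for each child.
#'
#' @param assignments percentile assignment tibble (one background) covering
#'   the family members.
#' @param pedigree tibble from [read_pedigree()] describing one trio or quad
#'   (one father, one mother, one or more children).
#' @param tolerance mid-parent tolerance in percentile points.
#' @return tibble with one row per phenotype x child: parent and child
#'   percentiles, bands, `midparent`, `delta`, `pattern`.
#' @export
family_report <- function(assignments, pedigree, tolerance = 20) {
  father <- pedigree$id[pedigree$role == "father"]
  mother <- pedigree$id[pedigree$role == "mother"]
  children <- pedigree$id[pedigree$role == "child"]
  if (length(father) != 1 || length(mother) != 1 || length(children) < 1) {
    abort("pedigree must contain exactly one father, one mother and >= 1 child",
          class = "prspipe_pedigree_error")
  }
  if (nrow(assignments) == 0) {
    return(tibble(
      phenotype_id = character(), child_id = character(),
      father_percentile = numeric(), mother_percentile = numeric(),
      child_percentile = numeric(), father_band = character(),
      mother_band = character(), child_band = character(),
      midparent = numeric(), delta = numeric(), pattern = character()
    ))
  }
  wide <- assignments |>
    select("sample_id", "phenotype_id", "percentile")
  rows <- purrr::map(unique(wide$phenotype_id), function(ph) {
    sub <- wide |> filter(.data$phenotype_id == ph)
    get_p <- function(id) {
      p <- sub$percentile[sub$sample_id == id]
      if (length(p) == 0) NA_real_ else p[[1]]
    }
    fp <- get_p(father); mp <- get_p(mother)
    purrr::map(children, function(ch) {
      cp <- get_p(ch)
      if (anyNA(c(fp, mp, cp))) {
        warn(paste0("incomplete trio percentiles for ", ph,
                    " (child ", ch, "); row partially filled"))
        mid <- tibble(midparent = NA_real_, delta = NA_real_,
                      pattern = NA_character_)
      } else {
        mid <- midparent_analysis(fp, mp, cp, tolerance = tolerance)
      }
      tibble(
        phenotype_id = ph, child_id = ch,
        father_percentile = round_half_up(fp, 2),
        mother_percentile = round_half_up(mp, 2),
        child_percentile = round_half_up(cp, 2),
        father_band = if (is.na(fp)) NA_character_ else band_of(fp),
        mother_band = if (is.na(mp)) NA_character_ else band_of(mp),
        child_band = if (is.na(cp)) NA_character_ else band_of(cp)
      ) |> bind_cols(mid)
    }) |> bind_rows()
  }) |> bind_rows()
  rows
}

#' Risk-translation report for a set of individuals
#'
#' Applies [translate_risk()] to every sample x phenotype in an assignment
#' table, using the risk tables and sex applicability from phenotype
#' metadata.
#'
#' @param assignments percentile assignment tibble (one background per
#'   sample x phenotype), with `z_score`.
#' @param meta phenotype metadata tibble (selected entries) carrying
#'   `risk_table` and `sex_applicability`.
#' @param sexes named character vector mapping sample_id to
#'   `"male"`/`"female"`.
#' @return tibble, one row per sample x phenotype, with the translation
#'   columns of [translate_risk()].
#' @export
risk_report <- function(assignments, meta, sexes = character()) {
  purrr::map(seq_len(nrow(assignments)), function(i) {
    row <- assignments[i, ]
    m <- meta |> filter(.data$phenotype == row$phenotype_id)
    rt <- if (nrow(m) > 0) m$risk_table[[1]] else NULL
    sexapp <- if (nrow(m) > 0) m$sex_applicability[[1]] else "any"
    translate_risk(
      percentile = row$percentile, z = row$z_score, risk_table = rt,
      sex = unname(sexes[row$sample_id] %||% NA_character_),
      sex_applicability = sexapp
    ) |>
      mutate(sample_id = row$sample_id, phenotype_id = row$phenotype_id,
             percentile = round_half_up(row$percentile, 2), .before = 1)
  }) |> bind_rows()
}
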