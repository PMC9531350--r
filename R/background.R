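#' Read a sample-to-population panel map
#'
#' 1000G-panel-style TSV with columns `sample`, `pop` and optionally
#' `super_pop`.
#'
#' @param path TSV path.
#' @return tibble with `sample`, `pop`, `super_pop`.
#' @export
read_panel_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(m) <- tolower(names(m))
  stopifnot(all(c("sample", "pop") %in% names(m)))
  if (!"super_pop" %in% names(m)) m$super_pop <- m$pop
  as_tibble(m[, c("sample", "pop", "super_pop")])
}

#' Build a background score distribution for a population subset
#'
#' Collects the raw scores of every cohort sample whose population (or
#' super-population) label is in the selector, sorts them, and labels the
#' result. Selectors may be unions, so nested subsets (a subpopulation, its
#' continental group, the full cohort) are expressed as progressively larger
#' selectors.
#'
#' @param cohort_scores score tibble (`sample_id`, `phenotype_id`,
#'   `raw_score`) for one phenotype.
#' @param panel_map tibble from [read_panel_map()].
#' @param populations character vector of `pop`/`super_pop` labels, or
#'   `"ALL"` to take every sample.
#' @param label label stored on the distribution (default: selector
#'   collapsed with `+`).
#' @return a `prs_background`: sorted scores with population label and `n`.
#' @export
build_background <- function(cohort_scores, panel_map, populations,
                             label = paste(populations, collapse = "+")) {
  stopifnot(is.data.frame(cohort_scores))
  phen <- unique(cohort_scores$phenotype_id)
  if (length(phen) != 1) {
    abort("cohort_scores must cover exactly one phenotype",
          class = "prspipe_background_error")
  }
  keep <- if (identical(populations, "ALL")) {
    panel_map$sample
  } else {
    panel_map$sample[panel_map$pop %in% populations |
                       panel_map$super_pop %in% populations]
  }
  sel <- cohort_scores |> filter(.data$sample_id %in% keep)
  if (nrow(sel) == 0) {
    abort(paste0("no cohort samples match selector: ",
                 paste(populations, collapse = ", ")),
          class = "prspipe_background_error")
  }
  missing_scores <- setdiff(keep, sel$sample_id)
  if (length(missing_scores) > 0 && !identical(populations, "ALL")) {
    warn(paste0(length(missing_scores),
                " selected sample(s) have no score and are excluded"))
  }
  if (nrow(sel) < 2) {
    abort("background needs at least 2 scored samples",
          class = "prspipe_background_error")
  }
  structure(
    list(
      phenotype_id = phen,
      population_label = label,
      n = nrow(sel),
      scores = sort(sel$raw_score)
    ),
    class = "prs_background"
  )
}

#' @exportS3Method base::print
print.prs_background <- function(x, ...) {
  cat("<prs_background> ", x$phenotype_id, " / ", x$population_label,
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Background scores as a tibble
#'
#' @param x a `prs_background`.
#' @param ... unused.
#' @return tibble of sorted raw scores.
#' @export
tidy.prs_background <- function(x, ...) {
  tibble(phenotype_id = x$phenotype_id, population = x$population_label,
         raw_score = x$scores)
}

#' One-row background summary
#'
#' @param x a `prs_background`.
#' @param ... unused.
#' @return tibble with n, mean, sd and range of the background scores.
#' @export
glance.prs_background <- function(x, ...) {
  tibble(
    phenotype_id = x$phenotype_id,
    population = x$population_label,
    n = x$n,
    mean = mean(x$scores),
    sd = sd(x$scores),
    min = min(x$scores),
    max = max(x$scores)
  )
}

#' Percentile of a score within a background distribution
#'
#' Midrank placement: `100 * (n_below + 0.5 * n_equal) / n`, where the
#' tested individual is never added to the background. With continuous
#' scores and no ties the result lies on the grid `{100 k / n}`.
#'
#' @param score raw score (vectorised).
#' @param dist a `prs_background`.
#' @return percentile(s) in `[0, 100]`, unrounded.
#' @export
percentile_of <- function(score, dist) {
  stopifnot(inherits(dist, "prs_background"))
  below <- findInterval(score, dist$scores, left.open = TRUE)
  at_or_below <- findInterval(score, dist$scores)
  equal <- at_or_below - below
  100 * (below + 0.5 * equal) / dist$n
}

#' Quintile of a percentile
#'
#' Half-open 20-point bins, top bin closed: `[0,20) [20,40) [40,60) [60,80)
#' [80,100]`. A percentile of exactly 80 falls in quintile 5.
#'
#' @param percentile numeric in `[0, 100]` (vectorised).
#' @return integer quintile 1-5.
#' @export
quintile_of <- function(percentile) {
  stopifnot(all(percentile >= 0 & percentile <= 100))
  pmin(as.integer(percentile %/% 20) + 1L, 5L)
}

#' Risk band of a percentile
#'
#' `top5` at or above the 95th percentile; `high` strictly above the 80th
#' (but below 95); symmetric `bottom5`/`low` bands at the other tail; `mid`
#' otherwise.
#'
#' @param percentile numeric in `[0, 100]` (vectorised).
#' @return character band.
#' @export
band_of <- function(percentile) {
  stopifnot(all(percentile >= 0 & percentile <= 100))
  case_when(
    percentile >= 95 ~ "top5",
    percentile > 80 ~ "high",
    percentile <= 5 ~ "bottom5",
    percentile < 20 ~ "low",
    TRUE ~ "mid"
  )
}

#' Place samples' scores in several background distributions
#'
#' @param scores score tibble (`sample_id`, `phenotype_id`, `raw_score`).
#' @param backgrounds named list of `prs_background` objects for the same
#'   phenotype.
#' @return tibble: sample x background with `percentile` (unrounded),
#'   `quintile`, `band` and `z_score` (score centred and scaled by the
#'   background mean/sd).
#' @export
assign_percentiles <- function(scores, backgrounds) {
  stopifnot(length(backgrounds) >= 1)
  if (is.null(names(backgrounds)) || any(!nzchar(names(backgrounds)))) {
    names(backgrounds) <- purrr::map_chr(backgrounds, "population_label")
  }
  purrr::imap(backgrounds, function(bg, lab) {
    p <- percentile_of(scores$raw_score, bg)
    tibble(
      sample_id = scores$sample_id,
      phenotype_id = scores$phenotype_id,
      population_label = lab,
      percentile = p,
      quintile = quintile_of(p),
      band = band_of(p),
      z_score = (scores$raw_score - mean(bg$scores)) / sd(bg$scores)
    )
  }) |> bind_rows()
}

#' Consistency of one sample's percentiles across backgrounds
#'
#' A set of placements is inconsistent when the choice of background moves
#' the percentile by more than 20 points AND changes the quintile; either
#' alone is tolerated.
#'
#' @param percentiles numeric vector of percentiles for one sample x
#'   phenotype across two or more backgrounds.
#' @return one-row tibble: `consistent` (logical), `max_spread`,
#'   `n_quintiles`.
#' @export
consistency_check <- function(percentiles) {
  stopifnot(length(percentiles) >= 2,
            all(percentiles >= 0 & percentiles <= 100))
  spread <- max(percentiles) - min(percentiles)
  nq <- length(unique(quintile_of(percentiles)))
  tibble(
    consistent = !(spread > 20 && nq >= 2),
    max_spread = spread,
    n_quintiles = nq
  )
}

#' Cross-background consistency report
#'
#' Applies [consistency_check()] per sample x phenotype over a percentile
#' assignment table.
#'
#' @param assignments tibble from [assign_percentiles()] covering >= 2
#'   backgrounds.
#' @return tibble with one row per sample x phenotype.
#' @export
consistency_report <- function(assignments) {
  assignments |>
    group_by(.data$sample_id, .data$phenotype_id) |>
    summarise(consistency_check(.data$percentile), .groups = "drop")
}
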