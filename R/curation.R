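#' Default curation configuration
#'
#' Encodes the design-selection policy: a performance threshold of 0.60
#' applied to AUC and C-index values as printed, a separate threshold for
#' R-squared metrics (variance-explained values live on a different scale),
#' a named exception list of phenotypes admitted despite falling below the
#' threshold, and per-phenotype duplicate overrides naming the source that
#' should win when several scores target the same phenotype.
#'
#' @param performance_threshold minimum performance for AUC/C-index entries.
#' @param metric_thresholds named numeric vector of per-metric thresholds
#'   overriding `performance_threshold` (default `c(R2 = 0.10)`).
#' @param exceptions character vector of phenotypes admitted below threshold.
#' @param duplicate_overrides named character vector: phenotype -> source_id
#'   forced to win duplicate resolution.
#' @return a list usable as the `config` argument of the curation functions.
#' @export
curation_config <- function(performance_threshold = 0.60,
                            metric_thresholds = c(R2 = 0.10),
                            exceptions = "Ischaemic stroke",
                            duplicate_overrides = c(
                              "Breast cancer" = "PGS000015",
                              "Coronary Artery Disease" = "PGS000013",
                              "Type 2 diabetes" = "PGS000014"
                            )) {
  list(
    performance_threshold = performance_threshold,
    metric_thresholds = metric_thresholds,
    exceptions = exceptions,
    duplicate_overrides = duplicate_overrides
  )
}

#' Read a curation config from YAML
#'
#' @param path YAML file with keys `performance_threshold`,
#'   `metric_thresholds`, `exceptions`, `duplicate_overrides`.
#' @return a curation config list (see [curation_config()]).
#' @export
read_curation_config <- function(path) {
  doc <- yaml::read_yaml(path)
  curation_config(
    performance_threshold = doc$performance_threshold %||% 0.60,
    metric_thresholds = unlist(doc$metric_thresholds %||% list(R2 = 0.10)),
    exceptions = unlist(doc$exceptions %||% character()),
    duplicate_overrides = unlist(doc$duplicate_overrides %||% character())
  )
}

threshold_for <- function(performance_type, config) {
  th <- config$metric_thresholds
  if (!is.null(th) && performance_type %in% names(th)) {
    unname(th[[performance_type]])
  } else {
    config$performance_threshold
  }
}

#' Apply the design-selection criteria to phenotype metadata
#'
#' Evaluates each metadata entry against the design criteria: the underlying
#' GWAS must be traceable to a recognised consortium, the score must have been
#' trained with a published method, validated in a large independent cohort,
#' and its performance metric must be available and at or above the configured
#' threshold (phenotypes on the exception list are admitted below it). These
#' are per-entry decisions; duplicate entries for the same phenotype are
#' resolved afterwards by [resolve_duplicates()].
#'
#' @param meta tibble of phenotype metadata as from [read_phenotype_meta()].
#' @param config curation config, see [curation_config()].
#' @return tibble: `phenotype`, `source_id`, `status`
#'   (`"selected"`/`"unselected"`), and a `reasons` list-column of reason
#'   codes (empty for selected entries).
#' @export
apply_design_criteria <- function(meta, config = curation_config()) {
  stopifnot(is.data.frame(meta), nrow(meta) > 0)
  decide_one <- function(row) {
    reasons <- character()
    if (!row$gwas_traceable) reasons <- c(reasons, "not_traceable_gwas")
    if (!row$trained_with_published_method) {
      reasons <- c(reasons, "not_published_method")
    }
    if (!row$large_validation) reasons <- c(reasons, "no_large_validation")
    if (row$performance_type == "unavailable") {
      reasons <- c(reasons, "performance_unavailable")
    } else {
      th <- threshold_for(row$performance_type, config)
      if (row$performance_value < th &&
          row$phenotype %not_in% config$exceptions) {
        reasons <- c(reasons, "performance_below_threshold")
      }
    }
    reasons
  }
  reasons <- purrr::map(seq_len(nrow(meta)), function(i) decide_one(meta[i, ]))
  tibble(
    phenotype = meta$phenotype,
    source_id = meta$source_id,
    status = if_else(lengths(reasons) == 0, "selected", "unselected"),
    reasons = reasons
  )
}

#' Resolve duplicate scores for the same phenotype
#'
#' When several design-eligible entries target one phenotype, at most one may
#' survive. The default rule keeps the entry with the highest performance
#' value (metrics compared on their raw printed values); a per-phenotype
#' override in the config forces a named source to win instead, recording
#' `judgement_override` on the winner. Losers that out-performed the winner
#' are tagged `validation_not_preferred_cohort` (they lost on cohort
#' preference, not performance); the rest get `lower_performance_duplicate`.
#'
#' @param meta phenotype metadata tibble.
#' @param decisions output of [apply_design_criteria()] on `meta`.
#' @param config curation config.
#' @return `decisions` updated so each phenotype has at most one selected
#'   entry.
#' @export
resolve_duplicates <- function(meta, decisions, config = curation_config()) {
  stopifnot(nrow(meta) == nrow(decisions))
  d <- decisions
  for (ph in unique(d$phenotype)) {
    idx <- which(d$phenotype == ph & d$status == "selected")
    if (length(idx) <= 1) next
    perf <- meta$performance_value[idx]
    override <- config$duplicate_overrides[ph]
    if (!is.na(override) && override %in% d$source_id[idx]) {
      win <- idx[match(override, d$source_id[idx])]
      d$reasons[[win]] <- "judgement_override"
    } else {
      win <- idx[which.max(perf)]
    }
    for (j in setdiff(idx, win)) {
      d$status[j] <- "unselected"
      d$reasons[[j]] <- if (isTRUE(meta$performance_value[j] >=
                                   meta$performance_value[win])) {
        "validation_not_preferred_cohort"
      } else {
        "lower_performance_duplicate"
      }
    }
  }
  d
}

#' Run the full design-curation stage
#'
#' [apply_design_criteria()] followed by [resolve_duplicates()].
#'
#' @inheritParams resolve_duplicates
#' @return decision tibble, one row per metadata entry.
#' @export
curate_phenotypes <- function(meta, config = curation_config()) {
  decisions <- apply_design_criteria(meta, config)
  resolve_duplicates(meta, decisions, config)
}

#' Summarise curation decisions
#'
#' @param decisions decision tibble from [curate_phenotypes()].
#' @return one-row tibble with `n_candidates`, `n_discarded_design`,
#'   `n_selected_design`.
#' @export
curation_summary <- function(decisions) {
  stopifnot(nrow(decisions) > 0)
  tibble(
    n_candidates = nrow(decisions),
    n_discarded_design = sum(decisions$status == "unselected"),
    n_selected_design = sum(decisions$status == "selected")
  )
}

#' Apply the bioinformatic gate to harmonisation accounting
#'
#' A phenotype passes when at least 95% of its reported variants survived
#' harmonisation (missingness at most 5.00% after half-up rounding to two
#' decimals) and the score contains no X/Y-chromosome variants.
#'
#' @param accounting tibble with columns `phenotype`, `missing_pct`
#'   (percent, `NA` treated as 0) and optionally `contains_xy` (logical).
#' @param max_missing_pct gate threshold in percent (default 5).
#' @return `accounting` with logical `pass_gate` and a `gate_reason` column
#'   (`NA` for passing rows).
#' @export
apply_bioinformatic_gate <- function(accounting, max_missing_pct = 5) {
  stopifnot(is.data.frame(accounting))
  pct <- accounting$missing_pct
  pct[is.na(pct)] <- 0
  xy <- if ("contains_xy" %in% names(accounting)) {
    !is.na(accounting$contains_xy) & accounting$contains_xy
  } else {
    rep(FALSE, nrow(accounting))
  }
  accounting |>
    mutate(
      pass_gate = pct <= max_missing_pct & !xy,
      gate_reason = case_when(
        xy ~ "contains_xy_variants",
        pct > max_missing_pct ~ "missing_snps_above_5pct",
        TRUE ~ NA_character_
      )
    )
}

#' Write a curation report
#'
#' TSV mirroring the status/reason layout of the design-curation table.
#'
#' @param decisions decision tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curation_report <- function(decisions, path) {
  out <- decisions |>
    mutate(reasons = purrr::map_chr(.data$reasons, paste, collapse = ";"))
  readr::write_tsv(out, path)
  invisible(path)
}
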