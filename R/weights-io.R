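#' Default column aliases for scoring files
#'
#' Scoring files from different repositories use different headers for the
#' same columns. Names are matched case-insensitively against this map; the
#' canonical names are `variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele` and `effect_weight`.
#'
#' @return named character vector mapping lowercase source headers to
#'   canonical column names.
#' @export
default_column_aliases <- function() {
  c(
    rsid           = "variant_id",
    variant_id     = "variant_id",
    snp            = "variant_id",
    chr_name       = "chrom",
    chrom          = "chrom",
    chr            = "chrom",
    chromosome     = "chrom",
    chr_position   = "pos",
    pos            = "pos",
    position       = "pos",
    effect_allele  = "effect_allele",
    risk_allele    = "effect_allele",
    other_allele   = "other_allele",
    reference_allele = "other_allele",
    effect_weight  = "effect_weight",
    weight         = "effect_weight",
    beta           = "effect_weight"
  )
}

new_scoring_file <- function(variants, phenotype_id, source_id = NA_character_,
                             genome_build = "GRCh37",
                             diagnostics = tibble(row = integer(), reason = character())) {
  structure(
    list(
      phenotype_id = phenotype_id,
      source_id = source_id,
      genome_build = genome_build,
      variants = variants,
      n_variants = nrow(variants),
      diagnostics = diagnostics
    ),
    class = "prs_scoring_file"
  )
}

#' @exportS3Method base::print
print.prs_scoring_file <- function(x, ...) {
  cat("<prs_scoring_file> ", x$phenotype_id,
      if (!is.na(x$source_id)) paste0(" (", x$source_id, ")"), "\n", sep = "")
  cat("  build: ", x$genome_build, ", variants: ", x$n_variants, "\n", sep = "")
  if (nrow(x$diagnostics) > 0)
    cat("  rejected rows: ", nrow(x$diagnostics), "\n", sep = "")
  print(x$variants, ...)
  invisible(x)
}

#' Turn a scoring file into a tibble of weighted variants
#'
#' @param x a `prs_scoring_file`.
#' @param ... unused.
#' @return tibble with one row per weighted variant.
#' @export
tidy.prs_scoring_file <- function(x, ...) x$variants

#' One-row summary of a scoring file
#'
#' @param x a `prs_scoring_file`.
#' @param ... unused.
#' @return tibble with phenotype, source, build, variant count and number of
#'   rejected input rows.
#' @export
glance.prs_scoring_file <- function(x, ...) {
  tibble(
    phenotype_id = x$phenotype_id,
    source_id = x$source_id,
    genome_build = x$genome_build,
    n_variants = x$n_variants,
    n_rejected = nrow(x$diagnostics),
    n_sex_chrom = sum(x$variants$sex_chrom)
  )
}

validate_weighted_variants <- function(v) {
  stopifnot(all(v$pos >= 1))
  bad_pair <- !is.na(v$other_allele) & v$other_allele == v$effect_allele
  if (any(bad_pair)) {
    abort("effect_allele equals other_allele for some rows", class = "prspipe_format_error")
  }
  dup <- duplicated(v[, c("chrom", "pos", "effect_allele")])
  if (any(dup)) {
    abort(
      paste0("duplicate (chrom, pos, effect_allele) triples at rows: ",
             paste(which(dup), collapse = ", ")),
      class = "prspipe_format_error"
    )
  }
  invisible(v)
}

#' Read a PGS-Catalog-style scoring file
#'
#' Parses a tab- or comma-separated scoring file with a header into a
#' `prs_scoring_file`. Leading `#key=value` pragma lines (PGS Catalog style)
#' are honoured for `pgs_id`, `trait_reported` and `genome_build`. Rows with
#' an unparseable weight or a malformed allele are rejected with row-numbered
#' diagnostics rather than silently dropped; X/Y rows are parsed but flagged
#' `sex_chrom` so curation can exclude the phenotype.
#'
#' @param path path to the scoring file.
#' @param build expected genome build label (default `"GRCh37"`); a file
#'   declaring a different build is an error — no liftover is attempted.
#' @param phenotype_id phenotype identifier; defaults to the file's
#'   `trait_reported` pragma or the file name.
#' @param aliases named map of accepted header names, see
#'   [default_column_aliases()].
#' @return a `prs_scoring_file`: variant tibble plus phenotype/source/build
#'   metadata and a `diagnostics` tibble of rejected rows.
#' @seealso [write_scoring_file()], [harmonize_phenotype()]
#' @export
read_scoring_file <- function(path, build = "GRCh37", phenotype_id = NULL,
                              aliases = default_column_aliases()) {
  if (!file.exists(path)) {
    abort(paste0("scoring file not found: ", path), class = "prspipe_path_error")
  }
  lines <- readr::read_lines(path)
  pragma <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]

  meta <- list()
  for (p in pragma) {
    kv <- strsplit(sub("^#+\\s*", "", p), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  file_build <- meta[["genome_build"]] %||% build
  if (!identical(toupper(file_build), toupper(build)) &&
      !(toupper(file_build) == "HG19" && toupper(build) %in% c("GRCH37", "HG19"))) {
    abort(
      paste0("scoring file declares build ", file_build, " but ", build,
             " is configured"),
      class = "prspipe_build_error"
    )
  }

  if (length(body) == 0) {
    abort("scoring file has no header line", class = "prspipe_format_error")
  }
  sep <- if (grepl("\t", body[1])) "\t" else ","
  raw <- readr::read_delim(
    I(paste(body, collapse = "\n")),
    delim = sep, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  names(raw) <- tolower(names(raw))
  known <- intersect(names(raw), names(aliases))
  raw <- raw[known]
  names(raw) <- unname(aliases[known])
  raw <- raw[!duplicated(names(raw))]

  required <- c("chrom", "pos", "effect_allele", "effect_weight")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      paste0("scoring file missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "prspipe_format_error"
    )
  }
  if (nrow(raw) == 0) {
    abort("scoring file contains a header but no variants",
          class = "prspipe_empty_error")
  }
  if (!"variant_id" %in% names(raw)) raw$variant_id <- NA_character_
  if (!"other_allele" %in% names(raw)) raw$other_allele <- NA_character_

  parsed <- raw |>
    mutate(
      .row = row_number(),
      chrom = norm_chrom(.data$chrom),
      pos = suppressWarnings(as.integer(.data$pos)),
      effect_allele = toupper(trimws(.data$effect_allele)),
      other_allele = toupper(trimws(.data$other_allele)),
      other_allele = if_else(
        is.na(.data$other_allele) | .data$other_allele %in% c("", "."),
        NA_character_, .data$other_allele),
      effect_weight = suppressWarnings(as.numeric(.data$effect_weight))
    )

  reason <- dplyr::case_when(
    !valid_allele(parsed$effect_allele) ~ "malformed effect allele",
    !is.na(parsed$other_allele) & !valid_allele(parsed$other_allele) ~
      "malformed other allele",
    is.na(parsed$effect_weight) | !is.finite(parsed$effect_weight) ~
      "unparseable effect weight",
    is.na(parsed$pos) | parsed$pos < 1 ~ "invalid position",
    TRUE ~ NA_character_
  )
  diagnostics <- tibble(row = parsed$.row[!is.na(reason)],
                        reason = reason[!is.na(reason)])
  kept <- parsed[is.na(reason), ]

  variants <- kept |>
    mutate(
      variant_id = if_else(is.na(.data$variant_id) | .data$variant_id == "",
                           paste0(.data$chrom, ":", .data$pos),
                           .data$variant_id),
      sex_chrom = is_sex_chrom(.data$chrom)
    ) |>
    select("chrom", "pos", "variant_id", "effect_allele", "other_allele",
           "effect_weight", "sex_chrom")
  if (nrow(variants) == 0) {
    abort("no parseable variants in scoring file", class = "prspipe_empty_error")
  }
  validate_weighted_variants(variants)

  phenotype_id <- phenotype_id %||% meta[["trait_reported"]] %||%
    tools::file_path_sans_ext(basename(path))
  new_scoring_file(
    variants,
    phenotype_id = phenotype_id,
    source_id = meta[["pgs_id"]] %||% NA_character_,
    genome_build = file_build,
    diagnostics = diagnostics
  )
}

#' Write a scoring file back to disk
#'
#' Emits the tab-separated dialect with `#` pragma header lines so that
#' [read_scoring_file()] round-trips the object exactly.
#'
#' @param sf a `prs_scoring_file`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scoring_file <- function(sf, path) {
  stopifnot(inherits(sf, "prs_scoring_file"))
  pragma <- c(
    if (!is.na(sf$source_id)) paste0("#pgs_id=", sf$source_id),
    paste0("#trait_reported=", sf$phenotype_id),
    paste0("#genome_build=", sf$genome_build)
  )
  body <- sf$variants |>
    select(rsID = "variant_id", chr_name = "chrom", chr_position = "pos",
           effect_allele = "effect_allele", other_allele = "other_allele",
           effect_weight = "effect_weight")
  readr::write_lines(pragma, path)
  readr::write_tsv(body, path, append = TRUE, col_names = TRUE,
                   escape = "none")
  invisible(path)
}

#' Construct a scoring file from a variant tibble
#'
#' Programmatic constructor used by the simulator and by tests; applies the
#' same invariants as the parser.
#'
#' @param variants tibble with columns `chrom`, `pos`, `variant_id`,
#'   `effect_allele`, `other_allele`, `effect_weight`.
#' @param phenotype_id phenotype identifier.
#' @param source_id optional catalogue identifier.
#' @param genome_build build label, default `"GRCh37"`.
#' @return a `prs_scoring_file`.
#' @export
scoring_file <- function(variants, phenotype_id, source_id = NA_character_,
                         genome_build = "GRCh37") {
  variants <- as_tibble(variants)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- paste0(variants$chrom, ":", variants$pos)
  }
  if (!"other_allele" %in% names(variants)) variants$other_allele <- NA_character_
  variants <- variants |>
    mutate(
      chrom = norm_chrom(.data$chrom),
      pos = as.integer(.data$pos),
      effect_allele = toupper(.data$effect_allele),
      sex_chrom = is_sex_chrom(.data$chrom)
    ) |>
    select("chrom", "pos", "variant_id", "effect_allele", "other_allele",
           "effect_weight", "sex_chrom")
  stopifnot(nrow(variants) > 0, all(is.finite(variants$effect_weight)),
            all(valid_allele(variants$effect_allele)))
  validate_weighted_variants(variants)
  new_scoring_file(variants, phenotype_id, source_id, genome_build)
}

#' Read phenotype metadata from a YAML config
#'
#' The config has one block per phenotype entry carrying curation metadata
#' (source, performance metric and value, validation cohort, booleans for
#' traceable GWAS / published training method / large validation cohort,
#' sex applicability) and an optional `risk_table` block of published
#' threshold-to-metric entries used by [translate_risk()].
#'
#' @param path path to a YAML file with a top-level `phenotypes` list.
#' @return tibble with one row per (phenotype, source) entry; `risk_table`
#'   is a list-column of tibbles (or `NULL`).
#' @export
read_phenotype_meta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("phenotype metadata not found: ", path),
          class = "prspipe_path_error")
  }
  doc <- yaml::read_yaml(path)
  entries <- doc$phenotypes %||% abort("config has no `phenotypes` list",
                                       class = "prspipe_config_error")
  known <- c("phenotype", "group", "source_id", "gwas_source",
             "gwas_traceable", "trained_with_published_method",
             "large_validation", "validation_cohort", "performance_type",
             "performance_value", "n_snps", "sex_applicability", "risk_table",
             "risk_metric")
  meta <- purrr::map(entries, function(e) {
    unknown <- setdiff(names(e), known)
    if (length(unknown) > 0) {
      warn(paste0("ignoring unknown metadata field(s) for ",
                  e$phenotype %||% "<unnamed>", ": ",
                  paste(unknown, collapse = ", ")))
    }
    perf_type <- e$performance_type %||% "unavailable"
    if (perf_type %not_in% c("AUC", "C-index", "R2", "unavailable")) {
      abort(paste0("invalid performance_type: ", perf_type),
            class = "prspipe_config_error")
    }
    perf_val <- e$performance_value
    if (perf_type == "unavailable" && !is.null(perf_val)) {
      abort(paste0(e$phenotype, ": performance_value given but type is unavailable"),
            class = "prspipe_config_error")
    }
    if (perf_type != "unavailable" && is.null(perf_val)) {
      abort(paste0(e$phenotype, ": performance_type ", perf_type,
                   " requires performance_value"),
            class = "prspipe_config_error")
    }
    if (perf_type %in% c("AUC", "C-index") && !is.null(perf_val) &&
        (perf_val <= 0 || perf_val > 1)) {
      abort(paste0(e$phenotype, ": ", perf_type, " must lie in (0, 1]"),
            class = "prspipe_config_error")
    }
    sex <- e$sex_applicability %||% "any"
    if (sex %not_in% c("any", "female_only", "male_only")) {
      abort(paste0("invalid sex_applicability: ", sex),
            class = "prspipe_config_error")
    }
    tibble(
      phenotype = e$phenotype %||% abort("phenotype entry without a name",
                                         class = "prspipe_config_error"),
      group = e$group %||% NA_character_,
      source_id = e$source_id %||% NA_character_,
      gwas_traceable = isTRUE(e$gwas_traceable %||% TRUE),
      trained_with_published_method = isTRUE(e$trained_with_published_method %||% TRUE),
      large_validation = isTRUE(e$large_validation %||% TRUE),
      validation_cohort = e$validation_cohort %||% NA_character_,
      performance_type = perf_type,
      performance_value = if (is.null(perf_val)) NA_real_ else as.numeric(perf_val),
      n_snps = if (is.null(e$n_snps)) NA_real_ else as.numeric(e$n_snps),
      sex_applicability = sex,
      risk_table = list(parse_risk_table(e$risk_table, e$phenotype))
    )
  }) |> bind_rows()

  dup <- duplicated(meta[, c("phenotype", "source_id")])
  if (any(dup)) {
    abort(
      paste0("duplicate phenotype/source entries: ",
             paste(unique(meta$phenotype[dup]), collapse = ", ")),
      class = "prspipe_config_error"
    )
  }
  meta
}

parse_risk_table <- function(rt, phenotype) {
  if (is.null(rt)) return(NULL)
  metric <- rt$metric_type %||% abort(
    paste0(phenotype, ": risk_table needs metric_type"),
    class = "prspipe_config_error")
  if (metric %not_in% c("OR", "HR")) {
    abort(paste0(phenotype, ": metric_type must be OR or HR"),
          class = "prspipe_config_error")
  }
  entries <- purrr::map(rt$entries, function(en) {
    tibble(
      threshold_kind = en$threshold_kind %||% "top_pct_vs_rest",
      top_pct = if (is.null(en$top_pct)) NA_real_ else as.numeric(en$top_pct),
      estimate = as.numeric(en$estimate),
      ci_low = if (is.null(en$ci_low)) NA_real_ else as.numeric(en$ci_low),
      ci_high = if (is.null(en$ci_high)) NA_real_ else as.numeric(en$ci_high)
    )
  }) |> bind_rows()
  validate_risk_table(entries, metric, phenotype)
  entries$metric_type <- metric
  entries
}

validate_risk_table <- function(entries, metric, phenotype) {
  bad_kind <- entries$threshold_kind %not_in% c("top_pct_vs_rest", "per_sd")
  if (any(bad_kind)) {
    abort(paste0(phenotype, ": invalid threshold_kind"),
          class = "prspipe_config_error")
  }
  if (any(entries$estimate <= 0)) {
    abort(paste0(phenotype, ": risk estimates must be positive"),
          class = "prspipe_config_error")
  }
  ci_bad <- !is.na(entries$ci_low) & !is.na(entries$ci_high) &
    (entries$ci_low > entries$estimate | entries$ci_high < entries$estimate)
  if (any(ci_bad)) {
    abort(paste0(phenotype, ": confidence interval does not bracket estimate"),
          class = "prspipe_config_error")
  }
  top <- entries$threshold_kind == "top_pct_vs_rest"
  if (any(top & (is.na(entries$top_pct) | entries$top_pct <= 0 |
                 entries$top_pct >= 100))) {
    abort(paste0(phenotype, ": top_pct must lie in (0, 100)"),
          class = "prspipe_config_error")
  }
  invisible(entries)
}
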