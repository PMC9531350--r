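#' Run configuration for the end-to-end pipeline
#'
#' Collects input paths and options for [run_pipeline()]. All paths must
#' exist at run time.
#'
#' @param scoring_files named character vector of scoring-file paths
#'   (names are phenotype IDs; unnamed entries use the file's own metadata).
#' @param phenotype_meta path to the phenotype metadata YAML.
#' @param panel_vcf path to the reference-panel (sites) VCF.
#' @param panel_map path to the sample-to-population TSV.
#' @param cohort_vcf path to the reference-cohort genotype VCF.
#' @param target_vcf path to the tested individuals' genotype VCF (may equal
#'   `cohort_vcf`).
#' @param pedigree optional pedigree TSV for the family analysis.
#' @param coding_bed optional BED of coding regions for QC.
#' @param out_dir directory for report TSVs.
#' @param curation curation config (see [curation_config()]).
#' @param backgrounds named list of population selectors, e.g.
#'   `list(IBS = "IBS", EUR = c("IBS", ...), ALL = "ALL")`.
#' @param primary_background name (in `backgrounds`) used for risk
#'   translation and the family report.
#' @param max_missing_pct harmonisation gate in percent.
#' @param denominator score denominator mode, see [compute_prs()].
#' @param midparent_tolerance tolerance for [midparent_analysis()].
#' @return a `prs_run_config` list.
#' @export
run_config <- function(scoring_files, phenotype_meta = NULL, panel_vcf,
                       panel_map, cohort_vcf, target_vcf = cohort_vcf,
                       pedigree = NULL, coding_bed = NULL,
                       out_dir = tempdir(),
                       curation = curation_config(),
                       backgrounds = list(ALL = "ALL"),
                       primary_background = names(backgrounds)[1],
                       max_missing_pct = 5,
                       denominator = "reported_M",
                       midparent_tolerance = 20) {
  if (is.null(names(scoring_files)) || any(!nzchar(names(scoring_files)))) {
    names(scoring_files) <- ifelse(
      nzchar(names(scoring_files) %||% rep("", length(scoring_files))),
      names(scoring_files),
      tools::file_path_sans_ext(basename(scoring_files))
    )
  }
  cfg <- list(
    scoring_files = scoring_files, phenotype_meta = phenotype_meta,
    panel_vcf = panel_vcf, panel_map = panel_map, cohort_vcf = cohort_vcf,
    target_vcf = target_vcf, pedigree = pedigree, coding_bed = coding_bed,
    out_dir = out_dir, curation = curation, backgrounds = backgrounds,
    primary_background = primary_background,
    max_missing_pct = max_missing_pct, denominator = denominator,
    midparent_tolerance = midparent_tolerance
  )
  path_fields <- c("phenotype_meta", "panel_vcf", "panel_map", "cohort_vcf",
                   "target_vcf", "pedigree", "coding_bed")
  for (f in path_fields) {
    p <- cfg[[f]]
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("run_config field `", f, "`: path does not exist: ", p),
            class = "prspipe_path_error")
    }
  }
  for (p in cfg$scoring_files) {
    if (!file.exists(p)) {
      abort(paste0("run_config field `scoring_files`: path does not exist: ", p),
            class = "prspipe_path_error")
    }
  }
  stopifnot(primary_background %in% names(backgrounds))
  structure(cfg, class = "prs_run_config")
}

stage_log <- function(stage, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the pipeline end to end
#'
#' Executes curate (when metadata is supplied) -> harmonise -> score the
#' reference cohort -> build backgrounds -> score targets -> percentile
#' placement -> risk translation -> family report -> cross-background
#' consistency (-> QC when a BED is supplied), writing one TSV per stage
#' into `out_dir`.
#'
#' @param config a `prs_run_config`.
#' @param verbose log per-stage counts via [message()].
#' @return named list of the stage result tables (`curation`,
#'   `harmonization`, `cohort_scores`, `target_scores`, `percentiles`,
#'   `risk`, `family`, `consistency`, `qc`), invisibly also written as TSVs.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "prs_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, paste0(name, ".tsv"))
  results <- list()

  meta <- NULL
  if (!is.null(config$phenotype_meta)) {
    meta <- read_phenotype_meta(config$phenotype_meta)
    decisions <- curate_phenotypes(meta, config$curation)
    results$curation <- decisions
    write_curation_report(decisions, out("curation"))
    stage_log("curate", nrow(decisions), " candidates, ",
              sum(decisions$status == "selected"), " selected",
              verbose = verbose)
    keep <- decisions$phenotype[decisions$status == "selected"]
    sel <- names(config$scoring_files) %in% keep
    if (any(sel)) config$scoring_files <- config$scoring_files[sel]
  }

  panel <- read_panel_vcf(config$panel_vcf)
  harmonizations <- purrr::imap(config$scoring_files, function(path, ph) {
    sf <- read_scoring_file(path, phenotype_id = ph)
    harmonize_phenotype(sf, panel, max_missing_pct = config$max_missing_pct)
  })
  results$harmonization <- write_harmonization_report(harmonizations,
                                                      out("harmonization"))
  passing <- purrr::keep(harmonizations, "pass_gate")
  stage_log("harmonize", length(harmonizations), " phenotypes, ",
            length(passing), " pass the missingness gate", verbose = verbose)
  if (length(passing) == 0) {
    abort("no phenotype passes the harmonisation gate",
          class = "prspipe_stage_error")
  }

  cohort <- read_genotypes_vcf(config$cohort_vcf)
  pmap <- read_panel_map(config$panel_map)
  cohort_ids <- intersect(cohort$samples, pmap$sample)
  cohort_scores <- purrr::map(passing, function(h) {
    score_cohort(cohort, h, samples = cohort_ids,
                 denominator = config$denominator)
  })
  results$cohort_scores <- bind_rows(cohort_scores)
  write_score_table(results$cohort_scores, out("cohort_scores"))
  stage_log("score", length(cohort_ids), " cohort samples x ",
            length(passing), " phenotypes", verbose = verbose)

  targets <- if (identical(config$target_vcf, config$cohort_vcf)) cohort else
    read_genotypes_vcf(config$target_vcf)
  target_ids <- setdiff(targets$samples, cohort_ids)
  if (length(target_ids) == 0) target_ids <- targets$samples
  target_scores <- purrr::map(passing, function(h) {
    score_cohort(targets, h, samples = target_ids,
                 denominator = config$denominator)
  })
  results$target_scores <- bind_rows(target_scores)
  write_score_table(results$target_scores, out("target_scores"))

  assignments <- purrr::map(names(passing), function(ph) {
    bgs <- purrr::imap(config$backgrounds, function(selector, lab) {
      build_background(cohort_scores[[ph]], pmap, selector, label = lab)
    })
    assign_percentiles(target_scores[[ph]], bgs)
  }) |> bind_rows()
  results$percentiles <- assignments |>
    mutate(percentile = round_half_up(.data$percentile, 2))
  readr::write_tsv(results$percentiles, out("percentiles"))
  stage_log("percentile", nrow(assignments), " placements across ",
            length(config$backgrounds), " backgrounds", verbose = verbose)

  primary <- assignments |>
    filter(.data$population_label == config$primary_background)
  if (!is.null(meta)) {
    sexes <- character()
    if (!is.null(config$pedigree)) {
      ped <- read_pedigree(config$pedigree)
      sexes <- setNames(ped$sex, ped$id)
    }
    results$risk <- risk_report(primary, meta, sexes)
    readr::write_tsv(results$risk, out("risk"))
    stage_log("translate", sum(results$risk$assigned), " of ",
              nrow(results$risk), " placements assigned a risk metric",
              verbose = verbose)
  }

  if (!is.null(config$pedigree)) {
    ped <- read_pedigree(config$pedigree)
    results$family <- family_report(primary, ped,
                                    tolerance = config$midparent_tolerance)
    readr::write_tsv(results$family, out("family"))
    stage_log("family", nrow(results$family), " phenotype x child rows",
              verbose = verbose)
  }

  if (length(config$backgrounds) >= 2) {
    results$consistency <- consistency_report(assignments)
    readr::write_tsv(results$consistency, out("consistency"))
    stage_log("consistency",
              sum(!results$consistency$consistent), " inconsistent of ",
              nrow(results$consistency), verbose = verbose)
  }

  if (!is.null(config$coding_bed)) {
    bed <- read_bed(config$coding_bed)
    qc <- purrr::map(target_ids, function(s) compute_qc(targets, bed, s)) |>
      bind_rows() |>
      clinical_grade_flags()
    results$qc <- qc
    write_qc_report(qc, out("qc"))
    stage_log("qc", nrow(qc), " samples", verbose = verbose)
  }

  results
}
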