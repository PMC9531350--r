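#' Read coding regions from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed
#' coordinates for point-in-interval tests against VCF positions.
#'
#' @param path BED path (3+ columns, no header).
#' @return tibble with `chrom`, `start`, `end` (1-based closed).
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  stopifnot(ncol(bed) >= 3)
  tibble(
    chrom = norm_chrom(bed[[1]]),
    start = as.integer(bed[[2]]) + 1L,
    end = as.integer(bed[[3]])
  )
}

# TRUE for positions falling inside any interval (1-based closed), per chrom
in_intervals <- function(chrom, pos, intervals) {
  out <- logical(length(pos))
  for (ch in unique(intervals$chrom)) {
    iv <- intervals |> filter(.data$chrom == ch) |> arrange(.data$start)
    # merge overlapping intervals so findInterval is well-defined
    merged_start <- integer(); merged_end <- integer()
    for (i in seq_len(nrow(iv))) {
      if (length(merged_end) > 0 && iv$start[i] <= merged_end[length(merged_end)] + 1L) {
        merged_end[length(merged_end)] <- max(merged_end[length(merged_end)], iv$end[i])
      } else {
        merged_start <- c(merged_start, iv$start[i])
        merged_end <- c(merged_end, iv$end[i])
      }
    }
    sel <- chrom == ch
    if (!any(sel)) next
    k <- findInterval(pos[sel], merged_start)
    out[sel] <- k >= 1 & pos[sel] <= merged_end[pmax(k, 1)]
  }
  out
}

transitions <- c("A>G", "G>A", "C>T", "T>C")

#' Clinical-grade variant-file QC metrics for one sample
#'
#' Computes, over the sample's variant calls (genotypes carrying at least
#' one alternate allele) restricted to coding intervals: median depth,
#' percentage of calls with genotype quality above 40, homozygous-alternate
#' over heterozygous ratio, and transition/transversion ratio over biallelic
#' SNVs (multi-allelic records are decomposed per alternate allele carried).
#' Metrics whose inputs are absent (no DP/GQ field, zero transversions) are
#' reported `NA` rather than 0.
#'
#' @param genotypes a `prs_genotypes` with `dp`/`gq` matrices where
#'   available.
#' @param coding_regions tibble from [read_bed()].
#' @param sample_id sample to assess.
#' @return one-row tibble of metrics (values at 1 decimal where the metric
#'   is a coverage or percentage) plus total/coding variant counts.
#' @export
compute_qc <- function(genotypes, coding_regions, sample_id) {
  stopifnot(inherits(genotypes, "prs_genotypes"))
  if (sample_id %not_in% genotypes$samples) {
    abort(paste0("sample not present: ", sample_id),
          class = "prspipe_lookup_error")
  }
  gt <- genotypes$gt[, sample_id]
  al <- split_gt(gt)
  alts <- strsplit(genotypes$sites$alt, ",", fixed = TRUE)
  has_alt <- (!is.na(al$a1) & al$a1 > 0) | (!is.na(al$a2) & al$a2 > 0)
  coding <- in_intervals(genotypes$sites$chrom, genotypes$sites$pos,
                         coding_regions)
  cv <- which(has_alt & coding)

  j <- match(sample_id, genotypes$samples)
  dp <- if (!is.null(genotypes$dp)) genotypes$dp[cv, j] else NULL
  gq <- if (!is.null(genotypes$gq)) genotypes$gq[cv, j] else NULL

  hom_alt <- sum(!is.na(al$a1[cv]) & !is.na(al$a2[cv]) &
                   al$a1[cv] == al$a2[cv] & al$a1[cv] > 0)
  het <- sum(!is.na(al$a1[cv]) & !is.na(al$a2[cv]) & al$a1[cv] != al$a2[cv])

  # ts/tv over carried alternate alleles at SNV sites, decomposed per alt
  ts <- 0L; tv <- 0L
  for (i in cv) {
    ref <- genotypes$sites$ref[i]
    if (nchar(ref) != 1) next
    carried <- unique(c(al$a1[i], al$a2[i]))
    carried <- carried[!is.na(carried) & carried > 0]
    for (ai in carried) {
      alt <- alts[[i]][ai]
      if (is.na(alt) || nchar(alt) != 1) next
      if (paste0(ref, ">", alt) %in% transitions) ts <- ts + 1L else tv <- tv + 1L
    }
  }

  tibble(
    sample_id = sample_id,
    median_coverage_coding =
      if (is.null(dp) || all(is.na(dp))) NA_real_
      else round_half_up(median(dp, na.rm = TRUE), 1),
    pct_gq_above_40_coding =
      if (is.null(gq) || all(is.na(gq))) NA_real_
      else round_half_up(100 * mean(gq > 40, na.rm = TRUE), 1),
    hom_het_ratio_coding =
      if (het == 0) NA_real_ else round_half_up(hom_alt / het, 2),
    ts_tv_ratio_coding =
      if (tv == 0) NA_real_ else round_half_up(ts / tv, 2),
    n_variants_total = sum(has_alt),
    n_variants_coding = length(cv)
  )
}

#' Clinical-grade star flags for QC metrics
#'
#' Encodes the clinical-grade thresholds: coverage star when median coding
#' coverage exceeds 40 (strict), genotype-quality star when more than 95% of
#' coding calls have quality above 40 (strict), homozygous/heterozygous star
#' when the ratio lies in `[0.5, 0.61]` (inclusive), transition/transversion
#' star when the ratio lies in `[2.71, 3.08]` (inclusive). `NA` metrics give
#' `NA` flags.
#'
#' @param metrics tibble from [compute_qc()] (any number of rows).
#' @param coverage_min,gq_pct_min strict lower bounds for the first two
#'   stars.
#' @param hom_het_range,ts_tv_range inclusive ranges for the ratio stars.
#' @return `metrics` with logical columns `star_coverage`, `star_gq`,
#'   `star_hom_het`, `star_ts_tv`.
#' @export
clinical_grade_flags <- function(metrics, coverage_min = 40, gq_pct_min = 95,
                                 hom_het_range = c(0.5, 0.61),
                                 ts_tv_range = c(2.71, 3.08)) {
  metrics |>
    mutate(
      star_coverage = .data$median_coverage_coding > coverage_min,
      star_gq = .data$pct_gq_above_40_coding > gq_pct_min,
      star_hom_het = .data$hom_het_ratio_coding >= hom_het_range[1] &
        .data$hom_het_ratio_coding <= hom_het_range[2],
      star_ts_tv = .data$ts_tv_ratio_coding >= ts_tv_range[1] &
        .data$ts_tv_ratio_coding <= ts_tv_range[2]
    )
}

#' Write a QC report
#'
#' TSV with metric columns and `*` markers appended to starred values.
#'
#' @param flagged tibble from [clinical_grade_flags()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(flagged, path) {
  starred <- function(v, s) {
    if_else(!is.na(s) & s, paste0(v, "*"), as.character(v))
  }
  out <- flagged |>
    mutate(
      coverage = starred(.data$median_coverage_coding, .data$star_coverage),
      genotype_quality = starred(.data$pct_gq_above_40_coding, .data$star_gq),
      hom_het = starred(.data$hom_het_ratio_coding, .data$star_hom_het),
      ts_tv = starred(.data$ts_tv_ratio_coding, .data$star_ts_tv)
    ) |>
    select("sample_id", "coverage", "genotype_quality", "hom_het", "ts_tv",
           "n_variants_total", "n_variants_coding")
  readr::write_tsv(out, path)
  invisible(path)
}
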