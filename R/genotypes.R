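#' Construct a genotype set
#'
#' Container for hard-called diploid genotypes at a set of sites: a site
#' tibble plus a sites-by-samples matrix of GT strings, with optional DP
#' (depth) and GQ (genotype quality) matrices used by the QC module.
#'
#' @param sites tibble with `chrom`, `pos`, `ref`, `alt` (comma-separated
#'   alternates allowed).
#' @param gt character matrix, `nrow(sites)` x samples, VCF GT strings
#'   (`"0/1"`, `"1|1"`, `"./."`, ...). Column names are sample IDs.
#' @param dp,gq optional numeric matrices with the same shape as `gt`.
#' @return a `prs_genotypes` object.
#' @export
genotype_set <- function(sites, gt, dp = NULL, gq = NULL) {
  sites <- as_tibble(sites) |>
    mutate(chrom = norm_chrom(.data$chrom), pos = as.integer(.data$pos),
           ref = toupper(.data$ref), alt = toupper(.data$alt))
  gt <- as.matrix(gt)
  stopifnot(nrow(gt) == nrow(sites), !is.null(colnames(gt)))
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(gt)))
  if (!is.null(gq)) stopifnot(all(dim(gq) == dim(gt)))
  structure(
    list(sites = sites, gt = gt, dp = dp, gq = gq,
         samples = colnames(gt)),
    class = "prs_genotypes"
  )
}

#' @exportS3Method base::print
print.prs_genotypes <- function(x, ...) {
  cat("<prs_genotypes> ", nrow(x$sites), " sites x ", length(x$samples),
      " samples\n", sep = "")
  cat("  samples: ", paste(utils::head(x$samples, 8), collapse = ", "),
      if (length(x$samples) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

#' Read genotypes from a VCF file
#'
#' @param path VCF path (plain or gzipped). GT is required; DP and GQ are
#'   extracted when present in FORMAT.
#' @return a `prs_genotypes`.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("genotype VCF not found: ", path), class = "prspipe_path_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  sites <- tibble(
    chrom = norm_chrom(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = toupper(v@fix[, "REF"]),
    alt = toupper(v@fix[, "ALT"])
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  fmt <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)))
  dp <- if ("DP" %in% fmt) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  }
  gq <- if ("GQ" %in% fmt) {
    suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  }
  genotype_set(sites, gt, dp = dp, gq = gq)
}

# split GT strings into an alleles-by-call integer matrix (NA for missing),
# honouring phased and unphased separators. Returns list(a1, a2) vectors.
split_gt <- function(gt) {
  gt <- as.character(gt)
  gt[is.na(gt)] <- "./."
  parts <- stringr::str_split_fixed(gt, "[/|]", 2)
  a1 <- suppressWarnings(as.integer(parts[, 1]))
  a2 <- suppressWarnings(as.integer(parts[, 2]))
  ploidy_one <- parts[, 2] == ""
  if (any(ploidy_one & !is.na(a1))) {
    abort("non-diploid genotype call encountered", class = "prspipe_ploidy_error")
  }
  list(a1 = a1, a2 = a2)
}

#' Extract effect-allele dosages for one sample
#'
#' For each retained (harmonised) variant, the dosage is the number of
#' alleles in the sample's genotype call equal to the effect allele. For a
#' whole-genome call set an absent record means a homozygous-reference call,
#' so an absent site contributes dosage 2 when the effect allele matched the
#' panel REF and 0 otherwise. A present record with a fully missing genotype
#' (`./.`) contributes 0 and is counted in `n_half_missing`; half-calls
#' (`./1`) count only the observed allele.
#'
#' @param genotypes a `prs_genotypes`.
#' @param sample_id sample to extract.
#' @param harmonized a `prs_harmonization` for the phenotype.
#' @return tibble of retained variants with a `dosage` column; attributes
#'   `n_sites_absent` and `n_half_missing` carry the accounting.
#' @export
extract_dosages <- function(genotypes, sample_id, harmonized) {
  stopifnot(inherits(genotypes, "prs_genotypes"),
            inherits(harmonized, "prs_harmonization"))
  if (sample_id %not_in% genotypes$samples) {
    abort(paste0("sample not present in genotypes: ", sample_id),
          class = "prspipe_lookup_error")
  }
  m <- dosage_matrix(genotypes, harmonized, samples = sample_id)
  out <- retained_variants(harmonized)
  out$dosage <- as.integer(m$dosage[, 1])
  attr(out, "n_sites_absent") <- m$n_sites_absent
  attr(out, "n_half_missing") <- m$n_half_missing[[sample_id]]
  out
}

#' Effect-allele dosage matrix for a cohort
#'
#' Vectorised form of [extract_dosages()] over many samples in one pass.
#'
#' @param genotypes a `prs_genotypes`.
#' @param harmonized a `prs_harmonization`.
#' @param samples sample IDs (default: all samples in `genotypes`).
#' @return list with `dosage` (retained-variants x samples integer matrix),
#'   `n_sites_absent`, and per-sample `n_half_missing` counts.
#' @export
dosage_matrix <- function(genotypes, harmonized, samples = genotypes$samples) {
  bad <- setdiff(samples, genotypes$samples)
  if (length(bad) > 0) {
    abort(paste0("sample(s) not present in genotypes: ",
                 paste(bad, collapse = ", ")),
          class = "prspipe_lookup_error")
  }
  rv <- retained_variants(harmonized)
  gkey <- site_key(genotypes$sites$chrom, genotypes$sites$pos)
  idx <- match(site_key(rv$chrom, rv$pos), gkey)
  present <- !is.na(idx)
  n_absent <- sum(!present)

  # which allele index codes the effect allele at each present site
  eff_idx <- rep(NA_integer_, nrow(rv))
  if (any(present)) {
    ref <- genotypes$sites$ref[idx[present]]
    alt <- genotypes$sites$alt[idx[present]]
    alt_list <- strsplit(alt, ",", fixed = TRUE)
    eff <- rv$effect_allele[present]
    ai <- purrr::map2_int(alt_list, eff, function(a, e) {
      p <- match(e, a)
      if (is.na(p)) NA_integer_ else p
    })
    eidx <- if_else(eff == ref, 0L, ai)
    if (any(is.na(eidx))) {
      bad_sites <- rv[present, ][is.na(eidx), ]
      abort(
        paste0("effect allele absent from genotype REF/ALT at ",
               paste(utils::head(site_key(bad_sites$chrom, bad_sites$pos), 5),
                     collapse = ", "),
               " - panel and genotype VCF disagree"),
        class = "prspipe_consistency_error"
      )
    }
    eff_idx[present] <- eidx
  }

  base <- if_else(rv$status == "matched_ref", 2L, 0L)  # absent => 0/0
  dosage <- matrix(rep(base, length(samples)), ncol = length(samples),
                   dimnames = list(NULL, samples))
  half_missing <- setNames(integer(length(samples)), samples)
  if (any(present)) {
    rows <- idx[present]
    for (s in samples) {
      al <- split_gt(genotypes$gt[rows, s])
      fully_missing <- is.na(al$a1) & is.na(al$a2)
      half_missing[[s]] <- sum(fully_missing)
      e <- eff_idx[present]
      d <- ((!is.na(al$a1)) & al$a1 == e) + ((!is.na(al$a2)) & al$a2 == e)
      d[fully_missing] <- 0L
      dosage[present, s] <- as.integer(d)
    }
  }
  if (any(half_missing > 0)) {
    warn(paste0("fully missing genotype calls treated as dosage 0 for ",
                sum(half_missing > 0), " sample(s)"))
  }
  list(dosage = dosage, n_sites_absent = n_absent,
       n_half_missing = as.list(half_missing))
}
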