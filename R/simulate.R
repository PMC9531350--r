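#' Simulation configuration
#'
#' Describes a synthetic study: a scoring file of `n_variants` weighted
#' variants, a stratified diploid cohort (one Balding-Nichols population per
#' row of `populations`, with divergence `fst` from a shared ancestral
#' frequency), optional Mendelian trios, and controlled harmonisation
#' failures (a fraction of variants absent from the panel, a fraction whose
#' panel alleles are rewritten so the effect allele mismatches).
#'
#' @param seed integer seed making every artifact reproducible.
#' @param n_variants number of scoring-file variants M.
#' @param weight_mean,weight_sd normal distribution of effect weights.
#' @param weights optional fixed weight vector overriding the normal draw.
#' @param populations tibble with columns `label`, `n_samples`, `fst`
#'   (`fst` in `[0, 1)`).
#' @param n_trios number of child genotypes to simulate from sampled parent
#'   pairs.
#' @param frac_panel_absent fraction of variants removed from the panel.
#' @param frac_allele_mismatch fraction of variants whose panel alleles are
#'   made incompatible with the effect allele.
#' @param phenotype_id label for the synthetic phenotype.
#' @return validated `prs_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_variants = 1000,
                       weight_mean = 0, weight_sd = 0.05, weights = NULL,
                       populations = tibble(label = c("POPA", "POPB"),
                                            n_samples = c(100, 100),
                                            fst = c(0.05, 0.05)),
                       n_trios = 0, frac_panel_absent = 0,
                       frac_allele_mismatch = 0,
                       phenotype_id = "synthetic_phenotype") {
  populations <- as_tibble(populations)
  stopifnot(
    n_variants >= 1,
    all(c("label", "n_samples", "fst") %in% names(populations)),
    sum(populations$n_samples) >= 2,
    all(populations$fst >= 0 & populations$fst < 1),
    frac_panel_absent >= 0, frac_panel_absent <= 1,
    frac_allele_mismatch >= 0, frac_allele_mismatch <= 1,
    frac_panel_absent + frac_allele_mismatch <= 1
  )
  if (!is.null(weights)) stopifnot(length(weights) == n_variants,
                                   all(is.finite(weights)))
  structure(
    list(seed = as.integer(seed), n_variants = as.integer(n_variants),
         weight_mean = weight_mean, weight_sd = weight_sd, weights = weights,
         populations = populations, n_trios = as.integer(n_trios),
         frac_panel_absent = frac_panel_absent,
         frac_allele_mismatch = frac_allele_mismatch,
         phenotype_id = phenotype_id),
    class = "prs_sim_config"
  )
}

#' Simulate a scoring file with known harmonisation truth
#'
#' Variants are placed at spaced positions on one synthetic chromosome with
#' distinct effect/other alleles and weights from the configured
#' distribution. Exactly `round(frac * M)` variants are marked for panel
#' absence and (disjointly) allele mismatch; the truth record says which.
#'
#' @param config a `prs_sim_config`.
#' @param seed overrides `config$seed` when given.
#' @return list with `scoring_file` (a `prs_scoring_file`) and `truth`
#'   (tibble `variant_id`, `injected_status` in
#'   `present`/`panel_absent`/`allele_mismatch`).
#' @export
simulate_scoring_file <- function(config, seed = config$seed) {
  with_seed_if(seed, {
    m <- config$n_variants
    bases <- c("A", "C", "G", "T")
    other <- sample(bases, m, replace = TRUE)
    # effect allele: a uniformly chosen base distinct from `other`
    effect <- bases[(match(other, bases) - 1L + sample(1:3, m, replace = TRUE)) %% 4L + 1L]
    w <- config$weights %||% rnorm(m, config$weight_mean, config$weight_sd)
    variants <- tibble(
      chrom = "1",
      pos = 1000L + 100L * seq_len(m),
      variant_id = paste0("rs", seq_len(m)),
      effect_allele = effect,
      other_allele = other,
      effect_weight = w
    )
    n_absent <- round(config$frac_panel_absent * m)
    n_mismatch <- round(config$frac_allele_mismatch * m)
    marked <- sample(m, n_absent + n_mismatch)
    status <- rep("present", m)
    status[marked[seq_len(n_absent)]] <- "panel_absent"
    if (n_mismatch > 0) {
      status[marked[n_absent + seq_len(n_mismatch)]] <- "allele_mismatch"
    }
    list(
      scoring_file = scoring_file(variants, config$phenotype_id,
                                  source_id = "SIM000001"),
      truth = tibble(variant_id = variants$variant_id,
                     injected_status = status)
    )
  })
}

#' Simulate a stratified reference panel and cohort
#'
#' Per variant an ancestral alternate-allele frequency is drawn uniform on
#' `[0.05, 0.95]`; each population's frequency comes from the
#' Balding-Nichols beta around it (`Beta(p(1-F)/F, (1-p)(1-F)/F)`; at
#' `F = 0` the ancestral frequency is used unchanged). Genotypes are
#' Hardy-Weinberg draws given the population frequency. The panel REF is the
#' scoring file's other allele and ALT its effect allele, except at injected
#' mismatch sites (alleles rewritten to exclude the effect allele) and
#' injected absent sites (dropped from the panel; cohort genotypes at those
#' sites are still emitted, as a genome-wide call set would contain them).
#'
#' @param config a `prs_sim_config`.
#' @param sim_sf output of [simulate_scoring_file()] for this config.
#' @param seed overrides `config$seed + 1` when given.
#' @param cohort simulate cohort genotypes (set `FALSE` for a panel-only
#'   run, e.g. harmonisation studies at large M).
#' @return list: `panel` (site tibble), `genotypes` (`prs_genotypes`, or
#'   `NULL` when `cohort = FALSE`), `sample_map` (sample/pop/super_pop
#'   tibble), `freqs` (variant x population allele-frequency truth).
#' @export
simulate_panel_and_cohort <- function(config, sim_sf = simulate_scoring_file(config),
                                      seed = config$seed + 1L, cohort = TRUE) {
  with_seed_if(seed, {
    v <- sim_sf$scoring_file$variants
    truth <- sim_sf$truth
    m <- nrow(v)
    p0 <- runif(m, 0.05, 0.95)
    pops <- config$populations
    freqs <- purrr::map(seq_len(nrow(pops)), function(k) {
      f <- pops$fst[k]
      pk <- if (f == 0) p0 else {
        rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      }
      # keep frequencies away from fixation so backgrounds have variance
      pk <- pmin(pmax(pk, 1e-4), 1 - 1e-4)
      tibble(variant_id = v$variant_id, pop = pops$label[k], freq = pk)
    }) |> bind_rows()

    sample_map <- purrr::map(seq_len(nrow(pops)), function(k) {
      tibble(
        sample = sprintf("%s_%03d", pops$label[k], seq_len(pops$n_samples[k])),
        pop = pops$label[k],
        super_pop = pops$label[k]
      )
    }) |> bind_rows()

    sites <- tibble(chrom = v$chrom, pos = v$pos, ref = v$other_allele,
                    alt = v$effect_allele)
    genotypes <- NULL
    if (cohort) {
      gt <- matrix(NA_character_, nrow = m, ncol = nrow(sample_map),
                   dimnames = list(NULL, sample_map$sample))
      for (k in seq_len(nrow(pops))) {
        pk <- freqs$freq[freqs$pop == pops$label[k]]
        cols <- which(sample_map$pop == pops$label[k])
        for (j in cols) {
          d <- rbinom(m, 2, pk)
          gt[, j] <- c("0/0", "0/1", "1/1")[d + 1]
        }
      }
      genotypes <- genotype_set(sites, gt)
    }

    mismatch <- truth$injected_status == "allele_mismatch"
    panel <- sites |>
      mutate(alts = .data$alt) |>
      select("chrom", "pos", "ref", "alts")
    if (any(mismatch)) {
      bases <- c("A", "C", "G", "T")
      keep_ref <- v$other_allele[mismatch]
      repl <- purrr::map2_chr(v$effect_allele[mismatch], keep_ref,
                              function(e, r) sample(setdiff(bases, c(e, r)), 1))
      panel$ref[mismatch] <- keep_ref
      panel$alts[mismatch] <- repl
    }
    panel <- panel[truth$injected_status != "panel_absent", ]
    list(panel = panel, genotypes = genotypes, sample_map = sample_map,
         freqs = freqs)
  })
}

#' Draw extra genotypes from simulated population frequencies
#'
#' Used to sample target individuals from the same generative population as
#' a simulated background cohort.
#'
#' @param freqs frequency truth tibble from [simulate_panel_and_cohort()].
#' @param sim_sf matching [simulate_scoring_file()] output (supplies sites).
#' @param pop population label to draw from.
#' @param n number of samples.
#' @param prefix sample-ID prefix.
#' @return a `prs_genotypes` of the new samples.
#' @export
simulate_genotypes_from_freqs <- function(freqs, sim_sf, pop, n,
                                          prefix = paste0(pop, "_T")) {
  v <- sim_sf$scoring_file$variants
  pk <- freqs |> filter(.data$pop == !!pop)
  stopifnot(nrow(pk) == nrow(v))
  pk <- pk$freq[match(v$variant_id, pk$variant_id)]
  gt <- matrix(NA_character_, nrow = nrow(v), ncol = n,
               dimnames = list(NULL, sprintf("%s%03d", prefix, seq_len(n))))
  for (j in seq_len(n)) {
    d <- rbinom(nrow(v), 2, pk)
    gt[, j] <- c("0/0", "0/1", "1/1")[d + 1]
  }
  genotype_set(
    tibble(chrom = v$chrom, pos = v$pos, ref = v$other_allele,
           alt = v$effect_allele),
    gt
  )
}

#' Simulate a Mendelian child from two parents
#'
#' At each variant the child receives one allele from each parent, chosen
#' uniformly and independently; with dosage coding the transmitted allele
#' from a parent with dosage `g` is alternate with probability `g/2`.
#'
#' @param father,mother integer dosage vectors (0/1/2) over a shared variant
#'   set.
#' @param seed optional seed for reproducibility.
#' @return integer dosage vector for the child.
#' @export
simulate_trio <- function(father, mother, seed = NULL) {
  stopifnot(length(father) == length(mother),
            all(father %in% 0:2), all(mother %in% 0:2))
  with_seed_if(seed, {
    rbinom(length(father), 1, father / 2) + rbinom(length(mother), 1, mother / 2)
  })
}

#' Simulate a Mendelian child within a genotype set
#'
#' Allele-level transmission on GT strings: one of the parent's two alleles
#' is picked uniformly at each site, preserving multi-allelic codes.
#'
#' @param genotypes a `prs_genotypes` containing both parents.
#' @param father_id,mother_id parent sample IDs.
#' @param child_id sample ID for the new column.
#' @param seed optional seed.
#' @return `genotypes` with the child's column appended.
#' @export
simulate_trio_genotypes <- function(genotypes, father_id, mother_id, child_id,
                                    seed = NULL) {
  stopifnot(inherits(genotypes, "prs_genotypes"),
            all(c(father_id, mother_id) %in% genotypes$samples))
  with_seed_if(seed, {
    fa <- split_gt(genotypes$gt[, father_id])
    mo <- split_gt(genotypes$gt[, mother_id])
    if (anyNA(c(fa$a1, fa$a2, mo$a1, mo$a2))) {
      abort("parents must have complete diploid calls",
            class = "prspipe_ploidy_error")
    }
    n <- nrow(genotypes$sites)
    from_f <- if_else(runif(n) < 0.5, fa$a1, fa$a2)
    from_m <- if_else(runif(n) < 0.5, mo$a1, mo$a2)
    child <- paste0(from_f, "/", from_m)
    gt <- cbind(genotypes$gt, child)
    colnames(gt)[ncol(gt)] <- child_id
    genotype_set(genotypes$sites, gt, dp = NULL, gq = NULL)
  })
}

#' Write a genotype set as VCF
#'
#' Emits a minimal VCFv4.2 with GT (plus DP/GQ when present). Output is
#' bgzip-free gzip when the path ends in `.gz`, plain text otherwise.
#'
#' @param genotypes a `prs_genotypes`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  s <- genotypes$sites
  has_dp <- !is.null(genotypes$dp)
  has_gq <- !is.null(genotypes$gq)
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_gq) "GQ"), collapse = ":")
  meta <- c(
    "##fileformat=VCFv4.2",
    "##source=prspipe_simulator",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    if (has_gq) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'
  )
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", genotypes$samples), collapse = "\t")
  cells <- genotypes$gt
  if (has_dp) cells <- matrix(paste(cells, genotypes$dp, sep = ":"),
                              nrow = nrow(cells), dimnames = dimnames(cells))
  if (has_gq) cells <- matrix(paste(cells, genotypes$gq, sep = ":"),
                              nrow = nrow(cells), dimnames = dimnames(cells))
  body <- paste(
    s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS", ".", fmt,
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, header, body), con)
  invisible(path)
}

#' Write a sites-only panel VCF
#'
#' @param panel panel tibble (`chrom`, `pos`, `ref`, `alts`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  meta <- c("##fileformat=VCFv4.2", "##source=prspipe_simulator")
  header <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO"), collapse = "\t")
  body <- paste(panel$chrom, panel$pos, ".", panel$ref, panel$alts, ".",
                "PASS", ".", sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(meta, header, body), con)
  invisible(path)
}
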