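# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (loops, linear scans) so they stay independent of the vectorised
# implementation paths they check.

fix_scoring <- function(weights = c(0.1, -0.2, 0.3),
                        chrom = rep("1", length(weights)),
                        pos = 100 * seq_along(weights),
                        effect = rep("A", length(weights)),
                        other = rep("G", length(weights)),
                        phenotype = "fixture") {
  scoring_file(
    tibble::tibble(
      chrom = chrom, pos = pos,
      variant_id = paste0("rs", seq_along(weights)),
      effect_allele = effect, other_allele = other, effect_weight = weights
    ),
    phenotype_id = phenotype
  )
}

fix_panel <- function(chrom, pos, ref, alts) {
  tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alts = alts)
}

# background with known scores, bypassing cohort scoring
fix_background <- function(scores, n = length(scores), label = "BG",
                           phenotype = "fixture") {
  structure(
    list(phenotype_id = phenotype, population_label = label,
         n = n, scores = sort(scores)),
    class = "prs_background"
  )
}

# naive per-variant loop PRS oracle
oracle_prs <- function(weights, dosages, M) {
  s <- 0
  for (i in seq_along(weights)) s <- s + weights[i] * dosages[i]
  s / M
}

# brute-force percentile oracle (double loop)
oracle_percentile <- function(score, scores) {
  below <- 0
  equal <- 0
  for (s in scores) {
    if (s < score) below <- below + 1
    if (s == score) equal <- equal + 1
  }
  100 * (below + 0.5 * equal) / length(scores)
}

# linear-scan harmonisation status oracle
oracle_match <- function(variants, panel) {
  vapply(seq_len(nrow(variants)), function(i) {
    hit <- NULL
    for (j in seq_len(nrow(panel))) {
      if (panel$chrom[j] == variants$chrom[i] &&
          panel$pos[j] == variants$pos[i]) {
        hit <- j
        break
      }
    }
    if (is.null(hit)) return("missing_absent")
    if (variants$effect_allele[i] == panel$ref[hit]) return("matched_ref")
    alts <- strsplit(panel$alts[hit], ",", fixed = TRUE)[[1]]
    if (variants$effect_allele[i] %in% alts) return("matched_alt")
    "missing_allele_mismatch"
  }, character(1))
}

# metadata catalogue + configs shipped with the package
catalogue_meta <- function() {
  read_phenotype_meta(system.file("extdata", "phenotypes.yaml",
                                  package = "prspipe"))
}

catalogue_curation_config <- function() {
  read_curation_config(system.file("extdata", "curation_config.yaml",
                                   package = "prspipe"))
}

accounting_table <- function() {
  read_harmonization_accounting()
}

# small genotype set: sites tibble built from ref/alt vectors, genotypes
# given as a samples-named list of GT string vectors
fix_genotypes <- function(chrom, pos, ref, alt, gt_list, dp = NULL, gq = NULL) {
  gt <- do.call(cbind, gt_list)
  colnames(gt) <- names(gt_list)
  genotype_set(
    tibble::tibble(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = ref, alt = alt),
    gt, dp = dp, gq = gq
  )
}
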