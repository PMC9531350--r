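test_that("simulated scoring files are reproducible and round-trip through the parser", {
  cfg <- sim_config(seed = 101, n_variants = 500)
  a <- simulate_scoring_file(cfg)
  b <- simulate_scoring_file(cfg)
  expect_identical(a, b)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_scoring_file(a$scoring_file, path)
  back <- read_scoring_file(path, phenotype_id = a$scoring_file$phenotype_id)
  expect_equal(tidy(back), tidy(a$scoring_file))

  cfg_fixed <- sim_config(seed = 1, n_variants = 3,
                          weights = c(0.1, -0.2, 0.3))
  sf <- simulate_scoring_file(cfg_fixed)
  expect_equal(sf$scoring_file$variants$effect_weight, c(0.1, -0.2, 0.3))
})

test_that("injected harmonisation failures land in exact counts", {
  cfg <- sim_config(seed = 103, n_variants = 1000,
                    frac_panel_absent = 0.05, frac_allele_mismatch = 0.01)
  sf <- simulate_scoring_file(cfg)
  expect_equal(sum(sf$truth$injected_status == "panel_absent"), 50)
  expect_equal(sum(sf$truth$injected_status == "allele_mismatch"), 10)

  sim <- simulate_panel_and_cohort(cfg, sf, cohort = FALSE)
  h <- harmonize_phenotype(sf$scoring_file, sim$panel)
  st <- tidy(h)
  expect_equal(sum(st$status == "missing_absent"), 50)
  expect_equal(sum(st$status == "missing_allele_mismatch"), 10)
  expect_equal(h$missing_pct, 6.00)
  expect_false(h$pass_gate)

  # exact-count injection at the gate boundary
  cfg5 <- sim_config(seed = 104, n_variants = 200, frac_panel_absent = 0.05)
  sf5 <- simulate_scoring_file(cfg5)
  sim5 <- simulate_panel_and_cohort(cfg5, sf5, cohort = FALSE)
  h5 <- harmonize_phenotype(sf5$scoring_file, sim5$panel)
  expect_equal(h5$missing_pct, 5.00)
  expect_true(h5$pass_gate)
})

test_that("cohort artifacts are deterministic given the seed", {
  cfg <- sim_config(seed = 107, n_variants = 50,
                    populations = tibble::tibble(label = "P", n_samples = 10,
                                                 fst = 0.1))
  sf <- simulate_scoring_file(cfg)
  s1 <- simulate_panel_and_cohort(cfg, sf)
  s2 <- simulate_panel_and_cohort(cfg, sf)
  expect_identical(s1$genotypes$gt, s2$genotypes$gt)
  expect_identical(s1$freqs, s2$freqs)

  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(s1$genotypes, p1)
  write_genotypes_vcf(s2$genotypes, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("per-population allele frequencies are recovered empirically", {
  cfg <- sim_config(seed = 109, n_variants = 60,
                    populations = tibble::tibble(label = "P", n_samples = 1000,
                                                 fst = 0.15))
  sf <- simulate_scoring_file(cfg)
  sim <- simulate_panel_and_cohort(cfg, sf)
  h <- harmonize_phenotype(sf$scoring_file, sim$panel)
  dm <- dosage_matrix(sim$genotypes, h)
  emp <- rowMeans(dm$dosage) / 2
  truth <- sim$freqs$freq
  se <- sqrt(truth * (1 - truth) / (2 * 1000))
  expect_true(all(abs(emp - truth) < 4 * se + 1e-9))
})

test_that("zero divergence makes pooled genotype frequencies indistinguishable", {
  cfg <- sim_config(seed = 111, n_variants = 40,
                    populations = tibble::tibble(label = c("A", "B"),
                                                 n_samples = c(300, 300),
                                                 fst = c(0, 0)))
  sf <- simulate_scoring_file(cfg)
  sim <- simulate_panel_and_cohort(cfg, sf)
  h <- harmonize_phenotype(sf$scoring_file, sim$panel)
  dm <- dosage_matrix(sim$genotypes, h)
  a_cols <- sim$sample_map$pop == "A"
  pvals <- vapply(seq_len(40), function(i) {
    tbl <- rbind(
      tabulate(dm$dosage[i, a_cols] + 1, nbins = 3),
      tabulate(dm$dosage[i, !a_cols] + 1, nbins = 3)
    )
    tbl <- tbl[, colSums(tbl) > 0, drop = FALSE]
    suppressWarnings(stats::chisq.test(tbl)$p.value)
  }, numeric(1))
  # at alpha = 0.01 across 40 sites, a no-divergence cohort should almost
  # never reject more than a small handful
  expect_lte(sum(pvals < 0.01, na.rm = TRUE), 3)
})

test_that("population divergence shifts mean scores in the predicted direction", {
  agree <- logical(50)
  for (s in seq_len(50)) {
    cfg <- sim_config(seed = 200 + s, n_variants = 200,
                      populations = tibble::tibble(label = c("A", "B"),
                                                   n_samples = c(50, 50),
                                                   fst = c(0.2, 0.2)))
    sf <- simulate_scoring_file(cfg)
    sim <- simulate_panel_and_cohort(cfg, sf)
    h <- harmonize_phenotype(sf$scoring_file, sim$panel)
    sc <- score_cohort(sim$genotypes, h)
    mean_a <- mean(sc$raw_score[sim$sample_map$pop == "A"])
    mean_b <- mean(sc$raw_score[sim$sample_map$pop == "B"])
    w <- sf$scoring_file$variants$effect_weight
    fa <- sim$freqs$freq[sim$freqs$pop == "A"]
    fb <- sim$freqs$freq[sim$freqs$pop == "B"]
    predicted <- sum(w * 2 * (fa - fb)) / length(w)
    agree[s] <- sign(mean_a - mean_b) == sign(predicted)
  }
  # weights correlated with frequency shifts move the means; sampling noise
  # can flip the sign only when the predicted shift is tiny
  expect_gte(sum(agree), 40)
})

test_that("trio simulation is Mendelian at every site", {
  set.seed(71)
  f <- sample(0:2, 500, TRUE)
  m <- sample(0:2, 500, TRUE)
  child <- simulate_trio(f, m, seed = 7)
  expect_identical(child, simulate_trio(f, m, seed = 7))
  from_f_min <- as.integer(f == 2); from_f_max <- as.integer(f >= 1)
  from_m_min <- as.integer(m == 2); from_m_max <- as.integer(m >= 1)
  expect_true(all(child >= from_f_min + from_m_min))
  expect_true(all(child <= from_f_max + from_m_max))
  expect_identical(simulate_trio(rep(2L, 10), rep(2L, 10)), rep(2L, 10))
  expect_identical(simulate_trio(rep(0L, 10), rep(0L, 10)), rep(0L, 10))
})

test_that("het x het parents give the 1:2:1 child dosage distribution", {
  set.seed(73)
  child <- simulate_trio(rep(1L, 10000), rep(1L, 10000))
  counts <- tabulate(child + 1, nbins = 3)
  expected <- c(2500, 5000, 2500)
  se <- sqrt(10000 * c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75))
  expect_true(all(abs(counts - expected) <= 3 * se))
})

test_that("allele-level trio simulation is consistent with its parents", {
  cfg <- sim_config(seed = 117, n_variants = 300,
                    populations = tibble::tibble(label = "P", n_samples = 2,
                                                 fst = 0.05))
  sf <- simulate_scoring_file(cfg)
  sim <- simulate_panel_and_cohort(cfg, sf)
  g <- simulate_trio_genotypes(sim$genotypes, "P_001", "P_002", "CHILD",
                               seed = 9)
  al_c <- do.call(rbind, strsplit(g$gt[, "CHILD"], "/", fixed = TRUE))
  al_f <- do.call(rbind, strsplit(g$gt[, "P_001"], "/", fixed = TRUE))
  al_m <- do.call(rbind, strsplit(g$gt[, "P_002"], "/", fixed = TRUE))
  ok <- vapply(seq_len(nrow(al_c)), function(i) {
    al_c[i, 1] %in% al_f[i, ] && al_c[i, 2] %in% al_m[i, ]
  }, logical(1))
  expect_true(all(ok))
})
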