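test_that("config validation rejects degenerate settings", {
  expect_error(cohort_config(maf_range = c(0, 0)), class = "hologuild_invalid_config")
  expect_error(cohort_config(n_animals = 1), class = "hologuild_invalid_config")
  expect_error(cohort_config(taxon_h2 = 1), class = "hologuild_invalid_config")
  expect_error(cohort_config(n_causal_variants = 10, n_variants = 5),
               class = "hologuild_invalid_config")
  expect_error(cohort_config(n_differential = c(10, 10, 10),
                             n_features_per_layer = c(5, 50, 50)),
               class = "hologuild_invalid_config")
})

test_that("genotype frequencies follow the binomial law at maf 0.5", {
  cfg <- cohort_config(n_animals = 1e5, n_variants = 1L,
                       maf_range = c(0.5, 0.5), n_causal_variants = 1L,
                       seed = 7L)
  g <- simulate_genotypes(cfg)$geno
  freq <- table(factor(g, levels = c(-1, 0, 1))) / length(g)
  mc_sd <- sqrt(0.25 * 0.75 / 1e5)
  expect_lt(abs(freq[["-1"]] - 0.25), 3 * mc_sd)
  expect_lt(abs(freq[["1"]] - 0.25), 3 * mc_sd)
  expect_lt(abs(freq[["0"]] - 0.5), 3 * sqrt(0.5 * 0.5 / 1e5))
})

test_that("identical seed and config give identical outputs across all ops", {
  cfg <- cohort_config(n_animals = 40, n_variants = 60,
                       n_causal_variants = 4,
                       n_features_per_layer = c(30, 30, 20),
                       n_differential = c(6, 6, 4), seed = 11L)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$tables, b$tables)
  # byte-identical TSV export
  fa <- withr::local_tempfile(fileext = ".tsv")
  fb <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(a$tables$MTB, fa)
  write_feature_table(b$tables$MTB, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("null causal chain shows no taxon-phenotype association", {
  cfg <- cohort_config(n_animals = 4000, n_variants = 50,
                       n_causal_variants = 5,
                       theta_taxon_to_mediator = 0,
                       delta_mediator_to_phenotype = 0, gamma_direct = 0,
                       seed = 3L)
  ch <- simulate_causal_chain(simulate_genotypes(cfg), cfg)
  expect_lt(abs(cor(ch$cohort$taxon, ch$cohort$phenotype)),
            3 / sqrt(cfg$n_animals))
})

test_that("noise-free limit makes the mediator an exact multiple of the taxon", {
  cfg <- cohort_config(n_animals = 50, n_variants = 30, n_causal_variants = 3,
                       theta_taxon_to_mediator = 0.5, noise_sd = 0,
                       pleiotropy_frac = 0, seed = 5L)
  ch <- simulate_causal_chain(simulate_genotypes(cfg), cfg)
  expect_equal(ch$cohort$mediator, 0.5 * ch$cohort$taxon, tolerance = 1e-12)
})

test_that("realized taxon heritability matches the configured value", {
  cfg <- cohort_config(n_animals = 5000, n_variants = 120,
                       n_causal_variants = 20, taxon_h2 = 0.3, seed = 9L)
  g <- simulate_genotypes(cfg)
  ch <- simulate_causal_chain(g, cfg)
  score <- as.numeric(g$geno[, ch$truth$causal_variant_ids] %*% ch$truth$alpha)
  r2 <- summary(lm(ch$cohort$taxon ~ score))$r.squared
  expect_lt(abs(r2 - 0.3), 0.02)
})

test_that("truth ledger ids all resolve in the emitted tables", {
  cfg <- cohort_config(n_animals = 40, n_variants = 80, n_causal_variants = 5,
                       n_features_per_layer = c(40, 40, 30),
                       n_differential = c(8, 8, 6), seed = 13L)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$causal_variant_ids %in%
                    co$genotypes$variants$variant_id))
  for (layer in names(co$tables)) {
    expect_true(all(co$truth$differential[[layer]]$feature_id %in%
                      co$tables[[layer]]$feature_id))
    expect_true(all(co$truth$group_species[[layer]] %in%
                      co$annotations[[layer]]$species))
  }
  expect_equal(co$truth$acme, co$truth$theta * co$truth$delta)
  # metabolite origin labels stay in the four classes, similarity straddles 200
  org <- co$annotations$MTB$origin
  expect_true(all(org %in% c("microbiota", "host", "co-metabolism", "others")))
  expect_true(any(co$annotations$MTB$similarity < 200) &&
                any(co$annotations$MTB$similarity > 200))
})

test_that("tables with no planted effect yield essentially no BH discoveries", {
  cfg <- cohort_config(n_features_per_layer = c(150, 150, 60),
                       n_differential = c(0, 0, 0), seed = 21L)
  layers <- simulate_feature_tables(cfg)
  res <- diff_test(normalize_cpm(layers$tables$MTP), layers$samples)
  expect_lte(sum(res$significant), 2)
})

test_that("PLINK and VCF round trips preserve the coded genotypes", {
  cfg <- cohort_config(n_animals = 15, n_variants = 25, n_causal_variants = 2,
                       seed = 17L)
  g <- simulate_genotypes(cfg)
  pre <- withr::local_tempfile()
  write_plink(g, pre)
  back <- read_plink(pre)
  expect_identical(unname(back$geno), unname(g$geno))
  expect_identical(back$variants$variant_id, g$variants$variant_id)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, vcf)
  back2 <- read_vcf_genotypes(vcf)
  expect_identical(unname(back2$geno[rownames(g$geno), ]), unname(g$geno))
})
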