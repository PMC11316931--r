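scan_row <- function(id, beta, se, p, p_adj, maf = 0.3) {
  tibble::tibble(variant_id = id, chrom = 1L, pos = 1L,
                 effect_allele = "B", other_allele = "A",
                 beta = beta, se = se, p = p, p_adj = p_adj, maf = maf,
                 n = 100L)
}

test_that("instrument selection prunes LD and respects the threshold", {
  set.seed(50)
  g1 <- rbinom(200, 2, 0.3) - 1L
  G <- cbind(v1 = g1, v2 = g1,                       # perfect LD pair
             v3 = rbinom(200, 2, 0.3) - 1L)
  genos <- make_geno(G)
  summ <- dplyr::bind_rows(
    scan_row("v1", 0.5, 0.05, 1e-8, 1e-6),
    scan_row("v2", 0.45, 0.05, 1e-6, 1e-4),
    scan_row("v3", 0.4, 0.05, 1e-5, 1e-3 - 1e-9)
  )
  iv <- select_instruments(summ, genos, p_adj_max = 0.001)
  expect_true("v1" %in% iv && !"v2" %in% iv)   # smaller p wins the LD pair
  expect_true("v3" %in% iv)
  expect_error(select_instruments(summ, genos, p_adj_max = 0),
               class = "hologuild_empty_instruments")
  # 28 mutually independent variants below threshold -> 28 instruments
  set.seed(51)
  G28 <- matrix(rbinom(500 * 28, 2, 0.3) - 1L, 500, 28)
  genos28 <- make_geno(G28)
  summ28 <- dplyr::bind_rows(lapply(seq_len(28), function(j) {
    scan_row(sprintf("v%04d", j), 0.3, 0.05, 1e-8, 1e-5)
  }))
  expect_length(select_instruments(summ28, genos28, p_adj_max = 0.001), 28)
})

test_that("harmonization aligns alleles and drops ambiguous palindromes", {
  ex <- dplyr::bind_rows(
    scan_row("v1", 0.5, 0.05, 1e-8, 1e-6),
    scan_row("v2", 0.4, 0.05, 1e-8, 1e-6),
    scan_row("v3", 0.3, 0.05, 1e-8, 1e-6, maf = 0.5)
  )
  ex$effect_allele <- c("G", "C", "A")
  ex$other_allele <- c("A", "T", "T")        # v3 is A/T palindromic, MAF 0.5
  ou <- ex
  ou$beta <- c(0.1, 0.3, 0.2)
  # v2 arrives with swapped alleles
  ou$effect_allele <- c("G", "T", "A")
  ou$other_allele <- c("A", "C", "T")
  h <- harmonize_instruments(ex, ou)
  expect_setequal(h$variant_id, c("v1", "v2"))
  expect_equal(h$beta_outcome[h$variant_id == "v1"], 0.1)   # unchanged
  expect_equal(h$beta_outcome[h$variant_id == "v2"], -0.3)  # sign flipped
})

test_that("IVW reduces to the Wald ratio and matches the WLS oracle", {
  h1 <- make_harmonized(0.5, 0.1, sy = 0.05)
  est <- mr_ivw(h1)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  expect_equal(est$se, 0.1, tolerance = 1e-12)
  # consensus ratios: estimate equals the shared ratio regardless of weights
  h2 <- make_harmonized(c(0.2, 0.5, 0.9), 0.2 * c(0.2, 0.5, 0.9),
                        sy = c(0.02, 0.07, 0.04))
  expect_equal(mr_ivw(h2)$beta, 0.2, tolerance = 1e-12)
  # three-instrument WLS-through-origin oracle
  h3 <- make_harmonized(c(0.4, 0.5, 0.3), c(0.12, 0.10, 0.03),
                        sy = c(0.05, 0.04, 0.06))
  wls <- lm(beta_outcome ~ 0 + beta_exposure, data = h3,
            weights = 1 / h3$se_outcome^2)
  expect_equal(mr_ivw(h3)$beta, unname(coef(wls)), tolerance = 1e-10)
})

test_that("MR-Egger fits the exact line and needs three instruments", {
  bx <- c(0.2, 0.35, 0.5, 0.65)
  h <- make_harmonized(bx, 0.1 + 0.3 * bx, sy = 0.05)
  est <- mr_egger(h)
  expect_equal(est$beta, 0.3, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(make_harmonized(c(0.2, 0.3), c(0.1, 0.2))),
               class = "hologuild_insufficient_instruments")
})

test_that("weighted median interpolates the weighted ratio distribution", {
  h <- make_harmonized(c(1, 1, 1), c(0.1, 0.2, 0.9), sy = 1)
  est <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  # consensus data returns the shared ratio
  hc <- make_harmonized(c(0.3, 0.5, 0.8), 0.25 * c(0.3, 0.5, 0.8), sy = 0.05)
  expect_equal(mr_weighted_median(hc, n_boot = 100, seed = 1)$beta, 0.25,
               tolerance = 1e-10)
  # estimate always lies inside the ratio range
  set.seed(52)
  for (r in 1:10) {
    hh <- make_harmonized(runif(8, 0.2, 0.6), rnorm(8, 0.1, 0.2), sy = 0.05)
    est_r <- mr_weighted_median(hh, n_boot = 50, seed = r)$beta
    expect_gte(est_r, min(hh$wald_ratio))
    expect_lte(est_r, max(hh$wald_ratio))
  }
})

test_that("mode-based estimators find the dominant ratio cluster", {
  hc <- make_harmonized(rep(0.5, 4), rep(0.5 * 0.7, 4), sy = 0.05)
  expect_equal(mr_mode(hc, n_boot = 50, seed = 1)$beta, 0.7, tolerance = 1e-12)
  set.seed(53)
  bx <- rep(0.5, 10)
  ratios <- c(rnorm(7, 0.2, 0.01), rnorm(3, 0.9, 0.01))
  hb <- make_harmonized(bx, bx * ratios, sy = 0.05)
  m_simple <- mr_mode(hb, weighted = FALSE, n_boot = 50, seed = 2)$beta
  expect_gt(m_simple, 0.17)
  expect_lt(m_simple, 0.23)
  # equal weights: simple and weighted modes agree
  heq <- make_harmonized(rep(0.4, 6), 0.4 * c(0.1, 0.12, 0.11, 0.3, 0.32, 0.5),
                         sy = 0.05)
  expect_equal(mr_mode(heq, weighted = FALSE, n_boot = 50, seed = 3)$beta,
               mr_mode(heq, weighted = TRUE, n_boot = 50, seed = 3)$beta,
               tolerance = 1e-10)
})

test_that("five-method report agrees on consensus data and flags k = 1", {
  h <- make_harmonized(c(0.3, 0.45, 0.6, 0.25), 0.2 * c(0.3, 0.45, 0.6, 0.25),
                       sy = 0.05)
  rep5 <- mr_report(h, n_boot = 100, seed = 4)
  est <- rep5$estimates
  expect_true(all(abs(est$beta - 0.2) < 1e-6))
  expect_equal(rep5$Q, 0, tolerance = 1e-12)
  # single instrument: IVW only, others flagged insufficient
  rep1 <- mr_report(h[1, ], n_boot = 50, seed = 5)
  expect_false(rep1$estimates$insufficient[rep1$estimates$method == "IVW"])
  expect_true(all(rep1$estimates$insufficient[rep1$estimates$method != "IVW"]))
  expect_equal(rep1$estimates$beta[rep1$estimates$method == "IVW"], 0.2,
               tolerance = 1e-12)
})

test_that("causal estimates are scale equivariant in the exposure effects", {
  set.seed(54)
  bx <- runif(10, 0.2, 0.6)
  by <- 0.3 * bx + rnorm(10, 0, 0.01)
  h <- make_harmonized(bx, by, sx = 0.02, sy = 0.03)
  h2 <- h
  h2$beta_exposure <- h$beta_exposure * 4
  h2$se_exposure <- h$se_exposure * 4
  h2$wald_ratio <- h2$beta_outcome / h2$beta_exposure
  for (f in list(mr_ivw,
                 mr_egger,
                 function(x) mr_weighted_median(x, n_boot = 50, seed = 6),
                 function(x) mr_mode(x, n_boot = 50, seed = 6))) {
    expect_equal(f(h2)$beta, f(h)$beta / 4, tolerance = 1e-6)
  }
})
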