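test_that("Shannon index matches direct formula evaluation", {
  expect_equal(shannon_index(c(5, 5, 5, 5)), log(4), tolerance = 1e-12)
  expect_equal(shannon_index(c(10)), 0)
  expect_equal(shannon_index(c(2, 1, 1)), 1.5 * log(2), tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), class = "hologuild_degenerate")
  # maximal at uniform composition
  set.seed(1)
  for (r in 1:20) {
    x <- rexp(6)
    expect_lte(shannon_index(x), log(6) + 1e-12)
  }
})

test_that("classic Chao1 follows the singleton/doubleton formula", {
  expect_equal(chao1_richness(c(5, 5, 5)), 3)
  expect_equal(chao1_richness(c(1, 1, 2, 5)), 6)
  expect_equal(chao1_richness(c(1, 2, 3)), 3.5)
  expect_error(chao1_richness(c(1.5, 2)), class = "hologuild_input_error")
  # never below observed richness
  set.seed(2)
  for (r in 1:20) {
    x <- rpois(15, 2)
    if (sum(x) == 0) next
    expect_gte(chao1_richness(x), sum(x > 0))
  }
})

test_that("Bray-Curtis matches its formula and is a bounded symmetric index", {
  m <- rbind(a = c(1, 2), b = c(2, 1))
  expect_equal(bray_curtis(m)[1, 2], 2 / 6, tolerance = 1e-12)
  same <- rbind(x = c(3, 1, 4), y = c(3, 1, 4))
  expect_equal(bray_curtis(same)[1, 2], 0)
  disjoint <- rbind(x = c(1, 0), y = c(0, 7))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
  set.seed(3)
  mm <- matrix(rexp(40), nrow = 8)
  d <- bray_curtis(mm)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 8))
  expect_error(bray_curtis(rbind(c(0, 0), c(0, 0))),
               class = "hologuild_degenerate")
})

test_that("PCA scores reproduce rank and reconstruction identities", {
  # collinear two-feature data: PC1 explains everything
  x <- rnorm(10)
  res <- pca_scores(cbind(x, 2 * x))
  expect_equal(res$explained[1], 1, tolerance = 1e-12)
  # duplicated samples land on identical coordinates
  m <- matrix(rnorm(20), nrow = 5)
  m <- rbind(m, m[1, ])
  sc <- pca_scores(m)$scores
  expect_equal(as.numeric(sc[6, -1]), as.numeric(sc[1, -1]), tolerance = 1e-10)
  # full reconstruction of the centred data
  set.seed(4)
  m2 <- matrix(rnorm(40), nrow = 10)
  fit <- pca_scores(m2)$fit
  recon <- fit$x %*% t(fit$rotation)
  expect_equal(recon, scale(m2, center = TRUE, scale = FALSE),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_scores(m2[1, , drop = FALSE]),
               class = "hologuild_input_error")
})

test_that("PERMANOVA equals the direct sum-of-squares computation", {
  set.seed(5)
  m <- matrix(rexp(6 * 4), nrow = 6)
  rownames(m) <- sprintf("s%d", 1:6)
  d <- bray_curtis(m)
  groups <- rep(c("a", "b"), each = 3)
  fit <- permanova(d, groups, n_perm = 99, seed = 1)
  oracle <- permanova_f_oracle(d, groups)
  expect_equal(fit$pseudo_F, oracle$F, tolerance = 1e-10)
  expect_equal(fit$R2, oracle$R2, tolerance = 1e-10)
})

test_that("PERMANOVA saturates under perfect separation and is scale invariant", {
  pts <- rbind(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
               matrix(rep(c(10, 10), 10), ncol = 2, byrow = TRUE))
  d <- as.matrix(dist(pts))
  groups <- rep(c("a", "b"), each = 10)
  fit <- permanova(d, groups, n_perm = 199, seed = 2)
  expect_equal(fit$R2, 1, tolerance = 1e-10)
  expect_equal(fit$p_perm, 1 / 200, tolerance = 1e-12)
  # scaling the distances changes neither F nor R2
  set.seed(6)
  m <- matrix(rexp(7 * 28), nrow = 7)
  d2 <- as.matrix(dist(m))
  g2 <- c("a", "a", "a", "b", "b", "b", "b")
  f1 <- permanova(d2, g2, n_perm = 49, seed = 3)
  f2 <- permanova(d2 * 7.3, g2, n_perm = 49, seed = 3)
  expect_equal(f1$pseudo_F, f2$pseudo_F, tolerance = 1e-10)
  expect_equal(f1$R2, f2$R2, tolerance = 1e-10)
  expect_equal(f1$p_perm, f2$p_perm)
  expect_error(permanova(d2, c("a", rep("b", 6)), n_perm = 9),
               class = "hologuild_invalid_design")
})

test_that("PERMDISP separates unequal dispersions but not translated clouds", {
  set.seed(7)
  base <- matrix(rnorm(20 * 4), ncol = 4)
  shifted <- sweep(base, 2, rep(50, 4), "+")
  d_same <- as.matrix(dist(rbind(base, shifted)))
  groups <- rep(c("a", "b"), each = 20)
  res_same <- permdisp(d_same, groups, n_perm = 199, seed = 8)
  expect_gt(res_same$p_perm, 0.2)
  d_diff <- as.matrix(dist(rbind(base, base * 5)))
  res_diff <- permdisp(d_diff, groups, n_perm = 199, seed = 9)
  expect_lte(res_diff$p_perm, 0.05)
  expect_gte(res_diff$p_perm, 1 / 200)
})

test_that("log2(F/q) effect size is exact arithmetic with a resolution floor", {
  expect_equal(effect_size_log2fq(8, 0.03125), 8)
  expect_equal(effect_size_log2fq(1, 1), 0)
  expect_equal(effect_size_log2fq(2.5, 0.004), log2(625), tolerance = 1e-12)
  # q below the permutation resolution is floored
  expect_equal(effect_size_log2fq(4, 1e-6, n_perm = 999),
               log2(4 * 1000))
  expect_error(effect_size_log2fq(0, 0.5), class = "hologuild_input_error")
  expect_error(effect_size_log2fq(2, 0), class = "hologuild_input_error")
})
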