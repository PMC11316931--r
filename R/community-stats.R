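#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over the positive proportions, natural log.
#'
#' @param counts Non-negative numeric vector of abundances.
#' @return The Shannon index (nats).
#' @export
shannon_index <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts)) {
    hg_abort("counts must be non-negative and complete", "input_error")
  }
  if (sum(counts) <= 0) hg_abort("all-zero abundance vector", "degenerate")
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' Classic Chao1 richness estimator
#'
#' `S_obs + F1^2 / (2 F2)` with singleton count `F1` and doubleton count
#' `F2`; when no doubletons exist the bias-controlled fallback
#' `S_obs + F1 (F1 - 1) / 2` is used. This is the classic (uncorrected)
#' form, not the +1-corrected variant some toolkits report.
#'
#' @param counts Non-negative integer vector of counts.
#' @return The Chao1 richness estimate.
#' @export
chao1_richness <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0) || anyNA(counts) ||
      any(counts != floor(counts))) {
    hg_abort("Chao1 needs non-negative integer counts", "input_error")
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all sample pairs.
#'
#' @param mat Samples x features non-negative matrix (or wide feature tibble,
#'   which is transposed internally).
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(mat) {
  if (is_tibble(mat) || is.data.frame(mat)) mat <- t(ft_matrix(mat))
  if (any(mat < 0)) hg_abort("negative abundances", "input_error")
  zero <- rowSums(mat) == 0
  if (sum(zero) >= 2) {
    hg_abort("at least two all-zero samples: Bray-Curtis undefined for that pair",
             "degenerate")
  }
  as.matrix(vegan::vegdist(mat, method = "bray"))
}

#' Principal component scores of a feature matrix
#'
#' Column-centred (not scaled) singular value decomposition of a samples x
#' features matrix.
#'
#' @param mat Samples x features matrix (or wide feature tibble, transposed
#'   internally so samples are rows).
#' @return List with `scores` (tibble: sample_id, PC1..), `explained`
#'   (variance fractions, non-increasing), and the `prcomp` fit.
#' @export
pca_scores <- function(mat) {
  if (is_tibble(mat) || is.data.frame(mat)) mat <- t(ft_matrix(mat))
  if (nrow(mat) < 2) hg_abort("PCA needs at least two samples", "input_error")
  fit <- prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x)
  scores <- dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(mat) %||% as.character(seq_len(nrow(mat)))),
    scores
  )
  list(scores = scores, explained = expl, fit = fit)
}

#' PERMANOVA on a distance matrix
#'
#' One-factor permutational multivariate analysis of variance: the total sum
#' of squares is decomposed from squared inter-sample distances, the
#' pseudo-F statistic is `(SS_between / (a - 1)) / (SS_within / (N - a))`,
#' and its p-value comes from free permutation of the group labels with the
#' observed statistic included in the null set, so `p >= 1 / (n_perm + 1)`.
#' Computed with [vegan::adonis2()].
#'
#' @param dist_mat Square distance matrix (or `dist`).
#' @param groups Factor-like group labels, >= 2 levels with >= 2 members each.
#' @param n_perm Number of permutations (999 by default).
#' @param seed Integer seed for the permutation stream.
#' @return A list of class `permanova_fit`: `pseudo_F`, `R2`, `p_perm`,
#'   `df`, `n_permutations`.
#' @export
permanova <- function(dist_mat, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(dist_mat)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size")) {
    hg_abort("groups length must match the distance matrix", "invalid_design")
  }
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    hg_abort("need >= 2 groups with >= 2 members each", "invalid_design")
  }
  check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(grp = groups)
  fit <- vegan::adonis2(d ~ grp, data = df, permutations = n_perm)
  structure(list(
    pseudo_F = fit$F[1],
    R2 = fit$R2[1],
    p_perm = fit$`Pr(>F)`[1],
    df = c(between = fit$Df[1], within = fit$Df[2]),
    n_permutations = n_perm
  ), class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("<permanova> pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d perms)\n",
              x$pseudo_F, x$R2, x$p_perm, x$n_permutations))
  invisible(x)
}

#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(term = "group", pseudo_F = x$pseudo_F, R2 = x$R2,
                 p_perm = x$p_perm, df_between = x$df[["between"]],
                 df_within = x$df[["within"]],
                 n_permutations = x$n_permutations)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the samples by principal coordinates (negative-eigenvalue axes
#' handled as in [vegan::betadisper()]), computes each sample's distance to
#' its group centroid, and permutation-tests the one-way F statistic on
#' those distances.
#'
#' @inheritParams permanova
#' @return List of class `permdisp_fit`: `F`, `p_perm`, `n_permutations`.
#' @export
permdisp <- function(dist_mat, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(dist_mat)
  groups <- as.factor(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    hg_abort("need >= 2 groups with >= 2 members each", "invalid_design")
  }
  check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  bd <- vegan::betadisper(d, groups, type = "centroid")
  pt <- vegan::permutest(bd, permutations = n_perm)
  structure(list(
    F = pt$tab$F[1],
    p_perm = pt$tab$`Pr(>F)`[1],
    n_permutations = n_perm
  ), class = "permdisp_fit")
}

#' @export
print.permdisp_fit <- function(x, ...) {
  cat(sprintf("<permdisp> F = %.4f, p = %.4g (%d perms)\n",
              x$F, x$p_perm, x$n_permutations))
  invisible(x)
}

#' log2(pseudo-F / q) effect size
#'
#' Effect-size summary for a PERMANOVA comparison: the pseudo-F statistic
#' divided by its (BH-adjusted) permutation p-value, on the log2 scale. `q`
#' is floored at the permutation resolution `1 / (n_perm + 1)` before
#' division so the statistic stays finite.
#'
#' @param pseudo_F Positive pseudo-F statistic.
#' @param q Adjusted permutation p-value in (0, 1].
#' @param n_perm Number of permutations behind `q` (optional; enables the
#'   resolution floor).
#' @return `log2(pseudo_F / q)`.
#' @export
effect_size_log2fq <- function(pseudo_F, q, n_perm = NULL) {
  if (!is.numeric(pseudo_F) || any(pseudo_F <= 0)) {
    hg_abort("pseudo_F must be > 0", "input_error")
  }
  if (!is.numeric(q) || any(q <= 0) || any(q > 1)) {
    hg_abort("q must be in (0, 1]", "input_error")
  }
  if (!is.null(n_perm)) q <- pmax(q, 1 / (n_perm + 1))
  log2(pseudo_F / q)
}
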