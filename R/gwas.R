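#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the heterozygote count given the allele counts
#' (the standard recurrence over all heterozygote counts of matching parity);
#' the p-value is the summed probability of all outcomes no more likely than
#' the observed one.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (AA, AB, BB).
#' @return The exact HWE p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  rare <- min(n_a, n_b)
  hets <- seq(rare %% 2, rare, by = 2)
  # unnormalized probabilities via the symmetric recurrence
  #  P(h+2)/P(h) = 4 * n_hom_rare(h) * n_hom_common(h) / ((h+2) * (h+1))
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1]
    hom_r <- (rare - h) / 2            # rare-allele homozygotes at h hets
    hom_c <- n - (rare + h) / 2        # common-allele homozygotes at h hets
    lp[k] <- lp[k - 1] +
      log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- match(n_ab, hets)
  if (is.na(obs)) hg_abort("heterozygote count incompatible with allele counts",
                           "input_error")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Variant quality control
#'
#' Removes variants with minor allele frequency below `maf_min`, missingness
#' above `missing_max`, or exact-test Hardy-Weinberg p below `hwe_alpha`.
#'
#' @param genos A `geno_matrix` (entries -1/0/1, `NA` for missing).
#' @param maf_min Minimum minor-allele frequency.
#' @param missing_max Maximum missing fraction.
#' @param hwe_alpha HWE exact-test threshold.
#' @return The filtered `geno_matrix`, with a `qc_report` attribute (tibble:
#'   variant_id, maf, missingness, hwe_p, removed_by).
#' @export
qc_variants <- function(genos, maf_min = 0.05, missing_max = 0.1,
                        hwe_alpha = 1e-6) {
  G <- genos$geno
  miss <- colMeans(is.na(G))
  freq_b <- colMeans(G + 1L, na.rm = TRUE) / 2
  maf <- pmin(freq_b, 1 - freq_b)
  hwe_p <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    hwe_exact_test(sum(g == -1L, na.rm = TRUE), sum(g == 0L, na.rm = TRUE),
                   sum(g == 1L, na.rm = TRUE))
  }, numeric(1))
  removed_by <- dplyr::case_when(
    maf < maf_min ~ "maf",
    miss > missing_max ~ "missingness",
    hwe_p < hwe_alpha ~ "hwe",
    TRUE ~ NA_character_
  )
  keep <- is.na(removed_by)
  if (!any(keep)) hg_abort("all variants removed by QC", "empty_panel")
  report <- tibble::tibble(variant_id = colnames(G), maf = maf,
                           missingness = miss, hwe_p = hwe_p,
                           removed_by = removed_by)
  out <- structure(list(geno = G[, keep, drop = FALSE],
                        variants = genos$variants[keep, , drop = FALSE]),
                   class = "geno_matrix")
  attr(out, "qc_report") <- report
  out
}

#' Genomic relationship (kinship) matrix
#'
#' VanRaden-style genomic relationship matrix `G = W W' / c` with `W` the
#' column-centred -1/0/1 coding (missing entries mean-imputed per variant)
#' and `c = sum(2 p_k (1 - p_k))` over realized allele frequencies.
#'
#' @param genos A `geno_matrix`.
#' @return Symmetric positive semidefinite animals x animals matrix.
#' @export
kinship_matrix <- function(genos) {
  W <- genos$geno
  storage.mode(W) <- "double"
  mu <- colMeans(W, na.rm = TRUE)
  for (j in which(colSums(is.na(W)) > 0)) {
    W[is.na(W[, j]), j] <- mu[j]
  }
  p <- (mu + 1) / 2
  c0 <- sum(2 * p * (1 - p))
  if (c0 <= 0) hg_abort("zero scaling constant (monomorphic panel)",
                        "degenerate")
  W <- sweep(W, 2, mu)
  tcrossprod(W) / c0
}

#' REML fit of the null polygenic model
#'
#' Fits `y = mu + a + e` with `a ~ N(0, K sigma_a2)` and
#' `e ~ N(0, I sigma_e2)` by restricted maximum likelihood, using a single
#' spectral decomposition of the kinship matrix and one-dimensional
#' optimization of the profiled REML criterion in the variance ratio
#' `delta = sigma_e2 / sigma_a2` (EMMA-style).
#'
#' @param trait Numeric trait vector.
#' @param kinship Kinship matrix from [kinship_matrix()], or a precomputed
#'   eigendecomposition (list with `values`, `vectors`) to reuse across
#'   traits.
#' @return List of class `reml_fit`: `sigma_a2`, `sigma_e2`, `lambda_ratio`
#'   (`sigma_e2 / sigma_a2`), `h2`, `loglik`, `loglik_fun` (the REML
#'   criterion as a function of `delta`), and the eigendecomposition.
#' @export
fit_null_reml <- function(trait, kinship) {
  if (!is.numeric(trait) || anyNA(trait) || any(!is.finite(trait))) {
    hg_abort("trait must be finite and complete", "input_error")
  }
  ek <- if (is.list(kinship) && !is.null(kinship$vectors)) {
    kinship
  } else {
    if (length(trait) != nrow(kinship)) {
      hg_abort("trait length must match kinship dimension", "input_error")
    }
    eigen(kinship, symmetric = TRUE)
  }
  n <- length(trait)
  d <- pmax(ek$values, 0)
  ys <- as.numeric(crossprod(ek$vectors, trait))
  xs <- as.numeric(crossprod(ek$vectors, rep(1, n)))
  p <- 1L

  loglik <- function(delta) {
    w <- 1 / (d + delta)
    xwx <- sum(w * xs^2)
    beta <- sum(w * xs * ys) / xwx
    r <- ys - xs * beta
    rss <- sum(w * r^2)
    0.5 * ((n - p) * log((n - p) / (2 * pi)) - (n - p) -
             (n - p) * log(rss) + sum(log(w)) - log(xwx))
  }
  opt <- optimize(function(ld) loglik(exp(ld)), interval = c(-12, 12),
                  maximum = TRUE, tol = 1e-8)
  cand <- c(exp(opt$maximum), exp(-12), exp(12))
  ll <- vapply(cand, loglik, numeric(1))
  delta <- cand[which.max(ll)]
  w <- 1 / (d + delta)
  beta <- sum(w * xs * ys) / sum(w * xs^2)
  rss <- sum(w * (ys - xs * beta)^2)
  sigma_a2 <- rss / (n - p)
  sigma_e2 <- delta * sigma_a2
  # near the upper boundary the polygenic component is indistinguishable from 0
  if (delta >= exp(11.9)) {
    sigma_e2 <- sigma_a2 * delta
    sigma_a2_eff <- 0
  } else {
    sigma_a2_eff <- sigma_a2
  }
  structure(list(
    sigma_a2 = sigma_a2_eff,
    sigma_e2 = if (sigma_a2_eff == 0) var(trait) else sigma_e2,
    lambda_ratio = delta,
    h2 = if (sigma_a2_eff == 0) 0 else sigma_a2 / (sigma_a2 + sigma_e2),
    loglik = max(ll),
    loglik_fun = loglik,
    eigen = ek,
    intercept = beta
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> sigma_a2 = %.4f, sigma_e2 = %.4f, h2 = %.3f\n",
              x$sigma_a2, x$sigma_e2, x$h2))
  invisible(x)
}

#' @export
tidy.reml_fit <- function(x, ...) {
  tibble::tibble(component = c("additive", "residual"),
                 estimate = c(x$sigma_a2, x$sigma_e2))
}

#' @export
glance.reml_fit <- function(x, ...) {
  tibble::tibble(h2 = x$h2, lambda_ratio = x$lambda_ratio,
                 loglik = x$loglik)
}

#' Mixed-model association scan for one omics trait
#'
#' Per-variant generalized least squares with the variance components fixed
#' at their null-model REML estimates (the P3D strategy): the data are
#' rotated by the kinship eigenvectors and whitened, after which each
#' variant's effect is an ordinary regression with a Wald t test
#' (df = n - 2). With `fit = NULL` (or a fit whose `sigma_a2` is 0) the scan
#' reduces exactly to per-marker ordinary least squares. P-values are BH
#' adjusted across the scan; variants constant after imputation are emitted
#' with p = 1 and flagged.
#'
#' @param trait Numeric trait vector (one record per animal).
#' @param genos A `geno_matrix`.
#' @param fit A [fit_null_reml()] object, or `NULL` for the OLS reduction.
#' @return Tibble of per-variant summary statistics: `variant_id`, `chrom`,
#'   `pos`, `effect_allele`, `other_allele`, `beta`, `se`, `p`, `p_adj`,
#'   `maf`, `n`, `constant`.
#' @export
marker_scan <- function(trait, genos, fit = NULL) {
  G <- genos$geno
  storage.mode(G) <- "double"
  if (length(trait) != nrow(G)) {
    hg_abort("trait length must match genotype rows", "input_error")
  }
  if (anyNA(trait) || any(!is.finite(trait))) {
    hg_abort("trait must be finite and complete", "input_error")
  }
  n <- length(trait)
  has_na <- colSums(is.na(G)) > 0
  mu <- colMeans(G, na.rm = TRUE)
  for (j in which(has_na)) G[is.na(G[, j]), j] <- mu[j]

  mixed <- !is.null(fit) && fit$sigma_a2 > 0
  if (mixed) {
    w_half <- sqrt(1 / (pmax(fit$eigen$values, 0) + fit$lambda_ratio))
    Ut <- t(fit$eigen$vectors)
    yt <- w_half * as.numeric(Ut %*% trait)
    x0 <- w_half * as.numeric(Ut %*% rep(1, n))
    Gt <- (Ut %*% G) * w_half
  } else {
    yt <- trait
    x0 <- rep(1, n)
    Gt <- G
  }
  # two-covariate regression (intercept-equivalent x0 + marker), vectorized
  a11 <- sum(x0^2)
  a12 <- as.numeric(crossprod(Gt, x0))
  a22 <- colSums(Gt^2)
  b1 <- sum(x0 * yt)
  b2 <- as.numeric(crossprod(Gt, yt))
  det <- a11 * a22 - a12^2
  constant <- det <= 1e-10 * a11 * pmax(a22, 1e-12)
  det[constant] <- NA_real_
  beta_g <- (a11 * b2 - a12 * b1) / det
  beta_0 <- (a22 * b1 - a12 * b2) / det
  yty <- sum(yt^2)
  rss <- yty - (beta_0 * b1 + beta_g * b2)
  rss <- pmax(rss, 0)
  df <- n - 2
  se <- sqrt(rss / df * a11 / det)
  tval <- beta_g / se
  p <- 2 * pt(-abs(tval), df = df)
  p[constant] <- 1
  beta_g[constant] <- 0
  se[constant] <- NA_real_
  beta_g <- unname(beta_g)
  se <- unname(se)
  p <- unname(p)
  constant <- unname(constant)

  freq_b <- (mu + 1) / 2
  v <- genos$variants
  tibble::tibble(
    variant_id = v$variant_id,
    chrom = v$chrom %||% NA_integer_,
    pos = v$pos %||% NA_integer_,
    effect_allele = v$a2 %||% "B",
    other_allele = v$a1 %||% "A",
    beta = beta_g,
    se = se,
    p = p,
    p_adj = p.adjust(p, method = "BH"),
    maf = pmin(freq_b, 1 - freq_b),
    n = n,
    constant = constant
  )
}

#' Write GWAS summary statistics to TSV
#'
#' @param summary Tibble from [marker_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(summary, path) {
  readr::write_tsv(summary, path)
  invisible(path)
}
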