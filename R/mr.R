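#' Select independent instrumental variables from a GWAS scan
#'
#' Keeps variants with `p_adj < p_adj_max`, then greedily prunes for linkage
#' disequilibrium in ascending p order so that no retained pair of variants
#' has squared genotype correlation above `ld_r2_max`.
#'
#' @param summary [marker_scan()]-style tibble for the exposure trait.
#' @param genos The `geno_matrix` the scan was run on (for LD pruning).
#' @param p_adj_max Significance threshold on the BH-adjusted p (the
#'   unadjusted `p` column is used instead when `use_adjusted = FALSE`).
#' @param ld_r2_max Maximum allowed squared correlation between retained
#'   instruments.
#' @param use_adjusted Select on `p_adj` (default) or raw `p`.
#' @return Character vector of instrument variant ids (ascending p).
#' @export
select_instruments <- function(summary, genos, p_adj_max = 0.001,
                               ld_r2_max = 0.1, use_adjusted = TRUE) {
  pcol <- if (use_adjusted) summary$p_adj else summary$p
  cand <- summary[pcol < p_adj_max, , drop = FALSE]
  cand <- cand[order(if (use_adjusted) cand$p_adj else cand$p, cand$p), ]
  if (nrow(cand) == 0) {
    hg_abort("no variant passes the instrument threshold", "empty_instruments")
  }
  G <- genos$geno[, cand$variant_id, drop = FALSE]
  storage.mode(G) <- "double"
  kept <- character(0)
  for (vid in cand$variant_id) {
    if (length(kept) == 0) {
      kept <- vid
      next
    }
    r <- suppressWarnings(stats::cor(G[, vid], G[, kept, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    r[is.na(r)] <- 0
    if (all(r^2 <= ld_r2_max)) kept <- c(kept, vid)
  }
  kept
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect allele: rows whose
#' effect/other alleles are swapped relative to the exposure have their betas
#' sign-flipped; strand-ambiguous palindromic variants (A/T, C/G) are dropped
#' unless their allele frequency is far enough from 0.5 (`maf < ambiguity
#' threshold 0.42`) to disambiguate; variants absent from either side are
#' dropped with a message.
#'
#' @param exposure,outcome [marker_scan()]-style summary tibbles.
#' @return Tibble of class `harmonized_instruments`: `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `effect_allele`, `wald_ratio`.
#' @export
harmonize_instruments <- function(exposure, outcome) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  dropped <- setdiff(union(exposure$variant_id, outcome$variant_id), shared)
  if (length(dropped) > 0) {
    rlang::inform(paste0(length(dropped),
                         " variant(s) absent from one side dropped"))
  }
  if (length(shared) == 0) {
    hg_abort("no overlapping variants to harmonize", "empty_instruments")
  }
  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]
  same <- ou$effect_allele == ex$effect_allele &
    ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele &
    ou$other_allele == ex$effect_allele
  palin <- is_palindromic(ex$effect_allele, ex$other_allele)
  maf <- ex$maf %||% rep(NA_real_, nrow(ex))
  ambiguous <- palin & (is.na(maf) | maf >= 0.42)
  keep <- (same | swapped) & !ambiguous
  if (any(ambiguous)) {
    rlang::inform(paste0(sum(ambiguous),
                         " palindromic variant(s) with ambiguous frequency dropped"))
  }
  if (!any(keep)) hg_abort("no harmonizable variants", "empty_instruments")
  beta_out <- ifelse(swapped, -ou$beta, ou$beta)
  h <- tibble::tibble(
    variant_id = shared[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$se[keep],
    beta_outcome = beta_out[keep],
    se_outcome = ou$se[keep],
    effect_allele = ex$effect_allele[keep]
  )
  zero_bx <- h$beta_exposure == 0
  if (any(zero_bx)) {
    rlang::warn(paste0(sum(zero_bx), " variant(s) with zero exposure effect excluded"))
    h <- h[!zero_bx, , drop = FALSE]
  }
  h$wald_ratio <- h$beta_outcome / h$beta_exposure
  class(h) <- c("harmonized_instruments", class(h))
  h
}

new_mr_estimate <- function(method, beta, se, p, n_snps,
                            egger_intercept = NA_real_,
                            intercept_p = NA_real_) {
  tibble::tibble(method = method, beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 p = p, n_snps = n_snps,
                 egger_intercept = egger_intercept,
                 intercept_p = intercept_p)
}

ivw_weights <- function(h) h$beta_exposure^2 / h$se_outcome^2

#' Cochran heterogeneity statistic of the Wald ratios
#'
#' `Q = sum(w_j (ratio_j - beta_IVW)^2)` with inverse-variance weights
#' `w_j = bx_j^2 / sy_j^2`; df = k - 1.
#'
#' @param h A `harmonized_instruments` tibble.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(h) {
  w <- ivw_weights(h)
  beta <- sum(w * h$wald_ratio) / sum(w)
  q <- sum(w * (h$wald_ratio - beta)^2)
  df <- nrow(h) - 1
  list(Q = q, df = df,
       p = if (df > 0) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect meta-analysis of the per-variant Wald ratios,
#' `beta = sum(bx by / sy^2) / sum(bx^2 / sy^2)`, equivalent to weighted
#' least squares of the outcome effects on the exposure effects through the
#' origin. Under overdispersion (Cochran Q / (k - 1) > 1) the standard error
#' is inflated multiplicatively (random-effect correction).
#'
#' @param h A `harmonized_instruments` tibble with >= 1 instrument.
#' @return One-row MR estimate tibble.
#' @export
mr_ivw <- function(h) {
  if (nrow(h) < 1) hg_abort("IVW needs >= 1 instrument", "empty_instruments")
  w <- ivw_weights(h)
  beta <- sum(w * h$wald_ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (nrow(h) > 1) {
    q <- cochran_q(h)
    phi <- q$Q / q$df
    if (phi > 1) se <- se * sqrt(phi)
  }
  new_mr_estimate("IVW", beta, se, 2 * pnorm(-abs(beta / se)), nrow(h))
}

#' MR-Egger regression
#'
#' Weighted regression of the outcome effects on the exposure effects with a
#' free intercept (weights `1 / sy^2`). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy, and its test is reported alongside. Standard
#' errors use the multiplicative random-effects convention (residual SD
#' floored at 1); inference is t with k - 2 df.
#'
#' @param h A `harmonized_instruments` tibble with >= 3 instruments.
#' @return One-row MR estimate tibble (with `egger_intercept`,
#'   `intercept_p`).
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) hg_abort("MR-Egger needs >= 3 instruments",
                      "insufficient_instruments")
  fit <- lm(beta_outcome ~ beta_exposure, data = h,
            weights = 1 / h$se_outcome^2)
  sm <- summary(fit)
  sigma <- sm$sigma
  infl <- max(1, sigma)
  co <- sm$coefficients
  se_slope <- co["beta_exposure", "Std. Error"] / sigma * infl
  se_int <- co["(Intercept)", "Std. Error"] / sigma * infl
  slope <- co["beta_exposure", "Estimate"]
  int <- co["(Intercept)", "Estimate"]
  p_slope <- 2 * pt(-abs(slope / se_slope), df = k - 2)
  p_int <- 2 * pt(-abs(int / se_int), df = k - 2)
  new_mr_estimate("Egger", slope, se_slope, p_slope, k,
                  egger_intercept = int, intercept_p = p_int)
}

weighted_median_point <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  if (any(abs(s - 0.5) < 1e-12)) {
    return(r[which.min(abs(s - 0.5))])
  }
  below <- max(which(s < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

boot_se <- function(h, point_fun, n_boot, seed) {
  check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  est <- vapply(seq_len(n_boot), function(b) {
    hb <- h
    hb$beta_exposure <- rnorm(nrow(h), h$beta_exposure, h$se_exposure)
    hb$beta_outcome <- rnorm(nrow(h), h$beta_outcome, h$se_outcome)
    hb <- hb[hb$beta_exposure != 0, , drop = FALSE]
    hb$wald_ratio <- hb$beta_outcome / hb$beta_exposure
    point_fun(hb)
  }, numeric(1))
  sd(est)
}

#' Weighted-median MR estimate
#'
#' Median of the inverse-variance-weighted empirical distribution of the
#' Wald ratios (consistent when at least half the weight comes from valid
#' instruments): ratios are ordered, cumulative standardized weights
#' `s_j = (sum_{k<=j} w_k - w_j / 2) / sum(w)` computed, and the estimate
#' interpolated linearly where `s` crosses 0.5. The standard error comes
#' from a parametric bootstrap of the per-variant effects.
#'
#' @param h A `harmonized_instruments` tibble with >= 3 instruments.
#' @param n_boot Bootstrap resamples for the SE.
#' @param seed Seed for the bootstrap.
#' @return One-row MR estimate tibble.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  if (nrow(h) < 3) hg_abort("weighted median needs >= 3 instruments",
                            "insufficient_instruments")
  beta <- weighted_median_point(h$wald_ratio, ivw_weights(h))
  se <- boot_se(h, function(hb) weighted_median_point(hb$wald_ratio,
                                                      ivw_weights(hb)),
                n_boot, seed)
  new_mr_estimate("weighted_median", beta, se, 2 * pnorm(-abs(beta / se)),
                  nrow(h))
}

mode_point <- function(ratios, w, bandwidth_factor) {
  if (length(unique(ratios)) == 1L) return(ratios[1])
  s <- 0.9 * min(sd(ratios), mad(ratios)) * length(ratios)^(-1 / 5)
  if (s <= 0) s <- 0.9 * sd(ratios) * length(ratios)^(-1 / 5)
  bw <- bandwidth_factor * s
  dens <- density(ratios, weights = w / sum(w), bw = bw, n = 2048)
  dens$x[which.max(dens$y)]
}

#' Mode-based MR estimate (simple and weighted)
#'
#' Normal-kernel density over the Wald ratios with bandwidth
#' `bandwidth_factor` times the modified Silverman rule
#' `0.9 min(sd, mad) k^(-1/5)`; the causal estimate is the density argmax
#' (the largest cluster of agreeing instruments). The simple mode weights
#' instruments equally; the weighted mode uses inverse-variance weights.
#' Standard errors by parametric bootstrap.
#'
#' @param h A `harmonized_instruments` tibble with >= 3 instruments.
#' @param weighted Use inverse-variance weights?
#' @param bandwidth_factor Multiplier on the modified-Silverman bandwidth.
#' @param n_boot Bootstrap resamples for the SE.
#' @param seed Seed for the bootstrap.
#' @return One-row MR estimate tibble.
#' @export
mr_mode <- function(h, weighted = FALSE, bandwidth_factor = 1,
                    n_boot = 1000, seed = NULL) {
  if (nrow(h) < 3) hg_abort("mode-based MR needs >= 3 instruments",
                            "insufficient_instruments")
  wfun <- function(hb) if (weighted) ivw_weights(hb) else rep(1, nrow(hb))
  beta <- mode_point(h$wald_ratio, wfun(h), bandwidth_factor)
  se <- boot_se(h, function(hb) mode_point(hb$wald_ratio, wfun(hb),
                                           bandwidth_factor),
                n_boot, seed)
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, 2 * pnorm(-abs(beta / se)), nrow(h))
}

#' Five-method Mendelian randomization report
#'
#' Runs IVW, MR-Egger, weighted median, and the simple and weighted mode
#' estimators on one harmonized instrument set, together with the Cochran Q
#' heterogeneity statistic. Methods whose minimum instrument count is not
#' met are reported as flagged rows with missing estimates (IVW runs from a
#' single instrument, where it reduces to the Wald ratio).
#'
#' @param h A `harmonized_instruments` tibble.
#' @param n_boot Bootstrap resamples for the median/mode SEs.
#' @param seed Seed for the bootstrap streams.
#' @param bandwidth_factor Bandwidth multiplier for the mode estimators.
#' @return List of class `mr_result`: `estimates` (tibble, one row per
#'   method with an `insufficient` flag), `Q`, `Q_df`, `Q_p`, `n_snps`.
#' @export
mr_report <- function(h, n_boot = 1000, seed = NULL, bandwidth_factor = 1) {
  check_seed(seed)
  runs <- list(
    IVW = function() mr_ivw(h),
    Egger = function() mr_egger(h),
    weighted_median = function() mr_weighted_median(h, n_boot, seed),
    simple_mode = function() mr_mode(h, FALSE, bandwidth_factor, n_boot,
                                     seed),
    weighted_mode = function() mr_mode(h, TRUE, bandwidth_factor, n_boot,
                                       seed)
  )
  rows <- purrr::imap(runs, function(f, nm) {
    tryCatch({
      est <- f()
      est$insufficient <- FALSE
      est
    }, hologuild_insufficient_instruments = function(e) {
      out <- new_mr_estimate(nm, NA_real_, NA_real_, NA_real_, nrow(h))
      out$insufficient <- TRUE
      out
    })
  })
  q <- if (nrow(h) > 1) cochran_q(h) else list(Q = NA_real_, df = 0,
                                               p = NA_real_)
  structure(list(estimates = dplyr::bind_rows(rows), Q = q$Q, Q_df = q$df,
                 Q_p = q$p, n_snps = nrow(h)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %d instruments, Q = %.3f (df %d, p %.3g)\n",
              x$n_snps, x$Q, x$Q_df, x$Q_p))
  print(x$estimates)
  invisible(x)
}

#' @export
tidy.mr_result <- function(x, ...) x$estimates

#' @export
glance.mr_result <- function(x, ...) {
  tibble::tibble(n_snps = x$n_snps, Q = x$Q, Q_df = x$Q_df, Q_p = x$Q_p)
}

#' Forest plot of MR estimates
#'
#' @param object An `mr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mr_result <- function(object, ...) {
  est <- object$estimates[!object$estimates$insufficient, ]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$beta, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.2) +
    ggplot2::labs(x = "causal effect (beta, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write an MR report to TSV
#'
#' @param result An `mr_result`.
#' @param path Output path.
#' @param exposure,outcome Labels recorded in the file.
#' @return `path`, invisibly.
#' @export
write_mr_report <- function(result, path, exposure = "exposure",
                            outcome = "outcome") {
  est <- result$estimates
  est$exposure <- exposure
  est$outcome <- outcome
  est$Q <- result$Q
  est$Q_df <- result$Q_df
  readr::write_tsv(est, path)
  invisible(path)
}
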