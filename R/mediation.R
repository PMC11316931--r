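#' Linear mediation analysis with bootstrap inference
#'
#' Decomposes the effect of an exposure (e.g. a taxon's abundance) on an
#' outcome (e.g. feed efficiency) into the indirect path through a mediator
#' (protein or metabolite level) and the direct path, with linear
#' no-interaction models: the mediator model `m ~ x (+ covariates)` gives
#' `a`, the outcome model `y ~ x + m (+ covariates)` gives `b` and the
#' direct effect `c'`; ACME = `a * b`, ADE = `c'`, and the total effect from
#' `y ~ x` equals ACME + ADE exactly. Inference is by nonparametric
#' case-resampling bootstrap with two-sided percentile p-values.
#'
#' @param data Data frame holding the variables.
#' @param exposure,mediator,outcome Column names (strings).
#' @param covariates Optional character vector of covariate column names.
#' @param n_boot Number of bootstrap resamples (warned below 100).
#' @param seed Integer seed for the bootstrap.
#' @return List of class `mediation_fit`: `acme`, `ade`, `total`,
#'   `prop_mediated` (NA-flagged when |total| < 1e-8), `p_acme`, `p_ade`,
#'   `p_total`, `n`, `n_boot`, `seed`, and the bootstrap draws.
#' @export
fit_mediation <- function(data, exposure, mediator, outcome,
                          covariates = NULL, n_boot = 1000, seed = NULL) {
  cols <- c(exposure, mediator, outcome, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    hg_abort(paste0("columns not found: ", paste(missing_cols, collapse = ", ")),
             "input_error")
  }
  d <- as.data.frame(data)[, cols, drop = FALSE]
  if (!all(vapply(d, is.numeric, logical(1))) || anyNA(d) ||
      any(!vapply(d, function(v) all(is.finite(v)), logical(1)))) {
    hg_abort("all mediation variables must be finite numeric vectors",
             "input_error")
  }
  n <- nrow(d)
  if (n < 10) hg_abort("mediation needs n >= 10", "input_error")
  if (stats::sd(d[[exposure]]) == 0) {
    hg_abort("constant exposure", "degenerate")
  }
  if (n_boot < 100) rlang::warn("n_boot < 100: bootstrap p-values are coarse")

  x <- d[[exposure]]
  m <- d[[mediator]]
  y <- d[[outcome]]
  Z <- if (length(covariates) > 0) as.matrix(d[, covariates, drop = FALSE])
       else NULL

  point <- mediation_point(x, m, y, Z)

  check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 3,
                 dimnames = list(NULL, c("acme", "ade", "total")))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- tryCatch(
      mediation_point(x[idx], m[idx], y[idx],
                      if (is.null(Z)) NULL else Z[idx, , drop = FALSE]),
      error = function(e) c(acme = NA_real_, ade = NA_real_,
                            total = NA_real_)
    )
    boot[b, ] <- est
  }
  boot <- boot[stats::complete.cases(boot), , drop = FALSE]
  pval <- function(draws) {
    if (length(draws) == 0) return(NA_real_)
    lo <- mean(draws <= 0)
    hi <- mean(draws >= 0)
    max(2 * min(lo, hi), 2 / (nrow(boot) + 1))
  }
  total <- point[["total"]]
  structure(list(
    acme = point[["acme"]],
    ade = point[["ade"]],
    total = total,
    prop_mediated = if (abs(total) < 1e-8) NA_real_ else
      point[["acme"]] / total,
    p_acme = pval(boot[, "acme"]),
    p_ade = pval(boot[, "ade"]),
    p_total = pval(boot[, "total"]),
    n = n, n_boot = n_boot, seed = seed,
    exposure = exposure, mediator = mediator, outcome = outcome,
    boot = boot
  ), class = "mediation_fit")
}

# OLS point estimates of (acme, ade, total) via the two linear models
mediation_point <- function(x, m, y, Z = NULL) {
  X_med <- cbind(1, x, Z)
  X_out <- cbind(1, x, m, Z)
  a <- stats::lm.fit(X_med, m)$coefficients[2]
  co <- stats::lm.fit(X_out, y)$coefficients
  b <- co[3]
  cprime <- co[2]
  acme <- a * b
  c(acme = unname(acme), ade = unname(cprime),
    total = unname(acme + cprime))
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> %s -> %s -> %s (n = %d)\n", x$exposure,
              x$mediator, x$outcome, x$n))
  cat(sprintf("  ACME = %.4f (p = %.4g), ADE = %.4f (p = %.4g), total = %.4f (p = %.4g)\n",
              x$acme, x$p_acme, x$ade, x$p_ade, x$total, x$p_total))
  if (!is.na(x$prop_mediated)) {
    cat(sprintf("  proportion mediated = %.3f\n", x$prop_mediated))
  } else {
    cat("  proportion mediated undefined (total ~ 0)\n")
  }
  invisible(x)
}

#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("acme", "ade", "total"),
    estimate = c(x$acme, x$ade, x$total),
    p.value = c(x$p_acme, x$p_ade, x$p_total)
  )
}

#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(prop_mediated = x$prop_mediated, n = x$n,
                 n_boot = x$n_boot)
}

#' Write mediation results to TSV
#'
#' @param fit A `mediation_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mediation <- function(fit, path) {
  readr::write_tsv(tibble::tibble(
    exposure = fit$exposure, mediator = fit$mediator, outcome = fit$outcome,
    acme = fit$acme, ade = fit$ade, total = fit$total,
    prop_mediated = fit$prop_mediated,
    p_acme = fit$p_acme, p_ade = fit$p_ade, p_total = fit$p_total,
    n_boot = fit$n_boot, seed = fit$seed %||% NA_integer_
  ), path)
  invisible(path)
}
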