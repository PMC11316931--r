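# fixtures and independent brute-force oracles used across test files

`%||%` <- function(x, y) if (is.null(x)) y else x

make_ft <- function(m, ids = sprintf("f%02d", seq_len(nrow(m))),
                    samples = sprintf("s%02d", seq_len(ncol(m)))) {
  dimnames(m) <- list(ids, samples)
  dplyr::bind_cols(tibble::tibble(feature_id = ids), tibble::as_tibble(m))
}

make_samples <- function(n_eff, n_ineff, fcr = NULL) {
  n <- n_eff + n_ineff
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = rep(c("efficient", "inefficient"), c(n_eff, n_ineff)),
    fcr = fcr %||% c(rnorm(n_eff, 5, 0.3), rnorm(n_ineff, 7, 0.3))
  )
}

make_harmonized <- function(bx, by, sx = 0.05, sy = 0.05) {
  h <- tibble::tibble(
    variant_id = sprintf("v%03d", seq_along(bx)),
    beta_exposure = bx, se_exposure = rep_len(sx, length(bx)),
    beta_outcome = by, se_outcome = rep_len(sy, length(bx)),
    effect_allele = "B", wald_ratio = by / bx
  )
  class(h) <- c("harmonized_instruments", class(h))
  h
}

make_geno <- function(G) {
  colnames(G) <- colnames(G) %||% sprintf("v%04d", seq_len(ncol(G)))
  rownames(G) <- rownames(G) %||% sprintf("a%04d", seq_len(nrow(G)))
  f <- colMeans(G + 1, na.rm = TRUE) / 2
  structure(list(
    geno = G,
    variants = tibble::tibble(variant_id = colnames(G),
                              chrom = 1L, pos = seq_len(ncol(G)),
                              a1 = "A", a2 = "B",
                              maf = pmin(f, 1 - f))
  ), class = "geno_matrix")
}

# --- independent oracles ------------------------------------------------

# BH step-up adjustment, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running_min <- 1
  for (k in rev(seq_len(m))) {
    running_min <- min(running_min, p[ord[k]] * m / k)
    adj[ord[k]] <- running_min
  }
  adj
}

# exact two-sided rank-sum p by full enumeration of group assignments
wilcox_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * length(y) / 2
  # symmetric null: double one tail, capped at 1
  if (u_obs > mu) {
    min(1, 2 * mean(u_all >= u_obs))
  } else if (u_obs < mu) {
    min(1, 2 * mean(u_all <= u_obs))
  } else 1
}

# two-sided Fisher p by hypergeometric enumeration at fixed margins
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  support <- lo:hi
  pr <- stats::dhyper(support, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# PERMANOVA pseudo-F from the sum-of-squares definition
permanova_f_oracle <- function(dmat, groups) {
  n <- nrow(dmat)
  groups <- as.factor(groups)
  ss_total <- sum(dmat[lower.tri(dmat)]^2) / n
  ss_within <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    sub <- dmat[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ss_between <- ss_total - ss_within
  a <- nlevels(groups)
  list(F = (ss_between / (a - 1)) / (ss_within / (n - a)),
       R2 = ss_between / ss_total)
}

# average-linkage agglomeration on a distance matrix, by hand
average_linkage_oracle <- function(dmat) {
  clusters <- as.list(seq_len(nrow(dmat)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- mean(dmat[clusters[[i]], clusters[[j]]])
          if (d < best_d) { best_d <- d; best <- c(i, j) }
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
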