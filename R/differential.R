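#' Two-group Wilcoxon rank-sum testing with Benjamini-Hochberg control
#'
#' Tests every feature of a table between the efficient and inefficient
#' groups with the two-sided Wilcoxon rank-sum test (exact enumeration when
#' both groups have <= 10 samples and no ties occur; tie-corrected normal
#' approximation otherwise), then adjusts p-values across the layer with the
#' BH step-up procedure. The log2 fold change is computed on group means with
#' a pseudo-count of half the smallest nonzero abundance of the layer, and is
#' oriented efficient over inefficient.
#'
#' @param ft Wide feature tibble (ideally already normalized).
#' @param samples Tibble with `sample_id` and `group`
#'   (efficient/inefficient).
#' @param alpha BH-adjusted significance threshold used to set `significant`.
#' @return Tibble: `feature_id`, `log2_fold_change`, `p`, `p_adj`,
#'   `direction` (up = higher in efficient animals), `significant`,
#'   `constant` (flag for features identical across all samples, whose p is
#'   1 by convention).
#' @export
diff_test <- function(ft, samples, alpha = 0.05) {
  m <- ft_matrix(ft)
  grp <- aligned_groups(ft, samples)
  eff <- grp == "efficient"
  ineff <- grp == "inefficient"
  if (sum(eff) < 2 || sum(ineff) < 2) {
    hg_abort("both groups need >= 2 samples", "invalid_design")
  }
  exact_ok <- sum(eff) <= 10 && sum(ineff) <= 10
  pseudo <- min(m[m > 0]) / 2
  res <- vapply(seq_len(nrow(m)), function(i) {
    x <- m[i, eff]
    y <- m[i, ineff]
    constant <- length(unique(c(x, y))) == 1L
    p <- if (constant) {
      1
    } else {
      ties <- anyDuplicated(c(x, y)) > 0
      suppressWarnings(
        wilcox.test(x, y, exact = exact_ok && !ties, correct = TRUE)$p.value
      )
    }
    lfc <- log2((mean(x) + pseudo) / (mean(y) + pseudo))
    c(p = p, lfc = lfc, constant = as.numeric(constant))
  }, numeric(3))
  out <- tibble::tibble(
    feature_id = rownames(m),
    log2_fold_change = unname(res["lfc", ]),
    p = unname(res["p", ]),
    p_adj = unname(p.adjust(res["p", ], method = "BH")),
    direction = ifelse(unname(res["lfc", ]) >= 0, "up", "down"),
    constant = unname(res["constant", ]) == 1
  )
  out$significant <- out$p_adj < alpha
  out
}

#' Fold-change quartiles of the significant features
#'
#' Ranks the BH-significant features by log2 fold change (ascending) and cuts
#' them at the empirical 25/50/75 percentiles into quartiles Q1..Q4 (Q4 =
#' largest fold changes, i.e. most strongly up in the efficient group). A
#' value tied with a cut point goes to the lower quartile. With fewer than 4
#' significant features quartiling is skipped with a warning.
#'
#' @param results Output of [diff_test()].
#' @param alpha Significance threshold on `p_adj`.
#' @return `results` with a `quartile` column (`"Q1"`..`"Q4"`, or `NA` for
#'   non-significant features).
#' @export
fold_change_quartiles <- function(results, alpha = 0.05) {
  results$quartile <- NA_character_
  sig <- results$p_adj < alpha
  if (sum(sig) < 4) {
    rlang::warn("fewer than 4 significant features: quartiling skipped")
    return(results)
  }
  lfc <- results$log2_fold_change[sig]
  cuts <- quantile(lfc, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  if (length(unique(lfc)) == 1L) {
    rlang::warn("all significant fold changes equal: every feature in Q1")
    results$quartile[sig] <- "Q1"
    return(results)
  }
  q <- cut(lfc, breaks = c(-Inf, cuts, Inf),
           labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  results$quartile[sig] <- as.character(q)
  results
}

#' Cross-layer Spearman correlation of significant features
#'
#' Spearman rho and p-value for every pair of significant features between
#' two layers, over the shared samples.
#'
#' @param results_a,results_b [diff_test()] outputs for layers A and B.
#' @param ft_a,ft_b The corresponding wide feature tibbles.
#' @return Long tibble: `feature_a`, `feature_b`, `rho`, `p`.
#' @export
spearman_matrix <- function(results_a, results_b, ft_a, ft_b) {
  shared <- intersect(sample_cols(ft_a), sample_cols(ft_b))
  if (length(shared) < 4) {
    hg_abort("need >= 4 shared samples for cross-layer correlation",
             "input_error")
  }
  ids_a <- results_a$feature_id[results_a$significant]
  ids_b <- results_b$feature_id[results_b$significant]
  ma <- ft_matrix(ft_a)[ids_a, shared, drop = FALSE]
  mb <- ft_matrix(ft_b)[ids_b, shared, drop = FALSE]
  grid <- tidyr::expand_grid(feature_a = ids_a, feature_b = ids_b)
  stats <- purrr::pmap(grid, function(feature_a, feature_b) {
    ct <- suppressWarnings(
      cor.test(ma[feature_a, ], mb[feature_b, ], method = "spearman")
    )
    tibble::tibble(rho = unname(ct$estimate), p = ct$p.value)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(stats))
}

#' Spearman correlation of features against a continuous phenotype
#'
#' @param ft Wide feature tibble.
#' @param samples Tibble with `sample_id` and the phenotype column.
#' @param phenotype Name of the phenotype column (default `"fcr"`).
#' @return Tibble: `feature_id`, `rho`, `p`.
#' @export
phenotype_correlation <- function(ft, samples, phenotype = "fcr") {
  m <- ft_matrix(ft)
  ph <- samples[[phenotype]][match(colnames(m), samples$sample_id)]
  if (anyNA(ph)) hg_abort("phenotype missing for some samples", "input_error")
  res <- vapply(seq_len(nrow(m)), function(i) {
    ct <- suppressWarnings(cor.test(m[i, ], ph, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2))
  tibble::tibble(feature_id = rownames(m), rho = res[1, ], p = res[2, ])
}

#' Volcano plot of differential results
#'
#' @param results Output of [diff_test()].
#' @param alpha Significance threshold drawn on the plot.
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.05) {
  results$status <- dplyr::case_when(
    results$p_adj < alpha & results$log2_fold_change > 0 ~ "up",
    results$p_adj < alpha & results$log2_fold_change < 0 ~ "down",
    TRUE ~ "ns"
  )
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$log2_fold_change,
                               y = -log10(.data$p),
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change (efficient / inefficient)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}
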