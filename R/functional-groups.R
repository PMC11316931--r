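new_functional_group <- function(layer, provenance) {
  # provenance: one row per supporting feature with species/family/categories
  members <- provenance %>%
    dplyr::distinct(.data$species, .data$family) %>%
    dplyr::arrange(.data$species)
  structure(list(layer = layer, members = members, provenance = provenance),
            class = "functional_group")
}

#' @export
print.functional_group <- function(x, ...) {
  cat(sprintf("<functional_group> %s: %d species / %d families from %d features\n",
              x$layer, nrow(x$members), length(unique(x$members$family)),
              nrow(x$provenance)))
  invisible(x)
}

#' Species set of a functional group
#' @param group A `functional_group`.
#' @return Character vector of member species.
#' @export
group_species <- function(group) group$members$species

group_provenance <- function(ids, annotations) {
  annotations %>%
    dplyr::filter(.data$feature_id %in% ids) %>%
    dplyr::select(dplyr::any_of(c("feature_id", "species", "family",
                                  "categories")))
}

#' Transcript-based (MTT) functional group
#'
#' Features are kept when their mean CPM exceeds `cpm_min` in at least one
#' group (strictly: CPM exactly at the threshold is excluded), their
#' BH-adjusted Wilcoxon p is below `alpha`, and they are up in the efficient
#' animals; surviving features are mapped feature -> species -> family.
#'
#' @param ft Wide MTT feature tibble (raw counts; CPM is computed
#'   internally).
#' @param samples Sample tibble with `sample_id`, `group`.
#' @param annotations Annotation sidecar tibble.
#' @param cpm_min CPM threshold (strict `>`).
#' @param alpha BH significance threshold.
#' @return A `functional_group`.
#' @export
build_mtt_group <- function(ft, samples, annotations, cpm_min = 5,
                            alpha = 0.05) {
  cpm <- normalize_cpm(ft)
  m <- ft_matrix(cpm)
  grp <- aligned_groups(cpm, samples)
  mean_eff <- rowMeans(m[, grp == "efficient", drop = FALSE])
  mean_ineff <- rowMeans(m[, grp == "inefficient", drop = FALSE])
  pass_cpm <- pmax(mean_eff, mean_ineff) > cpm_min
  res <- diff_test(cpm, samples, alpha = alpha)
  keep <- res$feature_id[res$significant & res$direction == "up" &
                           res$feature_id %in% rownames(m)[pass_cpm]]
  if (length(keep) == 0) rlang::warn("empty MTT functional group")
  new_functional_group("MTT", group_provenance(keep, annotations))
}

#' Protein-based (MTP) functional group
#'
#' Takes the differentially expressed proteins falling in fold-change
#' quartiles Q3 and Q4 (the half most strongly up in efficient animals) and
#' maps them to species, family, and functional categories.
#'
#' @param ft Wide MTP feature tibble.
#' @param samples Sample tibble.
#' @param annotations Annotation sidecar tibble.
#' @param diff_results Optional precomputed [fold_change_quartiles()] output;
#'   computed from `ft` when omitted.
#' @param alpha BH significance threshold.
#' @return A `functional_group`.
#' @export
build_mtp_group <- function(ft, samples, annotations, diff_results = NULL,
                            alpha = 0.05) {
  if (is.null(diff_results)) {
    diff_results <- fold_change_quartiles(diff_test(ft, samples, alpha),
                                          alpha = alpha)
  }
  if (!"quartile" %in% names(diff_results) ||
      all(is.na(diff_results$quartile))) {
    hg_abort("quartile labels unavailable (quartiling skipped upstream)",
             "missing_quartiles")
  }
  keep <- diff_results$feature_id[!is.na(diff_results$quartile) &
                                    diff_results$quartile %in% c("Q3", "Q4")]
  if (length(keep) == 0) rlang::warn("empty MTP functional group")
  new_functional_group("MTP", group_provenance(keep, annotations))
}

#' Metabolite-based (MTB) functional group
#'
#' Applies the four-stage metabolite filter chain: detected in strictly more
#' than `prev_min` of the samples; spectral-match similarity strictly over
#' `sim_min`; significantly higher in the efficient animals (BH-adjusted
#' Wilcoxon p < `alpha`); and significantly Spearman-correlated with the FCR
#' phenotype (p < `cor_alpha`). Only metabolites of microbiota or
#' co-metabolism origin are eligible; metabolites lacking an origin label are
#' skipped with a message.
#'
#' @param ft Wide MTB feature tibble.
#' @param samples Sample tibble with `sample_id`, `group`, `fcr`.
#' @param annotations Annotation tibble with `origin` and `similarity`.
#' @param alpha BH threshold for the differential filter.
#' @param cor_alpha Threshold for the FCR-correlation p.
#' @param sim_min Similarity threshold (strict `>`).
#' @param prev_min Prevalence threshold (strict `>`).
#' @return A `functional_group`.
#' @export
build_mtb_group <- function(ft, samples, annotations, alpha = 0.05,
                            cor_alpha = 0.05, sim_min = 200, prev_min = 0.5) {
  if (!all(c("origin", "similarity") %in% names(annotations))) {
    hg_abort("MTB annotations need origin and similarity columns",
             "input_error")
  }
  no_origin <- annotations$feature_id[is.na(annotations$origin)]
  if (length(no_origin) > 0) {
    rlang::inform(paste0("metabolites without origin label skipped: ",
                         paste(no_origin, collapse = ", ")))
  }
  prev_ok <- filter_prevalence(ft, prev_min)$feature_id
  sim_ok <- annotations$feature_id[!is.na(annotations$similarity) &
                                     annotations$similarity > sim_min]
  origin_ok <- annotations$feature_id[!is.na(annotations$origin) &
                                        annotations$origin %in%
                                        c("microbiota", "co-metabolism")]
  res <- diff_test(ft, samples, alpha = alpha)
  de_ok <- res$feature_id[res$significant & res$direction == "up"]
  corr <- phenotype_correlation(ft, samples, "fcr")
  cor_ok <- corr$feature_id[corr$p < cor_alpha]
  keep <- Reduce(intersect, list(prev_ok, sim_ok, origin_ok, de_ok, cor_ok))
  if (length(keep) == 0) rlang::warn("empty MTB functional group")
  new_functional_group("MTB", group_provenance(keep, annotations))
}

#' Compare functional groups across omics layers
#'
#' Computes all pairwise and triple species-set intersection counts (Venn
#' counts) and, per layer, a Bray-Curtis PERMANOVA on the submatrix of the
#' features that produced the group, with BH adjustment of the permutation
#' p-values across layers and the log2(pseudo-F / q) effect size.
#'
#' @param groups Named list of `functional_group`s (e.g. MTT, MTP, MTB).
#' @param tables Named list of the corresponding wide feature tibbles.
#' @param samples Sample tibble.
#' @param n_perm Permutations per PERMANOVA.
#' @param seed Seed for the permutation streams.
#' @return List of class `group_comparison`: `venn` (named intersection
#'   counts), `permanova` (tibble: layer, pseudo_F, R2, p_perm, q,
#'   effect_size_log2).
#' @export
compare_groups <- function(groups, tables, samples, n_perm = 999,
                           seed = NULL) {
  sets <- lapply(groups, group_species)
  nm <- names(sets)
  venn <- list()
  for (i in seq_along(sets)) venn[[nm[i]]] <- length(sets[[i]])
  if (length(sets) >= 2) {
    for (pair in utils::combn(seq_along(sets), 2, simplify = FALSE)) {
      venn[[paste(nm[pair], collapse = "&")]] <-
        length(intersect(sets[[pair[1]]], sets[[pair[2]]]))
    }
  }
  if (length(sets) >= 3) {
    venn[[paste(nm, collapse = "&")]] <- length(Reduce(intersect, sets))
  }
  for (i in seq_along(sets)) {
    venn[[paste0("unique_", nm[i])]] <-
      length(setdiff(sets[[i]], unlist(sets[-i])))
  }
  check_seed(seed)
  rows <- purrr::map(nm, function(layer) {
    grp <- groups[[layer]]
    ft <- tables[[layer]]
    ids <- intersect(grp$provenance$feature_id, ft$feature_id)
    if (length(ids) < 1) {
      return(tibble::tibble(layer = layer, pseudo_F = NA_real_,
                            R2 = NA_real_, p_perm = NA_real_))
    }
    sub <- ft[ft$feature_id %in% ids, , drop = FALSE]
    m <- ft_matrix(sub)
    # samples undetected for every member feature have no position in
    # Bray-Curtis space; they are left out of this layer's test
    nonzero <- colSums(m) > 0
    if (any(!nonzero)) {
      rlang::inform(sprintf("[%s] %d sample(s) with zero member-feature total excluded",
                            layer, sum(!nonzero)))
      sub <- sub[, c("feature_id", colnames(m)[nonzero]), drop = FALSE]
    }
    grp_lab <- aligned_groups(sub, samples)
    if (length(unique(grp_lab)) < 2 || min(table(grp_lab)) < 2) {
      return(tibble::tibble(layer = layer, pseudo_F = NA_real_,
                            R2 = NA_real_, p_perm = NA_real_))
    }
    d <- bray_curtis(sub)
    fit <- permanova(d, grp_lab, n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else
                       seed + match(layer, nm))
    tibble::tibble(layer = layer, pseudo_F = fit$pseudo_F, R2 = fit$R2,
                   p_perm = fit$p_perm)
  })
  perm <- dplyr::bind_rows(rows)
  perm$q <- p.adjust(perm$p_perm, method = "BH")
  ok <- !is.na(perm$pseudo_F) & perm$pseudo_F > 0
  perm$effect_size_log2 <- NA_real_
  perm$effect_size_log2[ok] <- effect_size_log2fq(perm$pseudo_F[ok],
                                                  perm$q[ok], n_perm = n_perm)
  structure(list(venn = venn, permanova = perm), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n  venn: ",
      paste(names(x$venn), unlist(x$venn), sep = "=", collapse = ", "),
      "\n", sep = "")
  print(x$permanova)
  invisible(x)
}

#' Sankey link table of a functional group
#'
#' Exports the two-level link list (functional category -> species ->
#' family) with link weights equal to the number of supporting features.
#'
#' @param group A non-empty `functional_group`.
#' @return Tibble: `source`, `target`, `level`
#'   (`"category-species"` or `"species-family"`), `weight`.
#' @export
export_sankey <- function(group) {
  prov <- group$provenance
  if (nrow(prov) == 0) hg_abort("empty functional group", "input_error")
  if ("categories" %in% names(prov)) {
    cat_links <- prov %>%
      dplyr::mutate(category = strsplit(.data$categories, ";", fixed = TRUE)) %>%
      tidyr::unnest("category") %>%
      dplyr::count(.data$category, .data$species, name = "weight") %>%
      dplyr::rename(source = "category", target = "species") %>%
      dplyr::mutate(level = "category-species")
  } else {
    cat_links <- tibble::tibble(source = character(), target = character(),
                                weight = integer(), level = character())
  }
  fam_links <- prov %>%
    dplyr::count(.data$species, .data$family, name = "weight") %>%
    dplyr::rename(source = "species", target = "family") %>%
    dplyr::mutate(level = "species-family")
  dplyr::bind_rows(cat_links, fam_links) %>%
    dplyr::select("source", "target", "level", "weight")
}
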