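# vocabulary is inferred from the category-id shape used by the synthetic
# ontology and common annotation exports
infer_vocabulary <- function(category) {
  dplyr::case_when(
    grepl("^GO:", category) ~ "GO",
    grepl("^ko\\d", category) ~ "KEGG",
    grepl("^PF\\d", category) ~ "domain",
    nchar(category) == 1L ~ "COG",
    TRUE ~ "other"
  )
}

#' Long annotation table of functional categories
#'
#' Unnests the semicolon-joined `categories` column of an annotation sidecar
#' into one row per (feature, category), tagging each category with its
#' vocabulary (COG letter, KEGG pathway, GO term, protein domain).
#'
#' @param annotations Annotation tibble with `feature_id` and `categories`.
#' @return Tibble: `feature_id`, `category`, `vocabulary`.
#' @export
annotation_categories <- function(annotations) {
  long <- annotations %>%
    dplyr::select("feature_id", "categories") %>%
    dplyr::mutate(category = strsplit(.data$categories, ";", fixed = TRUE)) %>%
    tidyr::unnest("category") %>%
    dplyr::select("feature_id", "category")
  long$vocabulary <- infer_vocabulary(long$category)
  long
}

#' Fisher-exact functional enrichment
#'
#' Tests each functional category of one vocabulary for enrichment of the
#' differential features against the full identified background, with the
#' two-tailed Fisher exact test (two-sided p = total probability of all
#' tables, at fixed margins, no more likely than the observed one). P-values
#' are BH-adjusted within the vocabulary. Categories absent from the
#' background are skipped.
#'
#' @param de_ids Character vector of differential feature ids (subset of
#'   `background_ids`).
#' @param background_ids Character vector of all identified feature ids.
#' @param annotations Annotation tibble (see [annotation_categories()]) or an
#'   already-long tibble with `feature_id`, `category`, `vocabulary`.
#' @param vocabulary One of `"COG"`, `"KEGG"`, `"GO"`, `"domain"`.
#' @return Tibble: `category`, `vocabulary`, `a`, `b`, `c`, `d` (2x2 counts:
#'   DE-in, DE-out, background-only-in, background-only-out), `odds_ratio`,
#'   `p`, `p_adj`.
#' @export
fisher_enrichment <- function(de_ids, background_ids, annotations,
                              vocabulary = c("COG", "KEGG", "GO", "domain")) {
  vocabulary <- match.arg(vocabulary)
  if (length(background_ids) == 0) hg_abort("empty background", "input_error")
  if (!all(de_ids %in% background_ids)) {
    hg_abort("de_ids must be a subset of background_ids", "input_error")
  }
  long <- if (all(c("category", "vocabulary") %in% names(annotations))) {
    annotations
  } else {
    annotation_categories(annotations)
  }
  long <- long %>%
    dplyr::filter(.data$vocabulary == !!vocabulary,
                  .data$feature_id %in% background_ids) %>%
    dplyr::distinct(.data$feature_id, .data$category)
  cats <- sort(unique(long$category))
  n_de <- length(unique(de_ids))
  n_bg <- length(unique(background_ids))
  rows <- purrr::map(cats, function(cat) {
    in_cat <- unique(long$feature_id[long$category == cat])
    a <- sum(de_ids %in% in_cat)
    b <- n_de - a
    cc <- length(setdiff(in_cat, de_ids))
    d <- (n_bg - n_de) - cc
    ft <- fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE))
    tibble::tibble(category = cat, vocabulary = vocabulary,
                   a = a, b = b, c = cc, d = d,
                   odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Quartile-wise enrichment z-score matrix with hierarchical clustering
#'
#' Collates per-quartile enrichment p-values into a categories x quartiles
#' matrix, keeps the categories enriched (p < `p_threshold`) in at least one
#' quartile, transforms to `x = -log10(p)`, z-scores each category row, and
#' clusters rows and columns by average-linkage hierarchical clustering on
#' Euclidean distance. Rows with zero variance are set to 0 and flagged.
#'
#' @param enrichments Named list (one element per quartile) of
#'   [fisher_enrichment()] tibbles.
#' @param p_threshold Retention threshold on the raw enrichment p.
#' @return List of class `quartile_clusters`: `z` (z-score matrix),
#'   `neg_log10_p`, `row_order`, `col_order`, `row_hclust`, `col_hclust`,
#'   `flat_rows` (categories with zero variance).
#' @export
quartile_cluster_matrix <- function(enrichments, p_threshold = 0.05) {
  if (length(enrichments) < 2) {
    hg_abort("need >= 2 quartile enrichment sets", "input_error")
  }
  cats <- sort(unique(unlist(lapply(enrichments, function(e) e$category))))
  pmat <- matrix(1, nrow = length(cats), ncol = length(enrichments),
                 dimnames = list(cats, names(enrichments)))
  for (j in seq_along(enrichments)) {
    e <- enrichments[[j]]
    pmat[e$category, j] <- e$p
  }
  keep <- apply(pmat, 1, function(p) any(p < p_threshold))
  pmat <- pmat[keep, , drop = FALSE]
  if (nrow(pmat) == 0) {
    hg_abort("no category passes the retention threshold", "input_error")
  }
  x <- -log10(pmat)
  z <- t(apply(x, 1, function(r) {
    s <- sd(r)
    if (s > 0) (r - mean(r)) / s else rep(0, length(r))
  }))
  dimnames(z) <- dimnames(x)
  flat <- rownames(x)[apply(x, 1, sd) == 0]
  if (length(flat) > 0) {
    rlang::warn(paste0("zero-variance categories z-scored to 0: ",
                       paste(flat, collapse = ", ")))
  }
  row_hc <- if (nrow(z) > 1) hclust(dist(z), method = "average") else NULL
  col_hc <- if (ncol(z) > 1) hclust(dist(t(z)), method = "average") else NULL
  structure(list(
    z = z, neg_log10_p = x,
    row_order = if (is.null(row_hc)) rownames(z) else rownames(z)[row_hc$order],
    col_order = if (is.null(col_hc)) colnames(z) else colnames(z)[col_hc$order],
    row_hclust = row_hc, col_hclust = col_hc, flat_rows = flat
  ), class = "quartile_clusters")
}

#' @export
print.quartile_clusters <- function(x, ...) {
  cat(sprintf("<quartile_clusters> %d categories x %d quartiles\n",
              nrow(x$z), ncol(x$z)))
  invisible(x)
}
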