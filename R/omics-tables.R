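#' Read an omics feature table from TSV
#'
#' Expects a tab-separated file whose first column is `feature_id` and whose
#' remaining columns are per-sample non-negative abundances. Duplicate
#' feature ids, missing cells, and negative values are rejected.
#'
#' @param path Path to the TSV file.
#' @param layer Optional layer tag (`"MTT"`, `"MTP"`, `"MTB"`) recorded as an
#'   attribute.
#' @return A wide feature tibble (`feature_id` + one numeric column per
#'   sample).
#' @export
read_feature_table <- function(path, layer = NULL) {
  ft <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(ft)[1] != "feature_id") {
    hg_abort("first column must be named 'feature_id'", "format_error")
  }
  validate_feature_table(ft)
  if (!is.null(layer)) attr(ft, "layer") <- layer
  ft
}

validate_feature_table <- function(ft) {
  if (anyDuplicated(ft$feature_id)) {
    hg_abort("duplicated feature ids", "format_error")
  }
  m <- ft_matrix(ft)
  if (anyNA(m) || any(!is.finite(m))) {
    hg_abort("missing or non-finite abundance values", "format_error")
  }
  if (any(m < 0)) hg_abort("negative abundance values", "format_error")
  invisible(ft)
}

#' Write an omics feature table to TSV
#'
#' @param ft A wide feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  readr::write_tsv(ft, path)
  invisible(path)
}

#' Read an annotation sidecar table
#'
#' Columns: `feature_id`, `species`, `family`, `categories` (semicolon-joined
#' functional category ids), and for metabolites `origin` and `similarity`.
#'
#' @param path Path to the TSV file.
#' @return An annotation tibble.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("feature_id", "species", "family") %in% names(ann))) {
    hg_abort("annotation table needs feature_id, species, family columns",
             "format_error")
  }
  if ("origin" %in% names(ann)) {
    bad <- setdiff(unique(ann$origin),
                   c("microbiota", "host", "co-metabolism", "others"))
    if (length(bad) > 0) {
      hg_abort(paste0("unknown origin labels: ", paste(bad, collapse = ", ")),
               "format_error")
    }
  }
  ann
}

#' Read the phenotype table
#'
#' @param path TSV with columns `sample_id`, `group`, `fcr`.
#' @return A tibble.
#' @export
read_phenotype <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("sample_id", "group") %in% names(ph))) {
    hg_abort("phenotype table needs sample_id and group columns",
             "format_error")
  }
  bad <- setdiff(unique(ph$group), c("efficient", "inefficient"))
  if (length(bad) > 0) {
    hg_abort(paste0("unknown group labels: ", paste(bad, collapse = ", ")),
             "format_error")
  }
  ph
}

#' Counts-per-million normalization
#'
#' Rescales every sample column to sum to one million, preserving
#' within-sample proportions exactly.
#'
#' @param ft A wide feature tibble.
#' @return The CPM-scaled feature tibble.
#' @export
normalize_cpm <- function(ft) {
  m <- ft_matrix(ft)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    hg_abort(paste0("sample(s) with zero total abundance: ",
                    paste(colnames(m)[cs <= 0], collapse = ", ")),
             "degenerate_sample")
  }
  matrix_ft(sweep(m, 2, cs, "/") * 1e6)
}

#' Prevalence filter
#'
#' Keeps features detected (abundance > 0) in strictly more than `min_frac`
#' of the samples; "over 50% of samples" therefore means a feature present in
#' exactly half of them is dropped. Zeros are treated as true absence.
#'
#' @param ft A wide feature tibble.
#' @param min_frac Proportion of samples in `[0, 1]`.
#' @param comparator Comparison applied to the prevalence fraction; the
#'   default `` `>` `` implements the strict "over" reading.
#' @return The filtered feature tibble.
#' @export
filter_prevalence <- function(ft, min_frac = 0.5, comparator = `>`) {
  assert_scalar_number(min_frac, "min_frac", 0, 1)
  m <- ft_matrix(ft)
  prev <- rowMeans(m > 0)
  ft[comparator(prev, min_frac), , drop = FALSE]
}
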