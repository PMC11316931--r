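# Internal helpers shared across modules.

# classed error so callers/tests can distinguish failure modes
hg_abort <- function(msg, class) {
  rlang::abort(msg, class = paste0("hologuild_", class))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_lower) x > lower else x >= lower) &&
    (if (strict_upper) x < upper else x <= upper)
  if (!ok) {
    hg_abort(sprintf("`%s` must be a finite number in %s%s, %s%s (got: %s)",
                     name,
                     if (strict_lower) "(" else "[", format(lower),
                     format(upper), if (strict_upper) ")" else "]",
                     paste(format(x), collapse = ", ")),
             "invalid_config")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
        x == floor(x))) {
    hg_abort(sprintf("`%s` must be an integer >= %d", name, min),
             "invalid_config")
  }
  invisible(as.integer(x))
}

# sample-id columns of a wide feature tibble (everything after feature_id)
sample_cols <- function(ft) setdiff(names(ft), "feature_id")

# wide feature tibble -> features x samples numeric matrix
ft_matrix <- function(ft) {
  m <- as.matrix(ft[, sample_cols(ft), drop = FALSE])
  rownames(m) <- ft$feature_id
  storage.mode(m) <- "double"
  m
}

matrix_ft <- function(m) {
  dplyr::bind_cols(tibble::tibble(feature_id = rownames(m)),
                   tibble::as_tibble(m))
}

# group labels aligned to the sample columns of a feature tibble
aligned_groups <- function(ft, samples) {
  ids <- sample_cols(ft)
  missing <- setdiff(ids, samples$sample_id)
  if (length(missing) > 0) {
    hg_abort(paste0("samples table lacks group labels for: ",
                    paste(missing, collapse = ", ")), "invalid_samples")
  }
  samples$group[match(ids, samples$sample_id)]
}

check_seed <- function(seed) {
  if (!is.null(seed)) assert_count(seed, "seed", min = 0L)
  invisible(seed)
}
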