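# Internal helpers shared across modules.

# Convert an expression tibble (gene_id + numeric sample columns) to a
# numeric matrix with gene_id rownames. Validates shape on the way.
expr_to_matrix <- function(expr, arg = "expr") {
  if (!is.data.frame(expr)) {
    abort(sprintf("`%s` must be a data frame with a `gene_id` column.", arg))
  }
  if (!"gene_id" %in% names(expr)) {
    abort(sprintf("`%s` must have a `gene_id` column as its first column.", arg))
  }
  ids <- as.character(expr$gene_id)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(sprintf(
      "Duplicate gene_id in `%s`: %s",
      arg, paste(head(dup, 5L), collapse = ", ")
    ))
  }
  value_cols <- setdiff(names(expr), "gene_id")
  if (anyDuplicated(value_cols)) {
    abort(sprintf("Duplicate sample ids in `%s`.", arg))
  }
  m <- as.matrix(expr[value_cols])
  if (!is.numeric(m)) {
    abort(sprintf("Sample columns of `%s` must all be numeric.", arg))
  }
  rownames(m) <- ids
  m
}

matrix_to_expr <- function(m, dataset_id = NULL) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, gene_id = rownames(m), .before = 1L)
  if (!is.null(dataset_id)) attr(out, "dataset_id") <- dataset_id
  out
}

dataset_id_of <- function(expr, fallback = NULL) {
  attr(expr, "dataset_id", exact = TRUE) %||% fallback
}

sample_ids_of <- function(expr) setdiff(names(expr), "gene_id")

# Row-wise mean and sample SD (denominator n - 1) ignoring NAs, vectorized.
row_mean_sd <- function(m) {
  n_finite <- rowSums(!is.na(m))
  mu <- rowMeans(m, na.rm = TRUE)
  centered <- m - mu
  ss <- rowSums(centered^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n_finite - 1L, 1L))
  s[n_finite < 2L] <- NA_real_
  list(mean = mu, sd = s, n = n_finite)
}

`%||%` <- rlang::`%||%`
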