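# Plain-text I/O: expression/clinical TSV and GMT gene sets.

check_gene_sets <- function(sets) {
  if (!is.data.frame(sets) ||
      !all(c("set_name", "gene_id") %in% names(sets))) {
    abort("Gene sets must be a tibble with `set_name` and `gene_id` columns.")
  }
  if (nrow(sets) == 0L) abort("Gene-set table is empty.")
  invisible(TRUE)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Reading returns the long
#' tibble used throughout the package (`set_name`, `description`,
#' `gene_id`); a description of the form `category=<tag>` is additionally
#' parsed into a `category` column. Writing inverts the mapping;
#' `write_gmt(read_gmt(f))` preserves set names, membership and order.
#'
#' @param path File path.
#' @return `read_gmt()`: long gene-set tibble.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) abort(sprintf("GMT file is empty: %s", path))
  rows <- purrr::imap(lines, function(l, i) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("Malformed GMT line %d in %s: need name, description and >= 1 gene.",
                    i, path))
    }
    tibble::tibble(set_name = parts[1], description = parts[2],
                   gene_id = parts[-(1:2)])
  })
  out <- dplyr::bind_rows(rows)
  cat_match <- stringr::str_match(out$description, "^category=(.+)$")
  if (any(!is.na(cat_match[, 2]))) out$category <- cat_match[, 2]
  out
}

#' @rdname read_gmt
#' @param sets Long gene-set tibble (`set_name`, `gene_id`, optional
#'   `description`/`category`).
#' @return `write_gmt()`: the path, invisibly.
#' @export
write_gmt <- function(sets, path) {
  check_gene_sets(sets)
  desc <- if ("description" %in% names(sets)) {
    sets$description
  } else if ("category" %in% names(sets)) {
    paste0("category=", sets$category)
  } else {
    rep("na", nrow(sets))
  }
  lines <- purrr::map_chr(unique(sets$set_name), function(s) {
    rows <- which(sets$set_name == s)
    paste(c(s, desc[rows[1]], sets$gene_id[rows]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read / write expression matrices as TSV
#'
#' The tabular dialect is: header row, first column `gene_id`, one numeric
#' column per sample, tab-separated. Duplicate gene ids are an error (named
#' in the message). The dataset id is attached as an attribute, defaulting
#' to the file name without extension.
#'
#' @param path File path.
#' @param dataset_id Dataset identifier; default derived from the file name.
#' @return `read_expression_tsv()`: an expression tibble.
#' @export
read_expression_tsv <- function(path, dataset_id = NULL) {
  if (!file.exists(path)) abort(sprintf("Expression file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(out)[1] != "gene_id") {
    abort(sprintf("First column of %s must be `gene_id`.", path))
  }
  expr_to_matrix(out, arg = path)  # validates ids and numeric columns
  attr(out, "dataset_id") <- dataset_id %||%
    tools::file_path_sans_ext(basename(path))
  out
}

#' @rdname read_expression_tsv
#' @param expr Expression tibble.
#' @return `write_expression_tsv()`: the path, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  expr_to_matrix(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}

clinical_columns <- c("sample_id", "condition", "stage", "grade", "prognosis",
                      "vascular_invasion", "survival_time", "event")

#' Read / write clinical annotation tables as TSV
#'
#' One row per sample; `sample_id` and `condition` (tumor/normal) are
#' required, the clinical/survival fields are optional and may be missing
#' (empty) for normal samples.
#'
#' @param path File path.
#' @return `read_clinical_tsv()`: a clinical tibble.
#' @export
read_clinical_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Clinical file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("sample_id", "condition"), names(out))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Clinical file %s lacks column(s): %s", path,
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(out$sample_id)) {
    abort(sprintf("Duplicate sample_id in clinical file %s.", path))
  }
  out
}

#' @rdname read_clinical_tsv
#' @param clinical Clinical tibble.
#' @return `write_clinical_tsv()`: the path, invisibly.
#' @export
write_clinical_tsv <- function(clinical, path) {
  readr::write_tsv(clinical, path, progress = FALSE)
  invisible(path)
}
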