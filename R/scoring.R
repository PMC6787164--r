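#' Per-patient gene-set scores
#'
#' For every sample and gene set, the patient score is the sum of the
#' sample's Z-scores over the set's member genes. Genes absent from the
#' matrix are skipped (and counted); missing Z entries contribute 0. A set
#' with no gene present yields an all-zero column with a warning.
#'
#' @param z Z-score tibble (from [zscore_normalize()] or [pool_datasets()]).
#' @param sets Gene-set tibble (`set_name`, `gene_id`, optional `category`).
#' @return Tibble with `sample_id` and one numeric column per set, plus a
#'   `genes_used` attribute (named integer vector: member genes found per
#'   set).
#' @export
#' @examples
#' z <- tibble::tibble(gene_id = c("A", "B"), s1 = c(1.5, -0.5))
#' sets <- tibble::tibble(set_name = "S", gene_id = c("A", "B"))
#' # patient_scores needs >= 2 samples upstream, but scoring itself is a sum
patient_scores <- function(z, sets) {
  m <- expr_to_matrix(z, arg = "z")
  check_gene_sets(sets)
  m[is.na(m)] <- 0
  set_names <- unique(sets$set_name)
  sets <- dplyr::distinct(sets, .data$set_name, .data$gene_id)
  used <- integer(length(set_names))
  names(used) <- set_names
  out <- matrix(0, nrow = ncol(m), ncol = length(set_names),
                dimnames = list(colnames(m), set_names))
  for (s in set_names) {
    members <- sets$gene_id[sets$set_name == s]
    present <- intersect(members, rownames(m))
    used[s] <- length(present)
    if (length(present) == 0L) {
      warn(sprintf("Gene set `%s` has no gene in the matrix; scores are 0.", s))
      next
    }
    out[, s] <- colSums(m[present, , drop = FALSE])
  }
  res <- tibble::as_tibble(out, .name_repair = "minimal")
  res <- tibble::add_column(res, sample_id = colnames(m), .before = 1L)
  attr(res, "genes_used") <- used
  res
}

#' Composite activity score
#'
#' Per-sample arithmetic mean of several gene sets' patient scores — e.g. an
#' HDAC1 activity score averaging three HDAC1-related set scores. With a
#' single component the composite equals that component.
#'
#' @param table Score table from [patient_scores()].
#' @param components Character vector of set (column) names to average.
#' @param name Name for the composite column.
#' @return Tibble with `sample_id` and one column named `name`.
#' @export
composite_score <- function(table, components, name) {
  missing_cols <- setdiff(components, names(table))
  if (length(missing_cols) > 0L) {
    abort(sprintf("Unknown component set(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(components) == 0L) abort("`components` must be non-empty.")
  vals <- rowMeans(as.matrix(table[components]))
  tibble::tibble(sample_id = table$sample_id, !!name := vals)
}

#' Split samples into low (G0) and high (G1) groups
#'
#' Default rule is the median split: values at or below the median go to G0
#' (low), values above to G1 (high); ties at the median therefore fall in
#' G0. The tertile rule labels the bottom third G0 and the top third G1,
#' leaving the middle third NA. Externally supplied labels (e.g.
#' Normal = G0 vs Tumor = G1) pass through unchanged.
#'
#' @param values Numeric vector of per-sample scores (length >= 4).
#' @param rule "median", "tertile" or "supplied".
#' @param labels For `rule = "supplied"`: a vector of "G0"/"G1" labels (NA
#'   allowed) aligned with `values`.
#' @return Character vector of "G0"/"G1" labels (NA outside the tertile
#'   extremes when `rule = "tertile"`).
#' @export
split_groups <- function(values, rule = c("median", "tertile", "supplied"),
                         labels = NULL) {
  rule <- match.arg(rule)
  if (rule == "supplied") {
    if (is.null(labels) || length(labels) != length(values)) {
      abort("`labels` must be supplied and match `values` in length.")
    }
    bad <- setdiff(unique(labels[!is.na(labels)]), c("G0", "G1"))
    if (length(bad) > 0L) abort("Supplied labels must be 'G0'/'G1' (or NA).")
    return(as.character(labels))
  }
  if (length(values) < 4L) abort("Grouping needs at least 4 samples.")
  if (length(unique(values[!is.na(values)])) < 2L) {
    abort("All values identical; no low/high split possible.")
  }
  if (rule == "median") {
    med <- median(values, na.rm = TRUE)
    out <- ifelse(values <= med, "G0", "G1")
  } else {
    qs <- quantile(values, c(1 / 3, 2 / 3), na.rm = TRUE, names = FALSE)
    out <- rep(NA_character_, length(values))
    out[values <= qs[1]] <- "G0"
    out[values > qs[2]] <- "G1"
  }
  out[is.na(values)] <- NA_character_
  out
}

#' Signed log10 pathway score for one gene set
#'
#' The pathway score condenses a two-group comparison of patient scores into
#' a signed magnitude: `magnitude = log10(|G0avg - G1avg|)` where `G0avg`
#' and `G1avg` are the groups' mean patient scores, and the sign is +1 when
#' the set is higher in G1, -1 when higher in G0, and 0 when the two-tailed
#' equal-variance t-test comparing the groups is not significant at `alpha`
#' (then the score itself is 0). The absolute difference is clamped below at
#' `floor` before the log so a (practically unattainable) exact tie cannot
#' produce -Inf; differences below 1 legitimately give negative magnitudes —
#' the formula targets scores summed over many genes, where the difference
#' is typically far above 1.
#'
#' @param table Score table from [patient_scores()] (or any tibble with a
#'   `sample_id` column and the set column).
#' @param labels "G0"/"G1" labels aligned with the table rows (NA rows are
#'   dropped).
#' @param set_name Which score column to test.
#' @param alpha Significance cutoff for the sign rule (default 0.05).
#' @param floor Lower clamp on `|G0avg - G1avg|` before log10.
#' @return One-row tibble: `set_name`, `g0_avg`, `g1_avg`, `n0`, `n1`,
#'   `p_value`, `sign`, `magnitude`, `pathway_score`.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = sprintf("s%d", 1:8),
#'                       S = c(5, 5, 5, 5, 3, 3, 3, 3) + rnorm(8, 0, 1e-6))
#' pathway_score(tbl, rep(c("G0", "G1"), each = 4), "S")
pathway_score <- function(table, labels, set_name, alpha = 0.05,
                          floor = 1e-12) {
  if (!set_name %in% names(table)) {
    abort(sprintf("Set `%s` not found in score table.", set_name))
  }
  if (length(labels) != nrow(table)) {
    abort("`labels` must align with the rows of `table`.")
  }
  keep <- !is.na(labels)
  vals <- table[[set_name]][keep]
  grp <- labels[keep]
  n0 <- sum(grp == "G0"); n1 <- sum(grp == "G1")
  if (n0 < 2L || n1 < 2L) {
    abort("Both groups need at least 2 samples for a pathway score.")
  }
  g0 <- vals[grp == "G0"]; g1 <- vals[grp == "G1"]
  if (sd(g0) == 0 && sd(g1) == 0 && mean(g0) == mean(g1)) {
    p <- 1
  } else {
    p <- t.test(g0, g1, var.equal = TRUE)$p.value
  }
  g0_avg <- mean(g0); g1_avg <- mean(g1)
  magnitude <- log10(max(abs(g0_avg - g1_avg), floor))
  sgn <- if (p >= alpha) 0L else if (g0_avg > g1_avg) -1L else 1L
  tibble::tibble(
    set_name = set_name,
    g0_avg = g0_avg, g1_avg = g1_avg,
    n0 = n0, n1 = n1,
    p_value = p,
    sign = sgn,
    magnitude = magnitude,
    pathway_score = sgn * magnitude
  )
}

#' Pathway-score matrix across cohorts
#'
#' Computes the signed pathway score of each gene set in each cohort,
#' producing the long table behind an enrichment heatmap (gene sets as rows,
#' cohorts as columns). Per-cell failures (e.g. a group with fewer than two
#' samples) become NA cells with a warning rather than aborting the matrix.
#'
#' @param tables Named list of cohorts, each a list with elements `scores`
#'   (a [patient_scores()] table) and `labels` ("G0"/"G1" per row).
#' @param sets Character vector of set names to include; defaults to every
#'   score column of the first cohort.
#' @param alpha Significance cutoff passed to [pathway_score()].
#' @return Long tibble (`cohort`, `set_name`, `pathway_score`, `p_value`,
#'   `sign`) of class `enrichment_matrix`; see [autoplot.enrichment_matrix()].
#' @export
enrichment_matrix <- function(tables, sets = NULL, alpha = 0.05) {
  if (!is.list(tables) || length(tables) == 0L) {
    abort("`tables` must be a non-empty named list of cohorts.")
  }
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- sprintf("cohort%d", seq_along(tables))
  }
  if (is.null(sets)) {
    sets <- setdiff(names(tables[[1]]$scores), "sample_id")
  }
  rows <- purrr::imap(tables, function(cohort, cname) {
    purrr::map(sets, function(s) {
      rec <- tryCatch(
        pathway_score(cohort$scores, cohort$labels, s, alpha = alpha),
        error = function(e) {
          warn(sprintf("Cell (%s, %s) failed: %s", cname, s, conditionMessage(e)))
          tibble::tibble(set_name = s, g0_avg = NA_real_, g1_avg = NA_real_,
                         n0 = NA_integer_, n1 = NA_integer_,
                         p_value = NA_real_, sign = NA_integer_,
                         magnitude = NA_real_, pathway_score = NA_real_)
        }
      )
      dplyr::mutate(rec, cohort = cname, .before = 1L)
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  out <- out[c("cohort", "set_name", "pathway_score", "p_value", "sign",
               "g0_avg", "g1_avg", "n0", "n1", "magnitude")]
  class(out) <- c("enrichment_matrix", class(out))
  out
}

#' Hypergeometric over-representation of a query gene list
#'
#' For each gene set, computes the upper-tail hypergeometric probability of
#' observing at least the actual overlap between the query list and the set
#' within a finite gene universe — the standard over-representation test
#' behind pathway-enrichment bar charts. Sets are returned ranked by
#' ascending p, with Benjamini-Hochberg adjusted values alongside.
#'
#' @param query Character vector of gene ids; must be a subset of
#'   `universe`.
#' @param sets Gene-set tibble (`set_name`, `gene_id`).
#' @param universe Character vector: all testable gene ids.
#' @return Tibble with `set_name`, `set_size` (within the universe),
#'   `overlap`, `p_value`, `p_adjusted`, ascending in `p_value`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe) {
  check_gene_sets(sets)
  universe <- unique(universe)
  if (length(universe) == 0L) abort("`universe` is empty.")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    abort(sprintf("%d query gene(s) are outside the universe (e.g. %s).",
                  length(outside), outside[1]))
  }
  n <- length(query)
  N <- length(universe)
  per_set <- sets |>
    dplyr::distinct(.data$set_name, .data$gene_id) |>
    dplyr::filter(.data$gene_id %in% universe) |>
    dplyr::group_by(.data$set_name) |>
    dplyr::summarise(
      set_size = dplyr::n(),
      overlap = sum(.data$gene_id %in% query),
      .groups = "drop"
    )
  per_set$p_value <- phyper(per_set$overlap - 1, per_set$set_size,
                            N - per_set$set_size, n, lower.tail = FALSE)
  per_set$p_adjusted <- p.adjust(per_set$p_value, method = "BH")
  dplyr::arrange(per_set, .data$p_value, .data$set_name)
}
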