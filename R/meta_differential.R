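#' Per-gene Z-score normalization within one dataset
#'
#' Standardizes every gene across all samples of a dataset (tumor and normal
#' together), using the sample SD (denominator n - 1). Missing entries are
#' excluded from the mean/SD and remain missing in the output. Genes with
#' zero variance (or fewer than two finite values) become all-zero rows so
#' that gene universes stay aligned across datasets; they are recorded in
#' the `zero_variance` attribute and treated as untestable downstream.
#'
#' @param expr Expression tibble: `gene_id` column plus one numeric column
#'   per sample. A `dataset_id` attribute, if present, is preserved.
#' @return A tibble of the same shape holding Z-scores, with attributes
#'   `dataset_id` and `zero_variance` (character vector of constant genes).
#' @export
#' @examples
#' m <- tibble::tibble(gene_id = "g1", s1 = 1, s2 = 2, s3 = 3)
#' zscore_normalize(m)  # -1, 0, 1
zscore_normalize <- function(expr) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2L) {
    abort("Z-score normalization needs at least 2 samples (SD undefined).")
  }
  st <- row_mean_sd(m)
  usable <- !is.na(st$sd) & st$sd > 0
  z <- m
  z[usable, ] <- (m[usable, , drop = FALSE] - st$mean[usable]) / st$sd[usable]
  if (any(!usable)) {
    zeros <- m[!usable, , drop = FALSE]
    zeros[!is.na(zeros)] <- 0
    z[!usable, ] <- zeros
  }
  out <- matrix_to_expr(z, dataset_id = dataset_id_of(expr))
  attr(out, "zero_variance") <- rownames(m)[!usable]
  out
}

#' Pool Z-scored datasets over their shared gene universe
#'
#' Column-concatenates a list of Z-scored matrices over the intersection of
#' their gene ids. Sample ids are prefixed with the dataset id
#' (`<dataset>.<sample>`) so they stay unique. Genes absent from any dataset
#' are dropped and reported via a message and the `dropped_genes` attribute.
#'
#' @param z_list List of Z-score tibbles as returned by [zscore_normalize()].
#'   Dataset ids are taken from each element's `dataset_id` attribute, or
#'   from the list names as a fallback.
#' @return A pooled Z-score tibble with attribute `sample_dataset` (named
#'   character vector mapping pooled sample id to source dataset).
#' @export
pool_datasets <- function(z_list) {
  if (!is.list(z_list) || length(z_list) == 0L) {
    abort("`z_list` must be a non-empty list of Z-score matrices.")
  }
  ids <- purrr::imap_chr(z_list, function(x, i) {
    dataset_id_of(x) %||% (if (is.character(i) && nzchar(i)) i else sprintf("d%s", i))
  })
  if (anyDuplicated(ids)) abort("Dataset ids must be unique when pooling.")
  mats <- purrr::map(z_list, expr_to_matrix, arg = "z_list element")
  shared <- Reduce(intersect, purrr::map(mats, rownames))
  if (length(shared) == 0L) {
    abort("No genes are shared by all datasets; cannot pool.")
  }
  n_union <- length(Reduce(union, purrr::map(mats, rownames)))
  dropped <- n_union - length(shared)
  if (dropped > 0L) {
    inform(sprintf("Dropping %d gene(s) absent from at least one dataset.", dropped))
  }
  blocks <- purrr::map2(mats, ids, function(m, id) {
    b <- m[shared, , drop = FALSE]
    colnames(b) <- paste(id, colnames(b), sep = ".")
    b
  })
  pooled <- do.call(cbind, blocks)
  out <- matrix_to_expr(pooled, dataset_id = "pooled")
  attr(out, "sample_dataset") <- setNames(
    rep(ids, times = purrr::map_int(mats, ncol)),
    colnames(pooled)
  )
  attr(out, "dropped_genes") <- setdiff(Reduce(union, purrr::map(mats, rownames)), shared)
  out
}

#' Pooled tumor-vs-normal differential test
#'
#' Runs a classical two-tailed equal-variance (Student) t-test per gene on
#' the pooled Z-score matrix, comparing tumor against normal samples, and
#' applies Bonferroni correction with multiplier m = number of genes
#' actually tested. Genes with fewer than two finite values in either group
#' are untestable and reported via the `untestable` attribute; zero-variance
#' genes from normalization fall in this class too (their pooled values are
#' constant, giving t = 0, p = 1 when both group means coincide).
#'
#' @param pooled Pooled Z-score tibble from [pool_datasets()] (any
#'   expression-shaped tibble works).
#' @param clinical Clinical tibble with `sample_id` and `condition`
#'   (values "tumor"/"normal") covering the pooled samples.
#' @return Tibble with one row per testable gene: `gene_id`, `n_tumor`,
#'   `n_normal`, `mean_diff` (tumor - normal, Z-units), `t_statistic`,
#'   `p_raw`, `p_bonferroni`, `direction` ("up" iff `mean_diff` > 0).
#'   Attribute `untestable` lists genes that could not be tested.
#' @export
differential_test <- function(pooled, clinical) {
  m <- expr_to_matrix(pooled, arg = "pooled")
  if (!is.data.frame(clinical) ||
      !all(c("sample_id", "condition") %in% names(clinical))) {
    abort("`clinical` must have `sample_id` and `condition` columns.")
  }
  cond <- clinical$condition[match(colnames(m), clinical$sample_id)]
  unknown <- colnames(m)[is.na(cond)]
  if (length(unknown) > 0L) {
    warn(sprintf("Dropping %d sample(s) missing from `clinical`.", length(unknown)))
  }
  keep <- !is.na(cond) & cond %in% c("tumor", "normal")
  m <- m[, keep, drop = FALSE]
  cond <- cond[keep]
  if (!any(cond == "tumor") || !any(cond == "normal")) {
    abort("Both conditions (tumor and normal) must be present.")
  }
  mt <- m[, cond == "tumor", drop = FALSE]
  mn <- m[, cond == "normal", drop = FALSE]
  st_t <- row_mean_sd(mt)
  st_n <- row_mean_sd(mn)
  testable <- st_t$n >= 2L & st_n$n >= 2L
  n1 <- st_t$n; n2 <- st_n$n
  diff <- st_t$mean - st_n$mean
  sp2 <- ((n1 - 1) * st_t$sd^2 + (n2 - 1) * st_n$sd^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- diff / se
  df <- n1 + n2 - 2
  # degenerate pooled variance: identical constants give t = 0, p = 1;
  # a nonzero mean difference with zero spread is maximally significant
  zero_se <- testable & !is.na(se) & se == 0
  tstat[zero_se & diff == 0] <- 0
  tstat[zero_se & diff != 0] <- sign(diff[zero_se & diff != 0]) * Inf
  p_raw <- 2 * pt(-abs(tstat), df)
  p_raw[zero_se & diff == 0] <- 1
  p_raw[zero_se & diff != 0] <- 0

  genes <- rownames(m)
  res <- tibble::tibble(
    gene_id = genes[testable],
    n_tumor = as.integer(unname(n1[testable])),
    n_normal = as.integer(unname(n2[testable])),
    mean_diff = unname(diff[testable]),
    t_statistic = unname(tstat[testable]),
    p_raw = unname(p_raw[testable])
  )
  m_tests <- nrow(res)
  res$p_bonferroni <- pmin(1, res$p_raw * m_tests)
  res$direction <- ifelse(res$mean_diff > 0, "up", "down")
  attr(res, "untestable") <- genes[!testable]
  attr(res, "n_tests") <- m_tests
  res
}

#' Top-N significant genes in one direction
#'
#' Filters a differential table to genes of the requested direction with
#' Bonferroni-adjusted p below `alpha`, ranks by adjusted p ascending with
#' ties broken by absolute mean difference descending then gene id, and
#' truncates to `n`. Returns fewer than `n` genes when fewer qualify.
#'
#' @param records Differential table from [differential_test()].
#' @param n Maximum list length.
#' @param direction "up" or "down".
#' @param alpha Significance cutoff on `p_bonferroni` (default 0.05).
#' @return Character vector of gene ids, best first.
#' @export
top_n_genes <- function(records, n = 1000, direction = c("down", "up"),
                        alpha = 0.05) {
  direction <- match.arg(direction)
  if (n < 1) abort("`n` must be >= 1.")
  hits <- dplyr::filter(records, .data$direction == !!direction,
                        .data$p_bonferroni < alpha)
  hits <- dplyr::arrange(hits, .data$p_bonferroni,
                         dplyr::desc(abs(.data$mean_diff)), .data$gene_id)
  head(hits$gene_id, n)
}

#' Z-difference rule for a single treated/control sample pair
#'
#' When only one expression profile per condition is available, each profile
#' is standardized across genes within the sample, and a gene is called
#' differential when the absolute difference of its two within-sample
#' Z-scores strictly exceeds `threshold` (default 1.96, i.e. the two-sided
#' 5% normal quantile; the boundary value itself is not flagged).
#'
#' @param expr Expression tibble containing (at least) the two sample
#'   columns named by `treated` and `control` over the same gene universe.
#' @param treated,control Column names of the treated and control samples.
#' @param threshold Flagging threshold on `|z_diff|` (strict inequality).
#' @return Tibble with `gene_id`, `z_treated`, `z_control`, `z_diff`
#'   (treated - control) and logical `is_differential`.
#' @export
zdiff_single_pair <- function(expr, treated, control, threshold = 1.96) {
  m <- expr_to_matrix(expr)
  for (col in c(treated, control)) {
    if (!col %in% colnames(m)) abort(sprintf("Sample `%s` not found in `expr`.", col))
  }
  if (nrow(m) < 3L) abort("Z-difference rule needs at least 3 genes.")
  zcol <- function(v) {
    if (anyNA(v)) abort("Missing values are not supported in single-pair columns.")
    s <- sd(v)
    if (s == 0) abort("A column with zero variance across genes cannot be standardized.")
    (v - mean(v)) / s
  }
  zt <- zcol(m[, treated])
  zc <- zcol(m[, control])
  zd <- zt - zc
  tibble::tibble(
    gene_id = rownames(m),
    z_treated = zt,
    z_control = zc,
    z_diff = zd,
    is_differential = abs(zd) > threshold
  )
}
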