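#' Kaplan-Meier product-limit estimator
#'
#' Nonparametric survival curve from right-censored data. At each distinct
#' observed time the risk set shrinks by the subjects who had an event or
#' were censored there; the survival probability steps down only at event
#' times, by the factor `1 - d/n`.
#'
#' @param times Positive observation times.
#' @param events Event indicators: 1 = event, 0 = censored.
#' @return A `km_curve`: tibble with `time` (distinct, ascending),
#'   `n_risk`, `n_event`, `n_censor`, `survival`, plus an `n` attribute.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 0))
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  ord <- order(times)
  times <- times[ord]; events <- events[ord]
  ut <- unique(times)
  d <- vapply(ut, function(t) sum(events[times == t] == 1L), integer(1))
  cns <- vapply(ut, function(t) sum(events[times == t] == 0L), integer(1))
  n_risk <- length(times) - c(0L, cumsum(d + cns))[seq_along(ut)]
  surv <- cumprod(1 - d / n_risk)
  out <- tibble::tibble(
    time = ut, n_risk = n_risk, n_event = d, n_censor = cns, survival = surv
  )
  attr(out, "n") <- length(times)
  class(out) <- c("km_curve", class(out))
  out
}

check_surv_input <- function(times, events) {
  if (length(times) == 0L) abort("Survival input is empty.")
  if (length(times) != length(events)) {
    abort("`times` and `events` must have equal length.")
  }
  if (anyNA(times) || anyNA(events)) {
    abort("Missing times/events must be excluded before estimation.")
  }
  if (any(times <= 0)) abort("All survival times must be > 0.")
  if (!all(events %in% c(0, 1))) abort("`events` must be 0/1.")
  invisible(TRUE)
}

#' Survival probability at a time point
#'
#' Step-function evaluation of a [km_estimate()] curve: S(t) is 1 before
#' the first observed time and constant between steps.
#'
#' @param curve A `km_curve`.
#' @param t Time point(s).
#' @return Numeric survival probabilities.
#' @export
km_survival_at <- function(curve, t) {
  vapply(t, function(tt) {
    idx <- which(curve$time <= tt)
    if (length(idx) == 0L) 1 else curve$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' Classical 1-df log-rank chi-square over the pooled risk sets, with all
#' events at a tied time contributing to the same risk-set row
#' (hypergeometric variance). Symmetric in the group labels.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Two-level group labels (e.g. "G0"/"G1") per subject.
#' @return An `lr_test` list: `chi_square`, `p_value`, `group_sizes`,
#'   `observed`, `expected` (per group, in label order).
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  if (length(groups) != length(times)) {
    abort("`groups` must align with `times`.")
  }
  keep <- !is.na(groups)
  times <- times[keep]; events <- events[keep]; groups <- as.character(groups[keep])
  lev <- sort(unique(groups))
  if (length(lev) != 2L) abort("Exactly two non-empty groups are required.")
  if (sum(events) == 0L) abort("At least one event is required.")
  g1 <- groups == lev[1]
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v1 <- 0
  for (t in ut) {
    at_risk <- times >= t
    n_j <- sum(at_risk)
    n1_j <- sum(at_risk & g1)
    d_j <- sum(times == t & events == 1)
    d1_j <- sum(times == t & events == 1 & g1)
    o1 <- o1 + d1_j
    e1 <- e1 + d_j * n1_j / n_j
    if (n_j > 1) {
      v1 <- v1 + d_j * (n_j - d_j) * n1_j * (n_j - n1_j) / (n_j^2 * (n_j - 1))
    }
  }
  if (v1 <= 0) {
    chi <- 0
  } else {
    chi <- (o1 - e1)^2 / v1
  }
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  structure(list(
    chi_square = chi,
    p_value = p,
    group_sizes = setNames(c(sum(g1), sum(!g1)), lev),
    observed = setNames(c(o1, sum(events) - o1), lev),
    expected = setNames(c(e1, sum(events) - e1), lev)
  ), class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("<log-rank test> chi-square = %.4g (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d, O=%.3g, E=%.3g)", names(x$group_sizes),
                            x$group_sizes, x$observed, x$expected),
                    collapse = "; ")))
  invisible(x)
}

#' @rdname logrank_test
#' @param x An `lr_test`.
#' @param ... Unused.
#' @export
glance.lr_test <- function(x, ...) {
  tibble::tibble(
    chi_square = x$chi_square,
    p_value = x$p_value,
    n = sum(x$group_sizes),
    df = 1L
  )
}

#' @rdname km_estimate
#' @param x A `km_curve`.
#' @param ... Unused.
#' @export
tidy.km_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("time", "n_risk", "n_event", "n_censor", "survival")])
}

#' Flag genes whose expression is associated with survival
#'
#' For each gene, tumor samples with outcome data are median-split on the
#' gene's Z-score and compared by log-rank test; the gene is flagged when
#' p < `alpha`. The direction records whether high expression tracks good
#' or poor survival, read off the two groups' KM curves at the median
#' follow-up time.
#'
#' @param z Z-score tibble (pooled or single-cohort).
#' @param clinical Clinical tibble with `sample_id`, `condition`,
#'   `survival_time`, `event`; only tumor rows with complete outcomes are
#'   used ("no available time or event" means exclusion).
#' @param alpha Flagging cutoff (default 0.05).
#' @param genes Optional subset of gene ids to test (default: all).
#' @return Tibble with `gene_id`, `p_value`, `flagged`, `direction`
#'   ("good_with_high" / "poor_with_high" / NA for untestable genes).
#' @export
flag_survival_genes <- function(z, clinical, alpha = 0.05, genes = NULL) {
  m <- expr_to_matrix(z, arg = "z")
  cl <- dplyr::filter(clinical, .data$condition == "tumor",
                      !is.na(.data$survival_time), !is.na(.data$event))
  cl <- cl[cl$sample_id %in% colnames(m), , drop = FALSE]
  if (nrow(cl) < 4L) {
    abort("Fewer than 4 tumor samples with outcomes; cannot flag genes.")
  }
  m <- m[, cl$sample_id, drop = FALSE]
  if (!is.null(genes)) {
    genes <- intersect(genes, rownames(m))
    m <- m[genes, , drop = FALSE]
  }
  med_fu <- median(cl$survival_time)
  res <- purrr::map(rownames(m), function(g) {
    v <- m[g, ]
    if (length(unique(v[!is.na(v)])) < 2L) {
      return(tibble::tibble(gene_id = g, p_value = NA_real_, flagged = FALSE,
                            direction = NA_character_))
    }
    grp <- split_groups(v, rule = "median")
    lr <- tryCatch(logrank_test(cl$survival_time, cl$event, grp),
                   error = function(e) NULL)
    if (is.null(lr)) {
      return(tibble::tibble(gene_id = g, p_value = NA_real_, flagged = FALSE,
                            direction = NA_character_))
    }
    km_hi <- km_estimate(cl$survival_time[grp == "G1"], cl$event[grp == "G1"])
    km_lo <- km_estimate(cl$survival_time[grp == "G0"], cl$event[grp == "G0"])
    dir <- if (km_survival_at(km_hi, med_fu) >= km_survival_at(km_lo, med_fu)) {
      "good_with_high"
    } else {
      "poor_with_high"
    }
    tibble::tibble(gene_id = g, p_value = lr$p_value,
                   flagged = lr$p_value < alpha, direction = dir)
  })
  dplyr::bind_rows(res)
}

#' Compare a per-sample score across levels of a clinical covariate
#'
#' Summarizes a numeric score (e.g. a signature patient score) within each
#' level of an ordinal/categorical covariate (stage, grade, prognosis,
#' vascular invasion) and runs two-tailed equal-variance t-tests between
#' level pairs — by default the extreme pair (first vs last level, e.g.
#' Stage I vs III), optionally all pairs. Levels with fewer than 2 samples
#' are dropped with a warning. P-values are uncorrected by default, as is
#' conventional for these per-panel comparisons; set `adjust = "holm"` (or
#' any [stats::p.adjust] method) to correct.
#'
#' @param values Data frame with `sample_id` and a numeric `score` column,
#'   or a named numeric vector.
#' @param clinical Clinical tibble containing `sample_id` and the covariate.
#' @param covariate Covariate column name.
#' @param pairs "extremes" (default) or "all".
#' @param adjust P-adjustment method (default "none").
#' @return A `covariate_comparison` list with tibbles `summary`
#'   (level, n, mean, sd) and `tests` (level_a, level_b, mean_a, mean_b,
#'   p_value); `tidy()` returns the tests.
#' @export
compare_by_covariate <- function(values, clinical, covariate,
                                 pairs = c("extremes", "all"),
                                 adjust = "none") {
  pairs <- match.arg(pairs)
  if (is.numeric(values) && !is.null(names(values))) {
    values <- tibble::tibble(sample_id = names(values), score = unname(values))
  }
  if (!all(c("sample_id", "score") %in% names(values))) {
    abort("`values` must have `sample_id` and `score` columns.")
  }
  if (!covariate %in% names(clinical)) {
    abort(sprintf("Covariate `%s` not found in `clinical`.", covariate))
  }
  df <- dplyr::inner_join(values, clinical[c("sample_id", covariate)],
                          by = "sample_id")
  df$level <- df[[covariate]]
  df <- df[!is.na(df$level) & !is.na(df$score), , drop = FALSE]
  counts <- table(df$level)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warn(sprintf("Dropping level(s) with < 2 samples: %s",
                 paste(small, collapse = ", ")))
    df <- df[!df$level %in% small, , drop = FALSE]
  }
  levels_seen <- sort(unique(df$level))
  if (length(levels_seen) < 2L) {
    abort("Covariate needs at least 2 usable levels.")
  }
  summ <- df |>
    dplyr::group_by(level = .data$level) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                     sd = sd(.data$score), .groups = "drop")
  pair_list <- if (pairs == "extremes") {
    list(c(levels_seen[1], levels_seen[length(levels_seen)]))
  } else {
    utils::combn(levels_seen, 2, simplify = FALSE)
  }
  tests <- purrr::map(pair_list, function(pr) {
    a <- df$score[df$level == pr[1]]
    b <- df$score[df$level == pr[2]]
    p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) 1 else
      t.test(a, b, var.equal = TRUE)$p.value
    tibble::tibble(level_a = pr[1], level_b = pr[2],
                   mean_a = mean(a), mean_b = mean(b), p_value = p)
  }) |> dplyr::bind_rows()
  tests$p_value <- p.adjust(tests$p_value, method = adjust)
  structure(list(summary = summ, tests = tests, covariate = covariate),
            class = "covariate_comparison")
}

#' @export
print.covariate_comparison <- function(x, ...) {
  cat(sprintf("<covariate_comparison> %s\n", x$covariate))
  print(x$summary)
  print(x$tests)
  invisible(x)
}

#' @rdname compare_by_covariate
#' @param x A `covariate_comparison`.
#' @param ... Unused.
#' @export
tidy.covariate_comparison <- function(x, ...) x$tests

#' Pearson correlation between two per-sample quantities
#'
#' Thin, validated wrapper around the two-sided Pearson correlation test,
#' used e.g. to relate a regulator activity score to a target gene's
#' expression. Pairs with missing values are dropped.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return Tibble with `r`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort("Correlation needs at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: a vector has zero variance.")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
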