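#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate, with censoring marks.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tidy(object)
  start <- tibble::tibble(time = 0, n_risk = attr(object, "n"),
                          n_event = 0L, n_censor = 0L, survival = 1)
  df <- dplyr::bind_rows(start, df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(df, .data$n_censor > 0),
                        shape = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot KM curves for low/high score groups
#'
#' @param curves Named list of `km_curve` objects (e.g. `G0`, `G1`).
#' @return A ggplot object.
#' @export
plot_km_groups <- function(curves) {
  df <- purrr::imap(curves, function(cv, nm) {
    dplyr::mutate(
      dplyr::bind_rows(
        tibble::tibble(time = 0, survival = 1),
        tidy(cv)[c("time", "survival")]
      ),
      group = nm
    )
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability", color = "Group") +
    ggplot2::theme_minimal()
}

#' Heatmap of a pathway-score enrichment matrix
#'
#' Gene sets as rows, cohorts as columns, tiles filled by the signed
#' pathway score (blue = enriched in G0, red = enriched in G1, white =
#' not significant).
#'
#' @param object An `enrichment_matrix` from [enrichment_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cohort, y = .data$set_name,
                                       fill = .data$pathway_score)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  na.value = "grey50") +
    ggplot2::labs(x = "Cohort", y = NULL, fill = "Pathway\nscore") +
    ggplot2::theme_minimal()
}

#' Dot plot of a score across covariate levels
#'
#' @param values Data frame with `sample_id` and `score`.
#' @param clinical Clinical tibble with `sample_id` and the covariate.
#' @param covariate Covariate column name.
#' @return A ggplot object.
#' @export
plot_score_by_covariate <- function(values, clinical, covariate) {
  df <- dplyr::inner_join(values, clinical[c("sample_id", covariate)],
                          by = "sample_id")
  df$level <- df[[covariate]]
  df <- df[!is.na(df$level), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          color = "red") +
    ggplot2::labs(x = covariate, y = "Patient score") +
    ggplot2::theme_minimal()
}
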