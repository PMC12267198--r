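#' Per-year impact bars for a scenario comparison
#'
#' One panel per outcome, bars showing the scenario II minus scenario I
#' difference accrued in each calendar year — the signature display of the
#' projection, where gains in life-years and reductions in recurrences and
#' deaths build up only several years after adoption, and the
#' adverse-event difference starts positive (more early-setting treatment)
#' before turning negative (fewer metastatic treatments).
#'
#' @param object A `pdl1_comparison`.
#' @param outcomes Outcomes to display (default: all eight).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdl1_comparison <- function(object, outcomes = outcome_names(),
                                     ...) {
  df <- tidy(object, type = "per_year")
  df <- df[df$outcome %in% outcomes, ]
  df$outcome <- factor(df$outcome, levels = outcome_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$difference,
                                   fill = .data$difference >= 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "#d95f0e")) +
    ggplot2::labs(x = "calendar year",
                  y = "scenario II − scenario I",
                  title = "Health impact of early-setting anti-PD-(L)1 use, by year") +
    ggplot2::theme_minimal()
}

#' Tornado diagram for a one-way sensitivity analysis
#'
#' Horizontal bars from the low- to the high-perturbation impact for one
#' outcome, ordered by impact range.
#'
#' @param object A `pdl1_tornado` from [one_way_sa()].
#' @param outcome Outcome to display (default: the analysis' sort key).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pdl1_tornado <- function(object, outcome = NULL, ...) {
  outcome <- outcome %||% attr(object, "sort_by")
  df <- object[object$outcome == outcome, ]
  df$variable <- factor(df$variable, levels = rev(unique(df$variable)))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$variable)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$low, xend = .data$high,
                                       yend = .data$variable),
                          linewidth = 4, colour = "#2c7fb8") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$base),
                        linetype = 2) +
    ggplot2::labs(x = paste("cumulative impact on", outcome),
                  y = NULL, title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Per-year outcome trajectories for one scenario
#'
#' @param object An `outcome_set`.
#' @param outcomes Outcomes to display (default: all eight).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outcome_set <- function(object, outcomes = outcome_names(), ...) {
  df <- tidy(object)
  df <- df[df$outcome %in% outcomes, ]
  df$outcome <- factor(df$outcome, levels = outcome_names())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "calendar year", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
print.pdl1_sensitivity <- function(x, ...) {
  cat("<pdl1_sensitivity> toggle:", attr(x, "toggle"), "\n")
  NextMethod()
}

#' Tidy a scenario sensitivity result
#'
#' @param x A `pdl1_sensitivity`.
#' @param ... Unused.
#' @return The underlying tibble with a `toggle` column prepended.
#' @export
tidy.pdl1_sensitivity <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(toggle = attr(x, "toggle")),
                   tibble::as_tibble(x))
}
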