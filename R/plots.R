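#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col facet_wrap labs scale_y_log10 position_dodge2
#' @export
ggplot2::autoplot

#' Plot a Lee-Carter fit
#'
#' Three panels: the age schedule `a(x)`, the loadings `b(x)` and the
#' mortality index `k(t)`.
#'
#' @param object A [fit_lee_carter()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lee_carter_fit <- function(object, ...) {
  td <- tidy(object)
  td$label <- factor(td$label, levels = unique(td$label))
  ggplot(td, aes(x = .data$label, y = .data$estimate, group = 1)) +
    geom_line() + geom_point(size = 0.8) +
    facet_wrap(~term, scales = "free") +
    labs(x = NULL, y = "estimate",
         title = "Lee-Carter components: age schedule a, loadings b, index k")
}

#' Plot identified BAPC effects
#' @param object A [fit_bapc()] object.
#' @param gauge Passed to [decompose_effects()].
#' @param ... Unused.
#' @return A ggplot with one panel per effect block and 95% credible bands.
#' @export
autoplot.bapc_fit <- function(object, gauge = "cohort_detrend", ...) {
  ef <- dplyr::filter(decompose_effects(object, gauge)$effects,
                      .data$effect != "intercept")
  ggplot(ef, aes(x = .data$index, y = .data$estimate)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.25) +
    geom_line() +
    facet_wrap(~effect, scales = "free") +
    labs(x = "index", y = "effect (logit scale)",
         title = "Identified age, period and cohort effects")
}

#' Plot a rate forecast
#' @param object A `rate_forecast`.
#' @param ... Unused.
#' @return A ggplot of central rates per age band over time (log scale) with
#'   95% bands.
#' @export
autoplot.rate_forecast <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$age_group <- factor(df$age_group, levels = attr(object, "ages")$labels)
  ggplot(df, aes(x = .data$year, y = .data$m)) +
    geom_ribbon(aes(ymin = .data$m_lower, ymax = .data$m_upper),
                alpha = 0.25) +
    geom_line() +
    facet_wrap(~age_group) +
    scale_y_log10() +
    labs(y = "central death rate (log scale)",
         title = paste0("Forecast death rates (", attr(object, "model"), ")"))
}

#' Plot projected total deaths
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot of observed and projected yearly totals with bounds.
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot(object$totals, aes(x = .data$year, y = .data$deaths)) +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper), alpha = 0.25) +
    geom_line() +
    geom_point(data = object$observed_totals, size = 0.7) +
    labs(y = "deaths",
         title = paste0("Projected total deaths (scenario '",
                        object$scenario, "')"))
}

#' Plot a validation report
#' @param object A `validation_report`.
#' @param ... Unused.
#' @return A ggplot of MAPE by age stratum (and model, if compared).
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$age_group <- factor(df$age_group, levels = unique(df$age_group))
  ggplot(df, aes(x = .data$age_group, y = .data$mape, fill = .data$model)) +
    geom_col(position = position_dodge2()) +
    labs(x = NULL, y = "MAPE (%)",
         title = "Hold-out mean absolute percent error by age stratum")
}
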