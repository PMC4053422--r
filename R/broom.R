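#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a Lee-Carter fit
#'
#' One row per parameter: the age schedule `a`, the age loadings `b` and the
#' mortality index `k` in long format.
#'
#' @param x A [fit_lee_carter()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `label`, `estimate`.
#' @export
tidy.lee_carter_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "a", label = x$ages$age_group,
                   estimate = x$ages$a),
    tibble::tibble(term = "b", label = x$ages$age_group,
                   estimate = x$ages$b),
    tibble::tibble(term = "k", label = as.character(x$index$year),
                   estimate = x$index$k)
  )
}

#' @rdname tidy.lee_carter_fit
#' @return For `glance()`: a one-row tibble with `drift`, `innovation_sd`,
#'   `n_ages`, `n_years`, `adjustment`, `rank1_share` (share of the centred
#'   log-rate variance carried by the leading singular pair, via residuals).
#' @export
glance.lee_carter_fit <- function(x, ...) {
  tibble::tibble(
    drift = x$drift,
    innovation_sd = x$innovation_sd,
    n_ages = nrow(x$ages),
    n_years = nrow(x$index),
    adjustment = x$constraints$adjustment,
    resid_sd = stats::sd(as.vector(x$residuals))
  )
}

#' Tidy a BAPC fit
#'
#' Posterior summaries of the gauge-identified effects (see
#' [decompose_effects()]).
#'
#' @param x A [fit_bapc()] object.
#' @param gauge Passed to [decompose_effects()].
#' @param ... Unused.
#' @return A tibble `effect`, `index`, `label`, `estimate`, `lower`, `upper`.
#' @export
tidy.bapc_fit <- function(x, gauge = "cohort_detrend", ...) {
  decompose_effects(x, gauge = gauge)$effects
}

#' @rdname tidy.bapc_fit
#' @return For `glance()`: one row with `dic`, `p_d`, `mean_deviance`,
#'   `n_draws`, `chains`, `accept_min`, `accept_max` (post-burn-in
#'   single-site acceptance across blocks).
#' @export
glance.bapc_fit <- function(x, ...) {
  d <- dic(x)
  acc <- colMeans(x$accept, na.rm = TRUE)
  acc <- acc[is.finite(acc)]
  tibble::tibble(
    dic = d$dic, p_d = d$p_d, mean_deviance = d$mean_deviance,
    n_draws = length(x$draws$mu), chains = x$spec$chains,
    accept_min = min(acc), accept_max = max(acc)
  )
}

#' @export
tidy.scenario_result <- function(x, ...) x$totals

#' @export
glance.scenario_result <- function(x, ...) {
  final <- x$totals[nrow(x$totals), ]
  tibble::tibble(scenario = x$scenario, sex = x$sex,
                 final_year = final$year, final_deaths = final$deaths,
                 final_lower = final$lower, final_upper = final$upper)
}
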