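#' Project death counts under constant last-observed rates (scenario A)
#'
#' The conventional counterfactual: the death probabilities of the last
#' observed year persist unchanged, and future deaths are obtained by
#' multiplying them by the projected population,
#' `deaths[i, t] = q[i, last] * N[i, t]`. Totals are simple sums over age.
#' Uncertainty, when requested, is binomial sampling variation around the
#' fixed rates — a construction of this package, documented as such.
#'
#' @param s A [mortality_surface()]; its last year supplies the frozen rates.
#' @param proj A [population_projection()] on the same age scheme, starting
#'   no later than the year after the surface ends.
#' @param measure `"probability"` (default): deaths = `q * N`;
#'   `"rate"`: deaths = `m * N` (differs at order `m^2`).
#' @param n_sims Binomial simulations for interval bounds; `0` disables them
#'   (bounds equal the point estimate).
#' @param seed RNG seed for the binomial simulations.
#' @return An object of class `scenario_result`: tibble `cells` (`sex`,
#'   `age_group`, `year`, `deaths`, `lower`, `upper`), tibble `totals`
#'   (`year`, `deaths`, `lower`, `upper`), tibble `observed_totals` from the
#'   surface, the per-draw total matrix, and the scenario label
#'   `"constant"`.
#' @export
scenario_constant <- function(s, proj, measure = c("probability", "rate"),
                              n_sims = 0, seed = 1) {
  stopifnot(inherits(s, "mortality_surface"),
            inherits(proj, "population_projection"))
  measure <- match.arg(measure)
  check_scheme(s, proj)
  last_year <- max(s$year)
  if (min(proj$year) > last_year + 1L) {
    stop("projection must start no later than the year after the surface ends",
         call. = FALSE)
  }
  r <- central_rates(s)
  last <- dplyr::filter(r, .data$year == last_year)
  rate <- if (measure == "probability") last$q else last$m
  names(rate) <- last$age_group
  Np <- surface_matrix(proj, "population")
  I <- nrow(Np); H <- ncol(Np)
  deaths <- rate[rownames(Np)] * Np
  draws_tot <- NULL
  lo <- hi <- deaths
  tot_lo <- tot_hi <- colSums(deaths)
  if (n_sims > 0) {
    with_seed(seed, {
      sims <- array(rbinom(n_sims * I * H, size = round(as.vector(Np)),
                           prob = rep(rate[rownames(Np)], H)),
                    c(I, H, n_sims))
    })
    lo <- apply(sims, c(1, 2), quantile, 0.025, names = FALSE)
    hi <- apply(sims, c(1, 2), quantile, 0.975, names = FALSE)
    draws_tot <- t(apply(sims, c(2, 3), sum))       # n_sims x H
    tot_lo <- apply(draws_tot, 2, quantile, 0.025, names = FALSE)
    tot_hi <- apply(draws_tot, 2, quantile, 0.975, names = FALSE)
  }
  new_scenario_result(s, proj, deaths, lo, hi, colSums(deaths),
                      tot_lo, tot_hi, draws_tot, "constant")
}

#' Project death counts from a rate forecast (scenario B)
#'
#' Applies a model forecast of death probabilities to the projected
#' population: per draw (when the forecast carries draws) or per point
#' estimate, `deaths[i, t] = q[i, t] * N[i, t]`. Totals and intervals come
#' from the 2.5/97.5 percentiles of the per-draw totals.
#'
#' @param f A `rate_forecast` (from [forecast_lee_carter()] or
#'   [predict.bapc_fit()]).
#' @param proj A [population_projection()] on the same grid.
#' @inheritParams scenario_constant
#' @param observed Optional [mortality_surface()] supplying observed yearly
#'   totals for later percent-change summaries.
#' @return A `scenario_result` with label `"forecast"`.
#' @export
scenario_forecast <- function(f, proj, measure = c("probability", "rate"),
                              observed = NULL) {
  stopifnot(inherits(f, "rate_forecast"),
            inherits(proj, "population_projection"))
  measure <- match.arg(measure)
  check_scheme(f, proj)
  if (!setequal(unique(f$year), unique(proj$year))) {
    stop("forecast and projection years do not align", call. = FALSE)
  }
  Np <- surface_matrix(proj, "population")
  Qm <- surface_matrix(f, if (measure == "probability") "q" else "m")
  deaths <- Qm * Np
  draws_q <- attr(f, "draws")
  lo <- surface_matrix(f, "lower") * Np
  hi <- surface_matrix(f, "upper") * Np
  tot <- colSums(deaths)
  tot_lo <- colSums(lo); tot_hi <- colSums(hi)
  draws_tot <- NULL
  if (!is.null(draws_q)) {
    H <- ncol(Np)
    n <- dim(draws_q)[1]
    draws_tot <- matrix(NA_real_, n, H)
    for (h in seq_len(H)) {
      dq <- if (measure == "probability") draws_q[, , h]
            else -log(1 - draws_q[, , h])
      draws_tot[, h] <- dq %*% Np[, h]
    }
    tot_lo <- apply(draws_tot, 2, quantile, 0.025, names = FALSE)
    tot_hi <- apply(draws_tot, 2, quantile, 0.975, names = FALSE)
  }
  new_scenario_result(observed, proj, deaths, lo, hi, tot, tot_lo, tot_hi,
                      draws_tot, "forecast")
}

new_scenario_result <- function(observed, proj, deaths, lo, hi,
                                tot, tot_lo, tot_hi, draws_tot, label) {
  ages <- attr(proj, "ages")
  years <- sort(unique(proj$year))
  I <- n_ages(ages); H <- length(years)
  cells <- tibble::tibble(
    sex = unique(proj$sex),
    age_group = rep(ages$labels, times = H),
    year = rep(years, each = I),
    deaths = as.vector(deaths),
    lower = as.vector(lo), upper = as.vector(hi)
  )
  totals <- tibble::tibble(year = years, deaths = unname(tot),
                           lower = unname(tot_lo), upper = unname(tot_hi))
  obs <- if (!is.null(observed)) {
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(observed), .data$year),
                     deaths = sum(.data$deaths), .groups = "drop")
  } else {
    tibble::tibble(year = integer(), deaths = double())
  }
  structure(list(cells = cells, totals = totals, observed_totals = obs,
                 draws_totals = draws_tot, scenario = label,
                 sex = unique(proj$sex), ages = ages),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> '", x$scenario, "', ", x$sex, ", years ",
      min(x$totals$year), "-", max(x$totals$year), "\n", sep = "")
  print(utils::tail(x$totals, 3))
  invisible(x)
}

#' Percent change of projected total deaths versus a reference year
#'
#' `100 * (total[t] - total[ref]) / total[ref]` for every projected year,
#' with interval bounds propagated per draw against the fixed observed
#' reference total. The reference defaults to the last observed year in the
#' scenario's observed series.
#'
#' @param result A `scenario_result` whose `observed_totals` include the
#'   reference year (pass `observed =` to [scenario_forecast()], or use
#'   [scenario_constant()] which records it automatically).
#' @param reference_year Observed year to compare against; default the last
#'   observed year.
#' @return A tibble `year`, `pct_change`, `lower`, `upper`.
#' @examples
#' # ref total 100, final total 162 -> +62%
#' @export
percent_change <- function(result, reference_year = NULL) {
  stopifnot(inherits(result, "scenario_result"))
  obs <- result$observed_totals
  if (nrow(obs) == 0L) {
    stop("scenario carries no observed totals to use as reference",
         call. = FALSE)
  }
  reference_year <- reference_year %||% max(obs$year)
  ref <- obs$deaths[obs$year == reference_year]
  if (length(ref) != 1L) {
    stop("reference year ", reference_year, " not in the observed data",
         call. = FALSE)
  }
  if (ref == 0) stop("zero reference total", call. = FALSE)
  pc <- function(x) 100 * (x - ref) / ref
  out <- tibble::tibble(year = result$totals$year,
                        pct_change = pc(result$totals$deaths),
                        lower = pc(result$totals$lower),
                        upper = pc(result$totals$upper))
  if (!is.null(result$draws_totals)) {
    out$lower <- pc(apply(result$draws_totals, 2, quantile, 0.025,
                          names = FALSE))
    out$upper <- pc(apply(result$draws_totals, 2, quantile, 0.975,
                          names = FALSE))
  }
  out
}

#' Combine single-sex scenario results into a both-sexes total
#'
#' Sums cell deaths, totals, observed totals and (when all components carry
#' them with equal draw counts) the per-draw totals.
#'
#' @param ... Two or more `scenario_result` objects on the same years.
#' @return A `scenario_result` with `sex = "all"`.
#' @export
combine_scenarios <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) >= 2L,
            all(vapply(parts, inherits, TRUE, "scenario_result")))
  years <- parts[[1]]$totals$year
  for (p in parts[-1]) {
    if (!identical(p$totals$year, years)) {
      stop("scenario years do not align", call. = FALSE)
    }
  }
  add <- function(get) Reduce(`+`, lapply(parts, get))
  cells <- parts[[1]]$cells
  cells$deaths <- add(function(p) p$cells$deaths)
  cells$lower <- add(function(p) p$cells$lower)
  cells$upper <- add(function(p) p$cells$upper)
  cells$sex <- "all"
  totals <- tibble::tibble(year = years,
                           deaths = add(function(p) p$totals$deaths),
                           lower = NA_real_, upper = NA_real_)
  draws <- lapply(parts, `[[`, "draws_totals")
  draws_tot <- NULL
  if (all(!vapply(draws, is.null, TRUE)) &&
      length(unique(vapply(draws, nrow, 1L))) == 1L) {
    draws_tot <- Reduce(`+`, draws)
    totals$lower <- apply(draws_tot, 2, quantile, 0.025, names = FALSE)
    totals$upper <- apply(draws_tot, 2, quantile, 0.975, names = FALSE)
  } else {
    totals$lower <- add(function(p) p$totals$lower)
    totals$upper <- add(function(p) p$totals$upper)
  }
  obs_all <- dplyr::bind_rows(lapply(parts, `[[`, "observed_totals"))
  obs <- dplyr::summarise(dplyr::group_by(obs_all, .data$year),
                          deaths = sum(.data$deaths), .groups = "drop")
  structure(list(cells = cells, totals = totals, observed_totals = obs,
                 draws_totals = draws_tot,
                 scenario = parts[[1]]$scenario, sex = "all",
                 ages = parts[[1]]$ages),
            class = "scenario_result")
}

check_scheme <- function(a, b) {
  sa <- attr(a, "ages"); sb <- attr(b, "ages")
  if (!same_scheme(sa, sb)) {
    stop("age schemes do not match: [", format(sa), "] vs [", format(sb),
         "]", call. = FALSE)
  }
  invisible(TRUE)
}
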