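#' Split a mortality surface into training and hold-out windows
#'
#' Years up to and including `split_year` form the training surface; later
#' years form the test surface. The partition is disjoint and exhaustive.
#'
#' @param s A [mortality_surface()].
#' @param split_year Last training year; must lie strictly inside the
#'   observed range so that both windows are non-empty.
#' @return A list with elements `train` and `test`, both mortality surfaces.
#' @examples
#' sim <- simulate_surface(sim_config(I = 3, J = 8, seed = 1))
#' str(holdout_split(sim$surface, split_year = 1982), max.level = 1)
#' @export
holdout_split <- function(s, split_year) {
  stopifnot(inherits(s, "mortality_surface"))
  yrs <- sort(unique(s$year))
  if (split_year < min(yrs) || split_year >= max(yrs)) {
    stop("split year must lie strictly inside the observed range ",
         min(yrs), "-", max(yrs), call. = FALSE)
  }
  ages <- attr(s, "ages")
  list(
    train = mortality_surface(dplyr::filter(tibble::as_tibble(s),
                                            .data$year <= split_year), ages),
    test = mortality_surface(dplyr::filter(tibble::as_tibble(s),
                                           .data$year > split_year), ages)
  )
}

#' Mean absolute percent error of a forecast against observed rates
#'
#' Per age stratum, `MAPE = (100 / T) * sum_t |obs_t - pred_t| / obs_t`,
#' computed on central death rates by default (death counts by flag when a
#' population is supplied). Cells with a zero observed value are excluded
#' and counted in the report. The overall summary is the unweighted mean of
#' the stratum values.
#'
#' @param observed A `rate_surface` or [mortality_surface()] covering the
#'   forecast years.
#' @param predicted A `rate_forecast`.
#' @param measure `"rate"` (default) compares central rates `m`; `"count"`
#'   compares implied death counts `q * population`.
#' @param model Label recorded in the report.
#' @return A tibble of class `validation_report`: `model`, `sex`,
#'   `age_group`, `mape` (percent), `n_years`, `n_excluded`, with the
#'   unweighted overall mean in attribute `overall`.
#' @export
mape <- function(observed, predicted, measure = c("rate", "count"),
                 model = attr(predicted, "model") %||% "model") {
  if (inherits(observed, "mortality_surface")) {
    observed <- central_rates(observed)
  }
  stopifnot(inherits(observed, "rate_surface"),
            inherits(predicted, "rate_forecast"))
  measure <- match.arg(measure)
  obs <- tibble::as_tibble(observed)
  prd <- tibble::as_tibble(predicted)
  if (measure == "rate") {
    obs$value <- obs$m
    prd$value <- prd$m
  } else {
    obs$value <- obs$deaths
    pop <- obs[c("age_group", "year", "population")]
    prd <- dplyr::inner_join(prd, pop, by = c("age_group", "year"))
    prd$value <- prd$q * prd$population
  }
  joined <- dplyr::inner_join(
    obs[c("sex", "age_group", "year", "value")],
    prd[c("age_group", "year", "value")],
    by = c("age_group", "year"), suffix = c("_obs", "_pred")
  )
  if (nrow(joined) == 0L) {
    stop("observed and predicted grids do not overlap", call. = FALSE)
  }
  n_zero <- sum(joined$value_obs == 0)
  if (n_zero > 0) {
    warning(n_zero, " zero observed cell(s) excluded from MAPE",
            call. = FALSE)
  }
  joined <- dplyr::filter(joined, .data$value_obs > 0)
  rep <- dplyr::summarise(
    dplyr::group_by(joined, .data$sex, .data$age_group),
    mape = 100 * mean(abs(.data$value_obs - .data$value_pred) /
                        .data$value_obs),
    n_years = dplyr::n(),
    .groups = "drop"
  )
  rep <- dplyr::mutate(rep, model = model,
                       n_excluded = n_zero, .before = 1)
  # keep ages in surface order
  ages <- attr(observed, "ages")
  rep <- dplyr::arrange(rep, match(.data$age_group, ages$labels))
  structure(rep, overall = mean(rep$mape),
            class = c("validation_report", class(tibble::tibble())))
}

#' Overall (unweighted mean) MAPE of a validation report
#' @param report A [mape()] or [compare_models()] report.
#' @return Named numeric: overall MAPE per model.
#' @export
overall_mape <- function(report) {
  stopifnot(inherits(report, "validation_report"))
  tapply(report$mape, report$model, mean)
}

#' Hold-out comparison of forecasting models
#'
#' Fits each candidate on the training window, forecasts the hold-out
#' window, and tabulates per-stratum MAPE. The winner per stratum (and
#' overall, by unweighted mean) is the model with the smallest MAPE; ties
#' break by the order models were supplied.
#'
#' @param s A [mortality_surface()].
#' @param models Named list of at least two model specifications: each a
#'   [bapc_spec()], an [lc_control()], or the string `"constant"` (rates
#'   frozen at the last training year).
#' @param split_year Passed to [holdout_split()].
#' @param seed Base seed for stochastic fits/forecasts.
#' @param measure Passed to [mape()].
#' @return A `validation_report` tibble over all models with a logical
#'   `winner` column per stratum; attribute `overall` holds per-model
#'   overall MAPE and attribute `best` the overall winner's name.
#' @export
compare_models <- function(s, models, split_year, seed = 1,
                           measure = "rate") {
  stopifnot(length(models) >= 2L, !is.null(names(models)),
            all(nzchar(names(models))))
  sp <- holdout_split(s, split_year)
  horizon <- length(unique(sp$test$year))
  obs <- central_rates(sp$test)
  reports <- vector("list", length(models))
  for (idx in seq_along(models)) {
    nm <- names(models)[idx]
    fc <- tryCatch(
      forecast_with(models[[idx]], sp$train, horizon, seed),
      error = function(e) e
    )
    reports[[idx]] <- if (inherits(fc, "error")) {
      tibble::tibble(model = nm, n_excluded = NA_integer_,
                     sex = unique(s$sex),
                     age_group = attr(s, "ages")$labels,
                     mape = NA_real_, n_years = 0L,
                     error = conditionMessage(fc))
    } else {
      r <- mape(obs, fc, measure = measure, model = nm)
      r$error <- NA_character_
      r
    }
  }
  out <- dplyr::bind_rows(reports)
  out <- dplyr::mutate(
    dplyr::group_by(out, .data$age_group),
    winner = !is.na(.data$mape) &
      seq_along(.data$mape) ==
        which.min(replace(.data$mape, is.na(.data$mape), Inf)),
    .keep = "all"
  )
  out <- dplyr::ungroup(out)
  out <- dplyr::arrange(out, match(.data$model, names(models)),
                        match(.data$age_group, attr(s, "ages")$labels))
  overall <- tapply(out$mape, out$model, function(x) mean(x))
  overall <- overall[names(models)]
  structure(out, overall = overall,
            best = names(models)[which.min(overall)],
            split_year = split_year,
            class = c("validation_report", class(tibble::tibble())))
}

#' Options for a Lee-Carter model inside [compare_models()]
#' @inheritParams fit_lee_carter
#' @inheritParams forecast_lee_carter
#' @return A list of class `lc_control`.
#' @export
lc_control <- function(adjust_k = TRUE, zero_offset = 0.5,
                       jump_off = "observed", n_sims = 2000) {
  structure(list(adjust_k = adjust_k, zero_offset = zero_offset,
                 jump_off = jump_off, n_sims = n_sims),
            class = "lc_control")
}

# Fit + forecast dispatcher used by compare_models() and run_pipeline().
forecast_with <- function(model, train, horizon, seed) {
  if (identical(model, "constant")) {
    frozen_forecast(train, horizon)
  } else if (inherits(model, "lc_control")) {
    fit <- fit_lee_carter(central_rates(train), adjust_k = model$adjust_k,
                          zero_offset = model$zero_offset)
    forecast_lee_carter(fit, horizon, n_sims = model$n_sims, seed = seed,
                        jump_off = model$jump_off)
  } else if (inherits(model, "bapc_spec")) {
    model$seed <- as.integer(seed)
    fit <- fit_bapc(train, model)
    predict(fit, horizon = horizon, seed = seed)
  } else {
    stop("unknown model specification of class ", class(model)[1],
         call. = FALSE)
  }
}

#' Frozen-rate forecast (the constant-rate counterfactual as a model)
#'
#' A `rate_forecast` whose rates equal the surface's last observed year in
#' every future year; no uncertainty. Feeding it to [scenario_forecast()]
#' reproduces [scenario_constant()] exactly.
#'
#' @param s A [mortality_surface()].
#' @param horizon Future years.
#' @return A `rate_forecast`.
#' @export
frozen_forecast <- function(s, horizon) {
  stopifnot(inherits(s, "mortality_surface"), horizon >= 1)
  r <- central_rates(s)
  last_year <- max(r$year)
  last <- dplyr::filter(r, .data$year == last_year)
  ages <- attr(s, "ages")
  m <- matrix(last$m[match(ages$labels, last$age_group)], n_ages(ages),
              horizon)
  new_rate_forecast(sex = unique(s$sex), ages = ages,
                    years = last_year + seq_len(horizon),
                    m = m, m_lower = m, m_upper = m, draws_q = NULL,
                    model = "constant")
}

#' @export
print.validation_report <- function(x, ...) {
  NextMethod()
  ov <- attr(x, "overall")
  cat("overall MAPE (unweighted mean over strata):",
      paste(sprintf("%s %.2f%%", names(ov) %||% "model", ov),
            collapse = ", "), "\n")
  if (!is.null(attr(x, "best"))) cat("best overall:", attr(x, "best"), "\n")
  invisible(x)
}
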