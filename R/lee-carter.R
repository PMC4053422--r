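#' Fit the Lee-Carter mortality model
#'
#' Decomposes the log central death rate as
#' `log m[x, t] = a[x] + b[x] * k[t] + e[x, t]`: `a` is the average age
#' pattern, `k` the mortality index whose random-walk-with-drift dynamics
#' drive the forecast, and `b` the age-specific sensitivity to the index.
#' `a` is the row mean of `log m`; `(b, k)` is the leading singular pair of
#' the centred log-rate matrix, rescaled to the usual normalisation
#' `sum(b) = 1`, `sum(k) = 0`. Optionally (default) `k` is re-estimated year
#' by year so that predicted total deaths, given the exposures, match the
#' observed totals — the standard second-stage adjustment.
#'
#' @param r A `rate_surface` (from [central_rates()]) or a
#'   [mortality_surface()].
#' @param adjust_k Re-estimate `k[t]` to match observed total deaths
#'   (default `TRUE`). The SVD index is kept alongside as `k_svd`.
#' @param zero_offset Added to the death count of zero-death cells before
#'   logging (default 0.5). Other cells are untouched.
#' @param smooth Optional function applied to the `I x J` log-rate matrix
#'   before fitting (an age-smoothing hook); default none, i.e. the model is
#'   fitted directly on the grouped grid.
#' @return An object of class `lee_carter_fit` with tibbles `ages`
#'   (`age_group`, `a`, `b`), `index` (`year`, `k`, `k_svd`), scalars `drift`
#'   and `innovation_sd`, the residual matrix, the jump-off log rates, and a
#'   record of the normalisation and adjustment used.
#' @examples
#' sim <- simulate_surface(sim_config(I = 4, J = 12, seed = 7))
#' fit <- fit_lee_carter(central_rates(sim$surface))
#' glance(fit)
#' @export
fit_lee_carter <- function(r, adjust_k = TRUE, zero_offset = 0.5,
                           smooth = NULL) {
  if (inherits(r, "mortality_surface")) r <- central_rates(r)
  stopifnot(inherits(r, "rate_surface"))
  ages <- attr(r, "ages")
  D <- surface_matrix(r, "deaths")
  N <- surface_matrix(r, "population")
  M <- surface_matrix(r, "m")
  if (any(M <= 0)) {
    if (is.null(zero_offset) || zero_offset <= 0) {
      stop("nonpositive rate with no zero-handling policy", call. = FALSE)
    }
    # zero-rate cells get an offset death count before logging
    M[M <= 0] <- (D[M <= 0] + zero_offset) / N[M <= 0]
  }
  logm <- log(M)
  if (!is.null(smooth)) logm <- smooth(logm)
  I <- nrow(logm); J <- ncol(logm)
  a <- rowMeans(logm)
  centred <- logm - a
  if (any(!is.finite(centred))) {
    stop("degenerate log-rate matrix: non-finite values", call. = FALSE)
  }
  sv <- svd(centred)
  if (sv$d[1] < 1e-12) {
    # no time variation at all: flat index, uniform loadings
    b_raw <- rep(1 / I, I)
    k_raw <- rep(0, J)
  } else {
    b_raw <- sv$u[, 1]
    k_raw <- sv$d[1] * sv$v[, 1]
  }
  sb <- sum(b_raw)
  if (abs(sb) < 1e-10) {
    stop("age loadings sum to zero; normalisation sum(b) = 1 is undefined",
         call. = FALSE)
  }
  b <- b_raw / sb
  k_svd <- k_raw * sb      # sum(k_svd) = 0 since the right singular
  k <- k_svd               # vectors of a row-centred matrix are mean-zero
  adjusted <- FALSE
  if (adjust_k) {
    tot_obs <- colSums(D)
    for (t in seq_len(J)) {
      f <- function(kt) sum(N[, t] * exp(a + b * kt)) - tot_obs[t]
      span <- max(50, 10 * (abs(k[t]) + 1))
      k[t] <- tryCatch(uniroot(f, c(k[t] - span, k[t] + span),
                               tol = 1e-10)$root,
                       error = function(e) k[t])
    }
    # restore sum(k) = 0, absorbing the shift into a (fitted values unchanged)
    shift <- mean(k)
    k <- k - shift
    a <- a + b * shift
    adjusted <- TRUE
  }
  drift <- (k[J] - k[1]) / (J - 1)
  innovation_sd <- if (J > 2) sqrt(sum((diff(k) - drift)^2) / (J - 2)) else 0
  fitted_log <- a + outer(b, k)
  years <- sort(unique(r$year))
  structure(
    list(
      ages = tibble::tibble(age_group = ages$labels, a = a, b = b),
      index = tibble::tibble(year = years, k = k, k_svd = k_svd),
      drift = drift,
      innovation_sd = innovation_sd,
      residuals = logm - fitted_log,
      jump_off_log_m = logm[, J],
      fitted_log_m = fitted_log,
      sex = unique(r$sex),
      age_scheme = ages,
      constraints = list(sum_b = 1, sum_k = 0,
                         adjustment = if (adjusted) "match_total_deaths"
                                      else "none"),
      zero_offset = zero_offset
    ),
    class = "lee_carter_fit"
  )
}

#' Forecast death rates from a Lee-Carter fit
#'
#' Extrapolates the mortality index as a random walk with drift
#' (ARIMA(0,1,0) with constant): the point forecast follows the drift path
#' `k[J + h] = k[J] + h * drift`; uncertainty comes from simulated paths with
#' Gaussian innovations at the fitted innovation standard deviation,
#' summarised at the 2.5/97.5 percentiles.
#'
#' @param fit A [fit_lee_carter()] object.
#' @param horizon Number of future years (>= 1).
#' @param n_sims Simulated index paths for the intervals.
#' @param seed RNG seed for the simulated paths.
#' @param jump_off Anchor of the forecast: `"observed"` (default) starts from
#'   the last observed log rates, `"fitted"` from the fitted values
#'   `a + b * k[J]`.
#' @return A `rate_forecast` tibble: `sex`, `age_group`, `year`, point
#'   estimates `m` and `q`, and 2.5/97.5 bounds on both scales; simulated
#'   per-draw death probabilities are attached as attribute `draws`
#'   (`n_sims x I x horizon`).
#' @export
forecast_lee_carter <- function(fit, horizon, n_sims = 2000, seed = 1,
                                jump_off = c("observed", "fitted")) {
  stopifnot(inherits(fit, "lee_carter_fit"), horizon >= 1)
  jump_off <- match.arg(jump_off)
  b <- fit$ages$b
  kJ <- fit$index$k[nrow(fit$index)]
  base_log <- if (jump_off == "observed") fit$jump_off_log_m
              else fit$ages$a + b * kJ
  h <- seq_len(horizon)
  k_point <- kJ + h * fit$drift
  with_seed(seed, {
    innov <- matrix(rnorm(n_sims * horizon, mean = fit$drift,
                          sd = fit$innovation_sd), n_sims, horizon)
    k_paths <- kJ + t(apply(innov, 1, cumsum))
    if (horizon == 1) k_paths <- matrix(k_paths, n_sims, 1)
  })
  I <- length(b)
  years <- fit$index$year[nrow(fit$index)] + h
  m_point <- exp(base_log + outer(b, k_point - kJ))
  # draws: n_sims x I x horizon
  draws_m <- array(NA_real_, c(n_sims, I, horizon))
  for (x in seq_len(I)) {
    draws_m[, x, ] <- exp(base_log[x] + b[x] * (k_paths - kJ))
  }
  lo_m <- apply(draws_m, c(2, 3), quantile, probs = 0.025, names = FALSE)
  hi_m <- apply(draws_m, c(2, 3), quantile, probs = 0.975, names = FALSE)
  new_rate_forecast(
    sex = fit$sex, ages = fit$age_scheme, years = years,
    m = m_point, m_lower = lo_m, m_upper = hi_m,
    draws_q = -expm1(-draws_m),
    model = "lee_carter"
  )
}

#' @export
print.lee_carter_fit <- function(x, ...) {
  cat("<lee_carter_fit> ", x$sex, ", ", nrow(x$ages), " ages x ",
      nrow(x$index), " years\n", sep = "")
  cat("  drift ", signif(x$drift, 4), ", innovation sd ",
      signif(x$innovation_sd, 4), ", adjustment: ",
      x$constraints$adjustment, "\n", sep = "")
  invisible(x)
}

# Shared constructor for rate forecasts (matrices are I x H).
new_rate_forecast <- function(sex, ages, years, m, m_lower, m_upper,
                              draws_q = NULL, model = "unknown") {
  I <- n_ages(ages); H <- length(years)
  q <- -expm1(-m)
  out <- tibble::tibble(
    sex = sex,
    age_group = rep(ages$labels, times = H),
    year = rep(years, each = I),
    m = as.vector(m),
    m_lower = as.vector(m_lower),
    m_upper = as.vector(m_upper),
    q = as.vector(q),
    lower = as.vector(-expm1(-m_lower)),
    upper = as.vector(-expm1(-m_upper))
  )
  structure(out, ages = ages, draws = draws_q, model = model,
            class = c("rate_forecast", class(tibble::tibble())))
}
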