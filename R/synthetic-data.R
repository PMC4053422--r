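#' Configuration for the synthetic mortality generator
#'
#' The generator emulates the statistical structure of national
#' coronary-heart-disease mortality series: a death probability rising
#' roughly exponentially with age, a sustained multiplicative period decline
#' with optional deceleration, small smooth cohort effects, cell-level
#' overdispersion, and a projected population whose density shifts towards
#' the oldest bands. Defaults mirror a six-band (35-44 ... 85+), 33-year
#' observation window with a 19-year projection horizon — the geometry of
#' England & Wales CHD data 1979-2011 projected to 2030.
#'
#' @param I Number of age groups (>= 3).
#' @param J Number of observed annual periods (>= 3).
#' @param C Width of the age bands in years (periods are annual).
#' @param horizon Projection horizon in years.
#' @param first_year Calendar label of the first observed period.
#' @param baseline_logit Length-`I` increasing vector: logit death
#'   probability by age in the first period. Default is a CHD-like schedule
#'   from ~3 per 10,000 at 35-44 to ~4.5 per 100 at 85+.
#' @param period_drift Additive change of the logit per year (negative =
#'   decline). Default -0.04/yr, a sustained decline that roughly halves
#'   rates every 17 years.
#' @param period_curvature Quadratic term in the period trend
#'   (positive = decelerating decline). Default 0.
#' @param cohort_amplitude Standard deviation of the smooth (second-order
#'   random walk, detrended) cohort effects on the logit scale. Default 0.05.
#' @param overdispersion_sd Standard deviation of i.i.d. Gaussian cell-level
#'   heterogeneity on the logit scale. Default 0.
#' @param pop_base Length-`I` vector of mid-year populations per age band,
#'   held constant over the observed window. Default resembles England &
#'   Wales band sizes (millions at working ages, ~0.5m at 85+).
#' @param ageing_rate Length-`I` vector of annual multiplicative population
#'   growth over the projection horizon. The default is backed out of
#'   cumulative 19-year shifts of about +4% below 65, +35% at 65-74, +50% at
#'   75-84 and +89% at 85+.
#' @param sex Sex label attached to generated tables.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A list of class `sim_config`.
#' @seealso [simulate_surface()], [simulate_projection()]
#' @export
sim_config <- function(I = 6L, J = 33L, C = 10L, horizon = 19L,
                       first_year = 1979L,
                       baseline_logit = NULL,
                       period_drift = -0.04,
                       period_curvature = 0,
                       cohort_amplitude = 0.05,
                       overdispersion_sd = 0,
                       pop_base = NULL,
                       ageing_rate = NULL,
                       sex = "male",
                       seed = 1L) {
  I <- as.integer(I); J <- as.integer(J); C <- as.integer(C)
  if (I < 3L || J < 3L) stop("I and J must both be at least 3", call. = FALSE)
  if (is.null(baseline_logit)) {
    full <- qlogis(c(3e-4, 1.2e-3, 4e-3, 1.1e-2, 2.4e-2, 4.5e-2))
    baseline_logit <- if (I <= 6L) full[seq_len(I)]
                      else qlogis(plogis(full[1]) * exp(seq(0, log(150), length.out = I)))
  }
  if (length(baseline_logit) != I || any(diff(baseline_logit) <= 0)) {
    stop("baseline_logit must be length I and strictly increasing", call. = FALSE)
  }
  if (is.null(pop_base)) {
    full <- c(3.6e6, 3.2e6, 2.7e6, 2.0e6, 1.2e6, 4.5e5)
    pop_base <- if (I <= 6L) full[seq_len(I)] else rep(2e6, I)
  }
  if (length(pop_base) != I || any(pop_base <= 0)) {
    stop("pop_base must be length I and positive", call. = FALSE)
  }
  if (is.null(ageing_rate)) {
    full <- c((1.04)^(1 / 19) - 1, (1.04)^(1 / 19) - 1, (1.10)^(1 / 19) - 1,
              (1.35)^(1 / 19) - 1, (1.50)^(1 / 19) - 1, (1.89)^(1 / 19) - 1)
    ageing_rate <- if (I <= 6L) full[seq_len(I)] else rep(0.01, I)
  }
  if (length(ageing_rate) != I) stop("ageing_rate must be length I", call. = FALSE)
  structure(
    list(I = I, J = J, C = C, horizon = as.integer(horizon),
         first_year = as.integer(first_year),
         baseline_logit = baseline_logit,
         period_drift = period_drift, period_curvature = period_curvature,
         cohort_amplitude = cohort_amplitude,
         overdispersion_sd = overdispersion_sd,
         pop_base = pop_base, ageing_rate = ageing_rate,
         sex = sex, seed = as.integer(seed)),
    class = "sim_config"
  )
}

sim_age_labels <- function(cfg) {
  lower <- 35L + cfg$C * (seq_len(cfg$I) - 1L)
  c(paste0(lower[-cfg$I], "-", lower[-cfg$I] + cfg$C - 1L),
    paste0(lower[cfg$I], "+"))
}

#' Simulate a mortality surface with known generating effects
#'
#' Builds `logit(q[i, j]) = mu + theta_i + phi_j + psi_k (+ z_ij)` with the
#' age schedule from the config baseline, a linear-plus-quadratic period
#' trend, a small detrended second-order random-walk cohort effect on the
#' index `k = C(I - i) + j`, and optional i.i.d. heterogeneity; then draws
#' `deaths[i, j] ~ Binomial(N[i, j], q[i, j])`. The generating effects are
#' returned so that model-recovery tests can compare against the truth.
#'
#' @param cfg A [sim_config()].
#' @param likelihood `"binomial"` (default, matching the Bayesian model) or
#'   `"poisson"` (convenient for Lee-Carter checks).
#' @return A list with elements `surface` (a [mortality_surface()]) and
#'   `effects` (list: `mu`, `theta`, `phi`, `psi`, `z`, `eta`, `q` — the last
#'   three as `I x J` matrices).
#' @examples
#' sim <- simulate_surface(sim_config(I = 3, J = 6, seed = 42))
#' sim$surface
#' @export
simulate_surface <- function(cfg, likelihood = c("binomial", "poisson")) {
  stopifnot(inherits(cfg, "sim_config"))
  likelihood <- match.arg(likelihood)
  I <- cfg$I; J <- cfg$J; C <- cfg$C
  K <- C * (I - 1L) + J
  with_seed(cfg$seed, {
    mu <- mean(cfg$baseline_logit)
    theta <- cfg$baseline_logit - mu
    jj <- seq_len(J) - 1
    phi <- cfg$period_drift * jj + cfg$period_curvature * jj^2
    psi <- numeric(K)
    if (cfg$cohort_amplitude > 0) {
      raw <- cumsum(cumsum(rnorm(K)))
      detr <- stats::residuals(lm(raw ~ seq_len(K)))
      psi <- cfg$cohort_amplitude * detr / stats::sd(detr)
    }
    kmat <- cohort_grid(I, J, C)
    eta <- mu + outer(theta, phi, "+") + matrix(psi[kmat], I, J)
    z <- matrix(0, I, J)
    if (cfg$overdispersion_sd > 0) {
      z <- matrix(rnorm(I * J, 0, cfg$overdispersion_sd), I, J)
      eta <- eta + z
    }
    q <- plogis(eta)
    if (any(q <= 0) || any(q >= 1) || any(!is.finite(q))) {
      stop("config produces death probabilities outside (0, 1)", call. = FALSE)
    }
    N <- matrix(round(cfg$pop_base), I, J)
    D <- if (likelihood == "binomial") {
      matrix(rbinom(I * J, size = N, prob = q), I, J)
    } else {
      matrix(pmin(rpois(I * J, lambda = N * q), N), I, J)
    }
    years <- cfg$first_year + seq_len(J) - 1L
    labels <- sim_age_labels(cfg)
    tab <- tibble::tibble(
      sex = cfg$sex,
      age_group = rep(labels, times = J),
      year = rep(years, each = I),
      deaths = as.vector(D),
      population = as.vector(N)
    )
    list(
      surface = mortality_surface(tab, ages = age_scheme(labels)),
      effects = list(mu = mu, theta = theta, phi = phi, psi = psi, z = z,
                     eta = eta, q = q, cohort = kmat)
    )
  })
}

#' Simulate an ageing population projection
#'
#' Extends the last observed population geometrically per age band:
#' `N[i, t] = N[i, J] * (1 + g_i)^t` for `t = 1..horizon`, with the
#' age-specific growth rates `g` from the config. Positive growth
#' concentrated in the oldest bands shifts population density upward in age,
#' the mechanism by which constant death rates still yield rising death
#' counts.
#'
#' @param cfg A [sim_config()].
#' @return A [population_projection()] covering the `horizon` years after the
#'   observed window.
#' @export
simulate_projection <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  I <- cfg$I; H <- cfg$horizon
  labels <- sim_age_labels(cfg)
  years <- cfg$first_year + cfg$J - 1L + seq_len(H)
  growth <- outer(1 + cfg$ageing_rate, seq_len(H), "^")
  tab <- tibble::tibble(
    sex = cfg$sex,
    age_group = rep(labels, times = H),
    year = rep(years, each = I),
    population = as.vector(round(cfg$pop_base) * growth)
  )
  population_projection(tab, ages = age_scheme(labels))
}
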