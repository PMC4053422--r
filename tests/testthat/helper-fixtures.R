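# Small deterministic fixtures built in code.

with_seed_test <- function(seed, code) {
  withr::with_seed(seed, code)
}

# A tiny hand-specified surface: I ages x J years, deaths chosen so rates
# decline over time.
tiny_surface <- function(I = 3, J = 4, first_year = 2000, sex = "female") {
  labels <- c(paste0(35 + 10 * (seq_len(I - 1) - 1), "-",
                     44 + 10 * (seq_len(I - 1) - 1)),
              paste0(35 + 10 * (I - 1), "+"))
  grid <- expand.grid(age_group = labels,
                      year = first_year + seq_len(J) - 1,
                      stringsAsFactors = FALSE)
  i <- match(grid$age_group, labels)
  j <- grid$year - first_year + 1
  grid$sex <- sex
  grid$population <- 1e5 * i
  grid$deaths <- round(grid$population * 0.002 * i * exp(-0.05 * j))
  mortality_surface(grid)
}

# Minimal bapc_fit object with hand-specified draws, for predictive-law
# tests that need full control over the chains.
fake_bapc_fit <- function(mu, theta, phi, psi, tau, order = "rw2",
                          z = NULL, C = 10, first_year = 1979,
                          sex = "male") {
  n <- length(mu)
  I <- ncol(theta); J <- ncol(phi); K <- ncol(psi)
  stopifnot(K == C * (I - 1) + J)
  labels <- c(paste0(35 + C * (seq_len(I - 1) - 1), "-",
                     34 + C * seq_len(I - 1)),
              paste0(35 + C * (I - 1), "+"))
  spec <- bapc_spec(age = order, period = order, cohort = order,
                    heterogeneity = !is.null(z), chains = 1,
                    iter = 2 * n, burn = n, thin = 1)
  tau_m <- matrix(tau, n, 4, byrow = length(tau) == 4)
  colnames(tau_m) <- c("age", "period", "cohort", "heterogeneity")
  structure(
    list(draws = list(mu = mu, theta = theta, phi = phi, psi = psi,
                      z = z, tau = tau_m),
         deviance = rep(NA_real_, n),
         accept = matrix(NA_real_, 1, 5),
         I = I, J = J, C = C, K = K,
         years = first_year + seq_len(J) - 1,
         sex = sex,
         age_scheme = age_scheme(labels),
         surface = NULL, spec = spec),
    class = "bapc_fit"
  )
}

# Pivot a long cell table to an age x year matrix (independent of the
# package's internal helper).
surface_matrix_test <- function(s, what) {
  ages <- attr(s, "ages")$labels
  years <- sort(unique(s$year))
  m <- matrix(NA_real_, length(ages), length(years))
  m[cbind(match(s$age_group, ages), match(s$year, years))] <- s[[what]]
  m
}

# Build a rate_surface from an I x J matrix of central rates.
rates_from_matrix <- function(mmat, labels, first_year = 2000,
                              sex = "male", population = 1e6) {
  I <- nrow(mmat); J <- ncol(mmat)
  rate_surface(tibble::tibble(
    sex = sex,
    age_group = rep(labels, times = J),
    year = rep(first_year + seq_len(J) - 1, each = I),
    m = as.vector(mmat),
    population = population
  ))
}

# Fast, deliberately small MCMC settings for unit tests.
quick_spec <- function(...) {
  bapc_spec(chains = 1, iter = 4000, burn = 1500, thin = 5, ...)
}

# cells tibble back to an I x H matrix
surface_matrix_test_cells <- function(res) {
  labels <- res$ages$labels
  years <- sort(unique(res$cells$year))
  m <- matrix(NA_real_, length(labels), length(years))
  m[cbind(match(res$cells$age_group, labels),
          match(res$cells$year, years))] <- res$cells$deaths
  m
}

rexp_pop <- function(I, H, seed) {
  withr::with_seed(seed, round(runif(I * H, 5e4, 5e5)))
}

# build a deterministic rate_forecast from a rate matrix
new_rate_forecast_test <- function(mmat, labels, years) {
  structure(
    tibble::tibble(
      sex = "male",
      age_group = rep(labels, times = length(years)),
      year = rep(years, each = length(labels)),
      m = as.vector(mmat),
      m_lower = as.vector(mmat), m_upper = as.vector(mmat),
      q = -expm1(-as.vector(mmat)),
      lower = -expm1(-as.vector(mmat)), upper = -expm1(-as.vector(mmat))
    ),
    ages = age_scheme(labels), model = "hand",
    class = c("rate_forecast", class(tibble::tibble()))
  )
}

# Age labels matching the generator's convention (35-based bands).
sim_age_labels_test <- function(cfg) {
  lower <- 35 + cfg$C * (seq_len(cfg$I) - 1)
  c(paste0(lower[-cfg$I], "-", lower[-cfg$I] + cfg$C - 1),
    paste0(lower[cfg$I], "+"))
}

# Linear-predictor draws for the observed window, rebuilt from the stored
# blocks and the exported cohort index (cells in age-major order).
bapc_eta_draws_test <- function(fit) {
  I <- fit$I; J <- fit$J
  idx_i <- rep(seq_len(I), times = J)
  idx_j <- rep(seq_len(J), each = I)
  idx_k <- cohort_index(idx_i, idx_j, I = I, C = fit$C)
  eta <- fit$draws$mu + fit$draws$theta[, idx_i, drop = FALSE] +
    fit$draws$phi[, idx_j, drop = FALSE] +
    fit$draws$psi[, idx_k, drop = FALSE]
  if (!is.null(fit$draws$z)) eta <- eta + fit$draws$z
  eta
}
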