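lc_labels <- c("35-44", "45-54", "55+")

# exact rank-1 rate surface from chosen (a, b, k) obeying the constraints
rank1_surface <- function(a, b, k, first_year = 1990) {
  I <- length(a); J <- length(k)
  grid <- expand.grid(age_group = lc_labels[seq_len(I)],
                      year = first_year + seq_len(J) - 1,
                      stringsAsFactors = FALSE)
  i <- match(grid$age_group, lc_labels)
  j <- grid$year - first_year + 1
  grid$sex <- "male"
  grid$m <- exp(a[i] + b[i] * k[j])
  rate_surface(grid)
}

test_that("a time-constant surface gives k = 0 and zero drift", {
  a <- c(-7, -6, -5)
  s <- rank1_surface(a, b = c(0.2, 0.3, 0.5), k = rep(0, 6))
  fit <- fit_lee_carter(s, adjust_k = FALSE)
  expect_equal(fit$ages$a, a, ignore_attr = TRUE)
  expect_equal(fit$index$k, rep(0, 6), tolerance = 1e-12)
  expect_equal(fit$drift, 0)
})

test_that("a noiseless rank-1 surface is recovered to 1e-8", {
  a <- c(-7.2, -5.9, -4.4)
  b <- c(0.15, 0.35, 0.5)                 # sum(b) = 1
  k <- c(5, 3, 1.5, 0, -1, -2.5, -6)      # sum(k) = 0
  s <- rank1_surface(a, b, k)
  fit <- fit_lee_carter(s, adjust_k = FALSE)
  expect_equal(fit$ages$a, a, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$ages$b, b, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$index$k, k, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(fit$ages$b), 1, tolerance = 1e-12)
  expect_equal(sum(fit$index$k), 0, tolerance = 1e-8)
})

test_that("the second-stage adjustment matches total deaths each year", {
  sim <- simulate_surface(sim_config(I = 4, J = 10, seed = 3,
                                     overdispersion_sd = 0.1))
  r <- central_rates(sim$surface)
  fit <- fit_lee_carter(r, adjust_k = TRUE)
  D <- xtabs(deaths ~ age_group + year, sim$surface)
  N <- xtabs(population ~ age_group + year, sim$surface)
  ord <- match(fit$ages$age_group, rownames(D))
  pred_tot <- colSums(N[ord, ] * exp(fit$ages$a + outer(fit$ages$b,
                                                        fit$index$k)))
  expect_equal(unname(pred_tot), unname(colSums(D)), tolerance = 1e-6)
  expect_equal(sum(fit$index$k), 0, tolerance = 1e-8)
})

test_that("the fit is invariant to scaling deaths and exposures together", {
  s <- tiny_surface(I = 3, J = 6)
  r1 <- central_rates(s)
  scaled <- dplyr::mutate(tibble::as_tibble(r1),
                          deaths = deaths * 1000,
                          population = population * 1000)
  r2 <- rate_surface(scaled)
  f1 <- fit_lee_carter(r1)
  f2 <- fit_lee_carter(r2)
  expect_equal(f1$ages, f2$ages)
  expect_equal(f1$index, f2$index)
})

test_that("zero-death cells are handled by the documented offset", {
  df <- tibble::as_tibble(tiny_surface(I = 3, J = 4))
  df$deaths[1] <- 0
  s <- mortality_surface(df)
  expect_error(fit_lee_carter(central_rates(s), zero_offset = NULL),
               "zero-handling")
  fit <- fit_lee_carter(central_rates(s), zero_offset = 0.5)
  expect_true(all(is.finite(fit$ages$a)))
})

test_that("deterministic forecasts follow the drift path exactly", {
  a <- c(-7.2, -5.9, -4.4)
  b <- c(0.15, 0.35, 0.5)
  k <- seq(6, -6, length.out = 7)        # exactly linear, sum 0
  s <- rank1_surface(a, b, k)
  fit <- fit_lee_carter(s, adjust_k = FALSE)
  expect_equal(fit$innovation_sd, 0, tolerance = 1e-9)
  h <- 1:5
  fc <- forecast_lee_carter(fit, 5, n_sims = 50, seed = 1,
                            jump_off = "fitted")
  expect_equal(surface_matrix_test(fc, "m"),
               exp(a + outer(b, k[7] + h * fit$drift)),
               tolerance = 1e-9)
  # zero drift, zero sd: forecast frozen at the last fitted rates
  s0 <- rank1_surface(a, b, rep(0, 6))
  f0 <- fit_lee_carter(s0, adjust_k = FALSE)
  fc0 <- forecast_lee_carter(f0, 3, n_sims = 10, seed = 1,
                             jump_off = "fitted")
  expect_equal(surface_matrix_test(fc0, "m"),
               matrix(exp(a), 3, 3), tolerance = 1e-9)
})

test_that("interval width matches the random-walk closed form", {
  sim <- simulate_surface(sim_config(I = 3, J = 20, seed = 8))
  fit <- fit_lee_carter(central_rates(sim$surface))
  fc <- forecast_lee_carter(fit, 10, n_sims = 20000, seed = 4)
  draws <- attr(fc, "draws")
  for (h in c(1, 4, 10)) {
    logm <- log(-log(1 - draws[, 2, h]))
    half <- diff(quantile(logm, c(0.025, 0.975))) / 2
    expect_equal(unname(half),
                 1.96 * fit$innovation_sd * sqrt(h) * abs(fit$ages$b[2]),
                 tolerance = 0.05)
  }
  # median of simulated paths converges on the drift path
  med <- apply(log(-log(1 - draws[, 2, ])), 2, stats::median)
  point <- log(fc$m[fc$age_group == "45-54"])
  expect_equal(unname(med), point, tolerance = 0.01)
})

test_that("poisson-noise surfaces recover the generating drift", {
  cfg0 <- sim_config(I = 4, J = 20, period_drift = -0.03,
                     cohort_amplitude = 0, overdispersion_sd = 0,
                     pop_base = rep(1e6, 4), seed = 1)
  labels <- attr(simulate_surface(cfg0)$surface, "ages")$labels
  truth <- fit_lee_carter(
    rates_from_matrix(simulate_surface(cfg0)$effects$q, labels),
    adjust_k = FALSE)$drift
  drifts <- vapply(1:20, function(sd) {
    cfg <- sim_config(I = 4, J = 20, period_drift = -0.03,
                      cohort_amplitude = 0, overdispersion_sd = 0,
                      pop_base = rep(1e6, 4), seed = 100 + sd)
    sim <- simulate_surface(cfg, likelihood = "poisson")
    fit_lee_carter(central_rates(sim$surface), adjust_k = FALSE)$drift
  }, numeric(1))
  mc_sd <- sd(drifts)
  expect_lt(abs(mean(drifts) - truth), 3 * mc_sd / sqrt(20))
})
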