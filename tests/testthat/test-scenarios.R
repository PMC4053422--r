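proj_from_matrix <- function(Np, labels, first_year, sex = "male") {
  H <- ncol(Np)
  population_projection(tibble::tibble(
    sex = sex,
    age_group = rep(labels, times = H),
    year = rep(first_year + seq_len(H) - 1, each = length(labels)),
    population = as.vector(Np)
  ))
}

test_that("constant-rate projection is exact arithmetic and linear", {
  s <- tiny_surface(I = 3, J = 4, first_year = 2000)
  labels <- attr(s, "ages")$labels
  r <- central_rates(s)
  last <- dplyr::filter(r, year == 2003)
  Np <- matrix(c(2e5, 3e5, 4e5), 3, 5) * outer(rep(1, 3), seq(1, 1.4, 0.1))
  proj <- proj_from_matrix(Np, labels, 2004, sex = unique(s$sex))
  res <- scenario_constant(s, proj)
  want <- last$q[match(labels, last$age_group)] * Np
  expect_equal(surface_matrix_test_cells(res), want)
  expect_equal(res$totals$deaths, colSums(want))

  # homogeneity degree 1 in the projection
  proj2 <- proj_from_matrix(2 * Np, labels, 2004, sex = unique(s$sex))
  res2 <- scenario_constant(s, proj2)
  expect_equal(res2$cells$deaths, 2 * res$cells$deaths)
  expect_equal(res2$totals$deaths, 2 * res$totals$deaths)

  # projection frozen at the last observed population reproduces the last
  # observed deaths (up to the rate/probability convention)
  Nlast <- matrix(last$population[match(labels, last$age_group)], 3, 2)
  res3 <- scenario_constant(s, proj_from_matrix(Nlast, labels, 2004,
                                                sex = unique(s$sex)),
                            measure = "rate")
  expect_equal(res3$cells$deaths[res3$cells$year == 2004],
               last$deaths[match(labels, last$age_group)])
})

test_that("an ageing population raises deaths even at constant rates", {
  cfg <- sim_config(seed = 14)   # default old-age growth mirrors ageing
  sim <- simulate_surface(cfg)
  proj <- simulate_projection(cfg)
  res <- scenario_constant(sim$surface, proj)
  obs_last <- sum(dplyr::filter(tibble::as_tibble(sim$surface),
                                year == max(year))$deaths)
  expect_gt(res$totals$deaths[nrow(res$totals)], obs_last)
})

test_that("a frozen-rate forecast reproduces the constant scenario exactly", {
  s <- tiny_surface(I = 4, J = 6, first_year = 1990)
  labels <- attr(s, "ages")$labels
  Np <- matrix(rexp_pop(4, 8, seed = 2), 4, 8)
  proj <- proj_from_matrix(Np, labels, 1996, sex = unique(s$sex))
  a <- scenario_constant(s, proj)
  b <- scenario_forecast(frozen_forecast(s, 8), proj, observed = s)
  expect_equal(b$cells$deaths, a$cells$deaths, tolerance = 1e-12)
  expect_equal(b$totals$deaths, a$totals$deaths, tolerance = 1e-12)
})

test_that("percent change follows the textbook arithmetic", {
  s <- tiny_surface(I = 3, J = 4)
  labels <- attr(s, "ages")$labels
  proj <- proj_from_matrix(matrix(1e5, 3, 3), labels, 2004,
                           sex = unique(s$sex))
  res <- scenario_constant(s, proj)
  ref_total <- sum(dplyr::filter(tibble::as_tibble(s), year == 2003)$deaths)
  # overwrite totals with hand values to check the formula itself
  res$totals$deaths <- c(162, 100, 44) * ref_total / 100
  res$totals$lower <- res$totals$deaths
  res$totals$upper <- res$totals$deaths
  res$draws_totals <- NULL
  pc <- percent_change(res, reference_year = 2003)
  expect_equal(pc$pct_change, c(62, 0, -56), tolerance = 1e-10)
  expect_error(percent_change(res, reference_year = 1900), "not in")

  zero <- res
  zero$observed_totals$deaths <- 0
  expect_error(percent_change(zero, reference_year = 2003), "zero reference")
})

test_that("interval bounds bracket the point estimates", {
  cfg <- sim_config(I = 4, J = 10, horizon = 6, seed = 3)
  sim <- simulate_surface(cfg)
  proj <- simulate_projection(cfg)
  res <- scenario_constant(sim$surface, proj, n_sims = 500, seed = 1)
  expect_true(all(res$cells$lower <= res$cells$deaths + 1e-9))
  expect_true(all(res$cells$upper >= res$cells$deaths - 1e-9))
  pc <- percent_change(res)
  expect_true(all(pc$lower <= pc$pct_change & pc$pct_change <= pc$upper))

  fit <- fit_bapc(sim$surface, quick_spec(seed = 2))
  fc <- predict(fit, horizon = 6, seed = 1)
  resb <- scenario_forecast(fc, proj, observed = sim$surface)
  expect_true(all(resb$cells$lower <= resb$cells$deaths + 1e-9))
  pcb <- percent_change(resb)
  expect_true(all(pcb$lower <= pcb$pct_change & pcb$pct_change <= pcb$upper))
})

test_that("declining forecasts against an ageing population can go either way", {
  # strong rate decline dominating modest ageing -> deaths fall
  cfg_fall <- sim_config(I = 3, J = 12, horizon = 10, period_drift = -0.06,
                         ageing_rate = rep(0.002, 3), seed = 8,
                         cohort_amplitude = 0)
  # mild decline overwhelmed by strong old-age growth -> deaths rise
  cfg_rise <- sim_config(I = 3, J = 12, horizon = 10, period_drift = -0.004,
                         ageing_rate = rep(0.05, 3), seed = 8,
                         cohort_amplitude = 0)
  for (case in list(list(cfg = cfg_fall, up = FALSE),
                    list(cfg = cfg_rise, up = TRUE))) {
    sim <- simulate_surface(case$cfg)
    proj <- simulate_projection(case$cfg)
    fit <- fit_bapc(sim$surface, quick_spec(seed = 5))
    fc <- predict(fit, horizon = 10, seed = 2)
    pc <- percent_change(scenario_forecast(fc, proj, observed = sim$surface))
    final <- pc$pct_change[nrow(pc)]
    if (case$up) expect_gt(final, 0) else expect_lt(final, 0)
  }
})

test_that("combining sexes sums totals and preserves draw-based intervals", {
  cfg_m <- sim_config(I = 3, J = 6, horizon = 4, seed = 1, sex = "male")
  cfg_f <- sim_config(I = 3, J = 6, horizon = 4, seed = 2, sex = "female",
                      baseline_logit = qlogis(c(2e-4, 8e-4, 3e-3)))
  out <- lapply(list(cfg_m, cfg_f), function(cfg) {
    sim <- simulate_surface(cfg)
    scenario_constant(sim$surface, simulate_projection(cfg),
                      n_sims = 200, seed = 3)
  })
  both <- combine_scenarios(out[[1]], out[[2]])
  expect_equal(both$totals$deaths,
               out[[1]]$totals$deaths + out[[2]]$totals$deaths)
  expect_equal(both$sex, "all")
  expect_true(all(both$totals$lower <= both$totals$deaths))
})
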