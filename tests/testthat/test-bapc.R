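test_that("cohort indexing enumerates K = C*(I-1)+J distinct cohorts", {
  expect_equal(cohort_index(1, 33, I = 6, C = 10), 83)
  expect_equal(cohort_index(6, 1, I = 6, C = 10), 1)
  grid <- expand.grid(i = 1:6, j = 1:33)
  k <- cohort_index(grid$i, grid$j, I = 6, C = 10)
  expect_equal(sort(unique(k)), 1:83)
  expect_error(cohort_index(7, 1, I = 6, C = 10), "out of range")
  expect_error(cohort_index(1, 0, I = 6, C = 10), ">= 1")
})

test_that("model specifications are validated", {
  expect_error(bapc_spec(age = "rw3"), "rw1.*rw2|must be")
  expect_error(bapc_spec(iter = 100, burn = 100), "iter > burn")
  expect_error(bapc_spec(prior_rate = -1), "positive")
  expect_error(bapc_spec(fixed_precision = c(bogus = 1)), "unknown")
  sp <- bapc_spec(fixed_precision = c(period = 50))
  expect_equal(sp$fixed_precision[["period"]], 50)
  expect_true(is.na(sp$fixed_precision[["age"]]))
})

test_that("chains are reproducible from the seed", {
  sim <- simulate_surface(sim_config(I = 3, J = 6, seed = 4))
  f1 <- fit_bapc(sim$surface, quick_spec(seed = 7))
  f2 <- fit_bapc(sim$surface, quick_spec(seed = 7))
  expect_identical(f1$draws, f2$draws)
  f3 <- fit_bapc(sim$surface, quick_spec(seed = 8))
  expect_false(identical(f1$draws$mu, f3$draws$mu))
})

test_that("an intercept-only truth is recovered with null effect blocks", {
  labels <- c("35-44", "45-54", "55+")
  J <- 8
  with_seed_test(99, {
    df <- tibble::tibble(
      sex = "male",
      age_group = rep(labels, times = J),
      year = rep(2000 + seq_len(J) - 1, each = 3),
      population = 1e6,
      deaths = rbinom(3 * J, 1e6, 0.01)
    )
  })
  s <- mortality_surface(df)
  fit <- fit_bapc(s, quick_spec(seed = 1))
  p_draws <- plogis(fit$draws$mu)
  expect_lt(abs(mean(p_draws) - 0.01), 3 * sd(p_draws) + 1e-5)
  ef <- decompose_effects(fit)$effects
  blocks <- dplyr::filter(ef, effect != "intercept")
  expect_lt(max(abs(blocks$estimate)), 0.02)
})

test_that("stored deviances equal the independent binomial log-pmf oracle", {
  sim <- simulate_surface(sim_config(I = 3, J = 5, seed = 12,
                                     overdispersion_sd = 0.1))
  fit <- fit_bapc(sim$surface, quick_spec(heterogeneity = TRUE, seed = 2))
  D <- surface_matrix_test(sim$surface, "deaths")
  N <- surface_matrix_test(sim$surface, "population")
  I <- fit$I; J <- fit$J
  for (d in c(1, 17, length(fit$deviance))) {
    eta <- matrix(NA_real_, I, J)
    for (i in seq_len(I)) for (j in seq_len(J)) {
      k <- cohort_index(i, j, I = I, C = fit$C)
      eta[i, j] <- fit$draws$mu[d] + fit$draws$theta[d, i] +
        fit$draws$phi[d, j] + fit$draws$psi[d, k] +
        fit$draws$z[d, (j - 1) * I + i]
    }
    oracle <- -2 * sum(dbinom(D, N, plogis(eta), log = TRUE))
    expect_equal(fit$deviance[d], oracle, tolerance = 1e-10)
  }
})

test_that("a degenerate posterior has pD = 0 and DIC = -2 log-lik", {
  sim <- simulate_surface(sim_config(I = 3, J = 5, seed = 12))
  fit <- fit_bapc(sim$surface, quick_spec(seed = 2))
  n <- length(fit$draws$mu)
  one <- fit
  one$draws$mu <- rep(fit$draws$mu[1], n)
  for (b in c("theta", "phi", "psi"))
    one$draws[[b]] <- fit$draws[[b]][rep(1, n), ]
  one$deviance <- rep(fit$deviance[1], n)
  d <- dic(one)
  expect_equal(d$p_d, 0, tolerance = 1e-8)
  expect_equal(d$dic, fit$deviance[1], tolerance = 1e-8)
  expect_error(dic(structure(list(deviance = 1), class = "bapc_fit")),
               "at least 2")
})

test_that("heterogeneity lowers DIC on overdispersed data", {
  cfg <- sim_config(I = 4, J = 12, overdispersion_sd = 0.2, seed = 31)
  s <- simulate_surface(cfg)$surface
  d0 <- dic(fit_bapc(s, quick_spec(seed = 1)))
  d1 <- dic(fit_bapc(s, quick_spec(heterogeneity = TRUE, seed = 1)))
  expect_lt(d1$dic, d0$dic)
})

test_that("random-walk predictive laws hold exactly in the limit", {
  I <- 3; J <- 6; C <- 2; K <- C * (I - 1) + J
  n <- 400
  line <- 0.5 - 0.3 * seq_len(J)          # exactly linear period block
  fit2 <- fake_bapc_fit(
    mu = rep(-4, n),
    theta = matrix(rep(c(-1, 0, 1), each = n), n, I),
    phi = matrix(rep(line, each = n), n, J),
    psi = matrix(0, n, K),
    tau = c(Inf, Inf, Inf, Inf), order = "rw2", C = C
  )
  fc2 <- predict(fit2, horizon = 4, seed = 1)
  got <- log(fc2$q / (1 - fc2$q))[fc2$age_group == fit2$age_scheme$labels[1]]
  want <- -4 - 1 + (0.5 - 0.3 * (J + 1:4))   # theta_1 = -1
  expect_equal(got, want, tolerance = 1e-10)

  fit1 <- fake_bapc_fit(
    mu = rep(-4, n),
    theta = matrix(rep(c(-1, 0, 1), each = n), n, I),
    phi = matrix(rep(line, each = n), n, J),
    psi = matrix(0, n, K),
    tau = c(Inf, Inf, Inf, Inf), order = "rw1", C = C
  )
  fc1 <- predict(fit1, horizon = 4, seed = 1)
  q_last <- plogis(-4 - 1 + line[J])
  expect_equal(fc1$q[fc1$age_group == fit1$age_scheme$labels[1]],
               rep(q_last, 4), tolerance = 1e-12)
})

test_that("RW1 predictive variance grows as h / tau", {
  I <- 2; J <- 5; C <- 1; K <- C * (I - 1) + J
  n <- 40000; tau <- 25
  fit <- fake_bapc_fit(
    mu = rep(-3, n), theta = matrix(0, n, I),
    phi = matrix(rep(seq(0.5, -0.5, length.out = J), each = n), n, J),
    psi = matrix(0, n, K),
    tau = matrix(rep(c(Inf, tau, Inf, Inf), each = n), n, 4),
    order = "rw1", C = C
  )
  fc <- predict(fit, horizon = 6, seed = 3)
  draws <- attr(fc, "draws")
  for (h in c(1, 3, 6)) {
    lg <- qlogis(draws[, 1, h])
    expect_equal(var(lg), h / tau, tolerance = 0.05)
  }
  # interval widths widen monotonically with horizon
  w <- tapply(fc$upper - fc$lower, fc$year, mean)
  expect_true(all(diff(w) > 0))
})

test_that("the reporting gauge is idempotent and never touches forecasts", {
  sim <- simulate_surface(sim_config(I = 4, J = 10, seed = 6))
  fit <- fit_bapc(sim$surface, quick_spec(seed = 3))
  g1 <- decompose_effects(fit, gauge = "cohort_detrend")
  # idempotent: re-applying to the transformed draws changes nothing
  refit <- fit; refit$draws <- g1$draws
  g2 <- decompose_effects(refit, gauge = "cohort_detrend")
  expect_equal(g1$effects, g2$effects, tolerance = 1e-10)
  # draw-wise eta is invariant under both gauges
  eta_of <- function(draws) {
    sapply(seq_len(fit$I), function(i) {
      j <- fit$J
      k <- cohort_index(i, j, I = fit$I, C = fit$C)
      draws$mu + draws$theta[, i] + draws$phi[, j] + draws$psi[, k]
    })
  }
  gp <- decompose_effects(fit, gauge = "period_detrend")
  expect_equal(eta_of(g1$draws), eta_of(fit$draws), tolerance = 1e-10)
  expect_equal(eta_of(gp$draws), eta_of(fit$draws), tolerance = 1e-10)
})

test_that("variance shares reflect the generating structure", {
  cfg0 <- sim_config(I = 5, J = 15, cohort_amplitude = 0, seed = 17)
  fit0 <- fit_bapc(simulate_surface(cfg0)$surface, quick_spec(seed = 4))
  sh0 <- decompose_effects(fit0)$variance_shares
  expect_lt(sh0$share[sh0$effect == "cohort"], 0.05)
  # the steep default age schedule dominates
  expect_equal(sh0$effect[which.max(sh0$share)], "age")
})

test_that("posterior mean of the intercept matches dense grid integration", {
  # 2 ages x 2 periods, C = 1, RW1 priors with fixed precisions: the
  # posterior on the sum-to-zero slice is proper and 5-dimensional, so a
  # dense grid is a genuine independent oracle.
  labels <- c("60-60", "61+")
  with_seed_test(5, {
    df <- tibble::tibble(
      sex = "f", age_group = rep(labels, 2),
      year = rep(2000:2001, each = 2), population = 500,
      deaths = rbinom(4, 500, c(0.08, 0.14, 0.07, 0.12))
    )
  })
  s <- mortality_surface(df)
  tau0 <- 2
  fit <- fit_bapc(s, bapc_spec(
    age = "rw1", period = "rw1", cohort = "rw1",
    fixed_precision = c(age = tau0, period = tau0, cohort = tau0),
    chains = 4, iter = 30000, burn = 5000, thin = 5, seed = 9
  ))
  D <- surface_matrix_test(s, "deaths"); N <- surface_matrix_test(s, "population")
  emp <- qlogis((D + 0.5) / (N + 1))
  ctr <- mean(emp)
  gr <- function(center, half = 0.9, len = 17) {
    seq(center - half, center + half, length.out = len)
  }
  g <- expand.grid(mu = gr(ctr), t1 = gr((emp[1, 1] + emp[1, 2]) / 2 - ctr),
                   p1 = gr(0, 0.6), s1 = gr(0, 0.9), s2 = gr(0, 0.9))
  # cells: (i=1,j) -> k = 1 + j ; (i=2,j) -> k = j ; psi3 = -s1 - s2
  eta11 <- g$mu + g$t1 + g$p1 + g$s2
  eta12 <- g$mu + g$t1 - g$p1 - g$s1 - g$s2
  eta21 <- g$mu - g$t1 + g$p1 + g$s1
  eta22 <- g$mu - g$t1 - g$p1 + g$s2
  lp <- dbinom(D[1, 1], N[1, 1], plogis(eta11), log = TRUE) +
    dbinom(D[1, 2], N[1, 2], plogis(eta12), log = TRUE) +
    dbinom(D[2, 1], N[2, 1], plogis(eta21), log = TRUE) +
    dbinom(D[2, 2], N[2, 2], plogis(eta22), log = TRUE) -
    tau0 / 2 * ((2 * g$t1)^2) - tau0 / 2 * ((2 * g$p1)^2) -
    tau0 / 2 * ((g$s2 - g$s1)^2 + (-g$s1 - 2 * g$s2)^2)
  w <- exp(lp - max(lp))
  oracle_mu <- sum(w * g$mu) / sum(w)
  expect_equal(mean(fit$draws$mu), oracle_mu, tolerance = 0.02)
})
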