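#' Cohort index on an age-group by period grid
#'
#' With age bands `C` times wider than the (annual) periods, age group `i`
#' (1 = youngest, `I` = oldest) and period `j` identify the birth cohort
#' `k = C * (I - i) + j`: the oldest age group in the first period is cohort
#' 1, the youngest in the last period the most recent cohort. Over a full
#' grid the distinct cohorts number `K = C * (I - 1) + J`.
#'
#' @param i Age-group index (1-based, youngest first); vectorised.
#' @param j Period index (1-based); vectorised.
#' @param I Total number of age groups.
#' @param C Width of the age bands in periods.
#' @return Integer cohort index `k`, `1 <= k <= C * (I - 1) + J`.
#' @examples
#' cohort_index(1, 33, I = 6, C = 10)  # youngest age, last period -> 83
#' cohort_index(6, 1, I = 6, C = 10)   # oldest age, first period -> 1
#' @export
cohort_index <- function(i, j, I, C) {
  if (any(i < 1L | i > I)) stop("age index out of range 1..", I, call. = FALSE)
  if (any(j < 1L)) stop("period index must be >= 1", call. = FALSE)
  as.integer(C * (I - i) + j)
}

#' Specify a Bayesian age-period-cohort model
#'
#' The model places the logit of the death probability on a linear predictor
#' `mu + theta_i + phi_j + psi_k (+ z_ij)` with Gaussian random-walk
#' smoothing priors of first (`"rw1"`) or second (`"rw2"`) order on the age,
#' period and cohort blocks, Gamma hyperpriors on the block precisions, and
#' optionally i.i.d. Gaussian cell-level heterogeneity `z` absorbing
#' overdispersion. Second-order walks are the default: their predictive mean
#' continues the local linear trend, which is what lets the fitted components
#' "continue along their last observed linear trends" when forecasting.
#'
#' @param age,period,cohort Prior order per block: `"rw1"` or `"rw2"`.
#' @param heterogeneity Include the cell-level heterogeneity term?
#' @param prior_shape,prior_rate Gamma hyperprior parameters for the block
#'   precisions, recycled to length 4 in the order age, period, cohort,
#'   heterogeneity. Defaults Gamma(1, 5e-5), weakly informative.
#' @param fixed_precision Optional named vector fixing some precisions
#'   (names among `age`, `period`, `cohort`, `heterogeneity`); fixed blocks
#'   skip the Gibbs update. Mainly for validation studies.
#' @param chains,iter,burn,thin MCMC settings; `iter` is per chain and
#'   includes `burn`.
#' @param seed Base seed; chain `c` runs under `seed + c - 1`.
#' @return A list of class `bapc_spec`.
#' @export
bapc_spec <- function(age = "rw2", period = "rw2", cohort = "rw2",
                      heterogeneity = FALSE,
                      prior_shape = 1, prior_rate = 5e-5,
                      fixed_precision = NULL,
                      chains = 4L, iter = 50000L, burn = 20000L, thin = 10L,
                      seed = 1L) {
  ords <- c(age = age, period = period, cohort = cohort)
  if (!all(ords %in% c("rw1", "rw2"))) {
    stop("prior orders must be 'rw1' or 'rw2'", call. = FALSE)
  }
  if (!(iter > burn && burn >= 0)) {
    stop("need iter > burn >= 0", call. = FALSE)
  }
  shape <- rep_len(prior_shape, 4L); rate <- rep_len(prior_rate, 4L)
  if (any(shape <= 0) || any(rate <= 0)) {
    stop("hyperparameters must be positive", call. = FALSE)
  }
  fp <- rep(NA_real_, 4L)
  names(fp) <- c("age", "period", "cohort", "heterogeneity")
  if (!is.null(fixed_precision)) {
    bad <- setdiff(names(fixed_precision), names(fp))
    if (length(bad)) stop("unknown fixed_precision name(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    fp[names(fixed_precision)] <- fixed_precision
  }
  structure(
    list(order = ords, heterogeneity = isTRUE(heterogeneity),
         prior_shape = shape, prior_rate = rate, fixed_precision = fp,
         chains = as.integer(chains), iter = as.integer(iter),
         burn = as.integer(burn), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "bapc_spec"
  )
}

#' Fit the Bayesian age-period-cohort model by MCMC
#'
#' Runs `spec$chains` Metropolis-within-Gibbs chains (single-site adaptive
#' Gaussian random-walk updates for the intercept and effect blocks, conjugate
#' Gamma updates for the precisions) on
#' `deaths[i, j] ~ Binomial(N[i, j], plogis(mu + theta_i + phi_j + psi_k (+ z_ij)))`.
#' Only the linear predictor is likelihood-identified; the sampler recentres
#' block levels into the intercept each iteration and leaves the
#' age-period-cohort linear confound free. Forecasts and deviances depend on
#' the identified predictor only; [decompose_effects()] applies a reporting
#' gauge.
#'
#' @param s A [mortality_surface()].
#' @param spec A [bapc_spec()].
#' @return An object of class `bapc_fit` holding the retained draws of all
#'   blocks and precisions, per-draw deviance, acceptance rates per chain,
#'   and the grid geometry (`I`, `J`, `C`, `K = C*(I-1)+J`).
#' @examples
#' \donttest{
#' sim <- simulate_surface(sim_config(I = 4, J = 10, seed = 3))
#' fit <- fit_bapc(sim$surface, bapc_spec(chains = 1, iter = 2000, burn = 500))
#' glance(fit)
#' }
#' @export
fit_bapc <- function(s, spec = bapc_spec()) {
  stopifnot(inherits(s, "mortality_surface"), inherits(spec, "bapc_spec"))
  ages <- attr(s, "ages")
  D <- surface_matrix(s, "deaths")
  N <- surface_matrix(s, "population")
  I <- nrow(D); J <- ncol(D); C <- ages$width
  K <- C * (I - 1L) + J
  ord <- function(b) if (spec$order[[b]] == "rw1") 1L else 2L
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    chains[[ch]] <- with_seed(spec$seed + ch - 1L, {
      bapc_chain(D, N, C,
                 ord("age"), ord("period"), ord("cohort"),
                 spec$heterogeneity,
                 spec$prior_shape, spec$prior_rate,
                 unname(spec$fixed_precision),
                 spec$iter, spec$burn, spec$thin)
    })
  }
  bind <- function(name) do.call(rbind, lapply(chains, function(x) {
    v <- x[[name]]
    if (is.matrix(v)) v else matrix(v, ncol = 1)
  }))
  draws <- list(
    mu = as.vector(bind("mu")),
    theta = bind("theta"), phi = bind("phi"), psi = bind("psi"),
    z = if (spec$heterogeneity) bind("z") else NULL,
    tau = bind("tau")
  )
  colnames(draws$tau) <- c("age", "period", "cohort", "heterogeneity")
  structure(
    list(draws = draws,
         deviance = as.vector(bind("deviance")),
         accept = do.call(rbind, lapply(chains, `[[`, "accept")),
         I = I, J = J, C = C, K = K,
         years = sort(unique(s$year)),
         sex = unique(s$sex),
         age_scheme = ages,
         surface = s,
         spec = spec),
    class = "bapc_fit"
  )
}

# Linear-predictor draws for the observed window: n_draws x (I*J), cells in
# column-major (age fastest) order.
eta_draws <- function(fit) {
  I <- fit$I; J <- fit$J
  kmat <- cohort_grid(I, J, fit$C)
  idx_i <- rep(seq_len(I), times = J)
  idx_j <- rep(seq_len(J), each = I)
  eta <- fit$draws$mu +
    fit$draws$theta[, idx_i, drop = FALSE] +
    fit$draws$phi[, idx_j, drop = FALSE] +
    fit$draws$psi[, as.vector(kmat), drop = FALSE]
  if (!is.null(fit$draws$z)) eta <- eta + fit$draws$z
  eta
}

#' @export
print.bapc_fit <- function(x, ...) {
  cat("<bapc_fit> ", x$sex, ", I=", x$I, " J=", x$J, " C=", x$C,
      " (K=", x$K, " cohorts)", if (x$spec$heterogeneity)
        " + heterogeneity", "\n", sep = "")
  cat("  ", length(x$draws$mu), " retained draws from ", x$spec$chains,
      " chain(s); mean acceptance ",
      paste(sprintf("%s %.0f%%", colnames(x$accept),
                    100 * colMeans(x$accept, na.rm = TRUE)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Forecast death probabilities from a fitted BAPC model
#'
#' Per retained draw, the future period and cohort effects are sampled from
#' their random-walk predictive distributions (an RW2 continues the local
#' linear trend in its predictive mean; an RW1 continues the last level) at
#' that draw's block precision; future heterogeneity is drawn from its prior
#' (or set to zero). Death probabilities per future cell are summarised by
#' the posterior mean and the 2.5/97.5 percentiles.
#'
#' @param object A [fit_bapc()] result.
#' @param horizon Years ahead to predict (>= 1).
#' @param seed RNG seed for the predictive draws.
#' @param future_z `"draw"` (default) samples future heterogeneity from its
#'   prior; `"zero"` switches it off. Ignored for models without
#'   heterogeneity.
#' @param ... Unused.
#' @return A `rate_forecast` tibble (see [forecast_lee_carter()]) with the
#'   per-draw probabilities in attribute `draws`.
#' @export
predict.bapc_fit <- function(object, horizon, seed = 1,
                             future_z = c("draw", "zero"), ...) {
  stopifnot(horizon >= 1)
  future_z <- match.arg(future_z)
  fit <- object
  I <- fit$I; J <- fit$J; C <- fit$C; K <- fit$K; H <- as.integer(horizon)
  n <- length(fit$draws$mu)
  ord <- function(b) if (fit$spec$order[[b]] == "rw1") 1L else 2L
  with_seed(seed, {
    phi_f <- rw_extend(fit$draws$phi, H, ord("period"),
                       fit$draws$tau[, "period"])
    psi_f <- rw_extend(fit$draws$psi, H, ord("cohort"),
                       fit$draws$tau[, "cohort"])
    z_f <- NULL
    if (!is.null(fit$draws$z) && future_z == "draw") {
      z_f <- matrix(rnorm(n * I * H, 0,
                          rep(1 / sqrt(fit$draws$tau[, "heterogeneity"]),
                              I * H)),
                    n, I * H)
    }
  })
  # future cells: age i, horizon step h -> period J + h, cohort C*(I-i)+J+h
  q_draws <- array(NA_real_, c(n, I, H))
  for (h in seq_len(H)) {
    for (i in seq_len(I)) {
      k <- C * (I - i) + J + h
      eta <- fit$draws$mu + fit$draws$theta[, i] + phi_f[, h] +
        (if (k <= K) fit$draws$psi[, k] else psi_f[, k - K])
      if (!is.null(z_f)) eta <- eta + z_f[, (h - 1) * I + i]
      q_draws[, i, h] <- plogis(eta)
    }
  }
  q_mean <- apply(q_draws, c(2, 3), mean)
  q_lo <- apply(q_draws, c(2, 3), quantile, probs = 0.025, names = FALSE)
  q_hi <- apply(q_draws, c(2, 3), quantile, probs = 0.975, names = FALSE)
  years <- fit$years[length(fit$years)] + seq_len(H)
  new_rate_forecast(
    sex = fit$sex, ages = fit$age_scheme, years = years,
    m = -log(1 - q_mean), m_lower = -log(1 - q_lo), m_upper = -log(1 - q_hi),
    draws_q = q_draws, model = "bapc"
  )
}

# Extend each row of a draws matrix H steps by its RW predictive
# distribution; tau gives the per-draw innovation precision (may be Inf).
rw_extend <- function(x, H, ord, tau) {
  n <- nrow(x); p <- ncol(x)
  sds <- 1 / sqrt(tau)
  sds[!is.finite(sds)] <- 0
  out <- matrix(NA_real_, n, H)
  last1 <- x[, p]
  last2 <- if (p >= 2) x[, p - 1] else x[, p]
  for (h in seq_len(H)) {
    mean_h <- if (ord == 1L) last1 else 2 * last1 - last2
    out[, h] <- mean_h + rnorm(n, 0, sds)
    last2 <- last1
    last1 <- out[, h]
  }
  out
}

#' Deviance information criterion of a BAPC fit
#'
#' `DIC = mean(deviance) + pD` with
#' `pD = mean(deviance) - deviance(posterior mean linear predictor)`; the
#' deviance is minus twice the binomial log-likelihood (including the
#' binomial coefficient). The focus is the cell-level linear predictor.
#' Smaller DIC indicates a better supported, more parsimonious model.
#'
#' @param fit A [fit_bapc()] result with at least 2 retained draws.
#' @return A one-row tibble with columns `dic`, `p_d`, `mean_deviance`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "bapc_fit"))
  if (length(fit$deviance) < 2L) {
    stop("need at least 2 retained draws to compute DIC", call. = FALSE)
  }
  dbar <- mean(fit$deviance)
  eta_bar <- colMeans(eta_draws(fit))
  D <- surface_matrix(fit$surface, "deaths")
  N <- surface_matrix(fit$surface, "population")
  dhat <- -2 * sum(dbinom(as.vector(D), as.vector(N),
                          plogis(eta_bar), log = TRUE))
  tibble::tibble(dic = dbar + (dbar - dhat), p_d = dbar - dhat,
                 mean_deviance = dbar)
}

#' Identify and summarise age, period and cohort effects
#'
#' The likelihood identifies only the linear predictor: levels can move
#' between the intercept and each block, and a linear trend can move among
#' the three blocks along `k = C*(I-i) + j`. For reporting, a gauge is
#' applied to every retained draw: each block is centred to sum to zero and
#' the inseparable linear component is removed from one block (default: from
#' the cohort block, i.e. the common drift is attributed to period and the
#' age schedule). Forecasts never use the gauge — they are functions of the
#' identified predictor — so the choice only affects interpretation.
#'
#' @param fit A [fit_bapc()] result.
#' @param gauge `"cohort_detrend"` (default; removes the linear trend from
#'   the cohort block) or `"period_detrend"` (removes it from the period
#'   block instead).
#' @return An object of class `bapc_effects`: tibble `effects` (`effect`,
#'   `index`, `label`, `estimate`, `lower`, `upper`), tibble `variance_shares`
#'   (`effect`, `share` — posterior mean share of cell-level linear-predictor
#'   variance), the gauge label, and the gauge-transformed draws.
#' @export
decompose_effects <- function(fit, gauge = c("cohort_detrend",
                                             "period_detrend")) {
  stopifnot(inherits(fit, "bapc_fit"))
  gauge <- match.arg(gauge)
  g <- apply_gauge(fit$draws, fit$I, fit$J, fit$C, fit$K, gauge)
  kmat <- cohort_grid(fit$I, fit$J, fit$C)
  summ <- function(mat, effect, labels, index = seq_len(ncol(mat))) {
    tibble::tibble(
      effect = effect, index = index, label = labels,
      estimate = colMeans(mat),
      lower = apply(mat, 2, quantile, 0.025, names = FALSE),
      upper = apply(mat, 2, quantile, 0.975, names = FALSE)
    )
  }
  effects <- dplyr::bind_rows(
    summ(matrix(g$mu, ncol = 1), "intercept", "mu", 1L),
    summ(g$theta, "age", fit$age_scheme$labels),
    summ(g$phi, "period", as.character(fit$years)),
    summ(g$psi, "cohort", as.character(seq_len(fit$K)))
  )
  # per-draw cell-level variance share of each block
  idx_i <- rep(seq_len(fit$I), times = fit$J)
  idx_j <- rep(seq_len(fit$J), each = fit$I)
  idx_k <- as.vector(kmat)
  v_age <- apply(g$theta[, idx_i, drop = FALSE], 1, var)
  v_per <- apply(g$phi[, idx_j, drop = FALSE], 1, var)
  v_coh <- apply(g$psi[, idx_k, drop = FALSE], 1, var)
  v_z <- if (!is.null(fit$draws$z)) apply(fit$draws$z, 1, var) else NULL
  tot <- v_age + v_per + v_coh + (v_z %||% 0)
  shares <- tibble::tibble(
    effect = c("age", "period", "cohort",
               if (!is.null(v_z)) "heterogeneity"),
    share = c(mean(v_age / tot), mean(v_per / tot), mean(v_coh / tot),
              if (!is.null(v_z)) mean(v_z / tot))
  )
  structure(list(effects = effects, variance_shares = shares,
                 gauge = gauge, draws = g),
            class = "bapc_effects")
}

# Gauge transform applied draw-wise; keeps mu + theta_i + phi_j + psi_k
# invariant cell-by-cell. Idempotent.
apply_gauge <- function(draws, I, J, C, K, gauge) {
  theta <- draws$theta; phi <- draws$phi; psi <- draws$psi
  mu <- draws$mu
  kk <- seq_len(K); jj <- seq_len(J); ii <- seq_len(I)
  if (gauge == "cohort_detrend") {
    kc <- kk - mean(kk)
    slope <- (psi %*% kc) / sum(kc^2)            # per-draw OLS slope on k
    psi <- psi - tcrossprod(slope, kk)
    phi <- phi + tcrossprod(slope, jj)
    theta <- theta + tcrossprod(slope, C * (I - ii))
  } else {
    jc <- jj - mean(jj)
    slope <- (phi %*% jc) / sum(jc^2)
    phi <- phi - tcrossprod(slope, jj)
    psi <- psi + tcrossprod(slope, kk)
    theta <- theta - tcrossprod(slope, C * (I - ii))
  }
  for (nm in c("theta", "phi", "psi")) {
    b <- get(nm)
    mu <- mu + rowMeans(b)
    assign(nm, b - rowMeans(b))
  }
  list(mu = mu, theta = theta, phi = phi, psi = psi, z = draws$z,
       tau = draws$tau)
}

#' @export
print.bapc_effects <- function(x, ...) {
  cat("<bapc_effects> gauge:", x$gauge, "\n")
  cat("variance shares of the linear predictor:\n")
  print(x$variance_shares)
  invisible(x)
}
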