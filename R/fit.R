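#' MCMC settings
#'
#' Defaults: 2000 burn-in sweeps, 5000 retained samples at thinning 2.
#' Proposal scales are adapted during burn-in only (toward 40% acceptance
#' for the integer visibility walk, 25-30% for the parameter blocks) and
#' frozen afterwards, so the chain is a valid time-homogeneous sampler over
#' the retained draws and bit-reproducible under `rng_seed`.
#'
#' @param burnin number of burn-in sweeps.
#' @param samples number of retained draws.
#' @param thin thinning interval.
#' @param rng_seed optional integer seed.
#' @param prop_scale_N initial sd of the integer random walk on `N`
#'   (default `median_N / 10`, resolved at fit time).
#' @param prop_scale_theta initial sd of the superpopulation parameter walk.
#' @param prop_scale_meas initial sd of the reporting parameter walk.
#' @param prop_scale_u initial sd of the integer visibility walk.
#' @param prop_scale_W initial sd of the random walk on the unsampled total
#'   visibility, as a fraction of the sd of the superpopulation sum.
#' @param store_u if `TRUE`, keep the full matrix of imputed visibility
#'   draws (samples x n).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(burnin = 2000, samples = 5000, thin = 2,
                        rng_seed = NULL,
                        prop_scale_N = NULL, prop_scale_theta = 0.1,
                        prop_scale_meas = 0.15, prop_scale_u = 2,
                        prop_scale_W = 0.3, store_u = FALSE) {
  stopifnot(burnin >= 0, samples >= 1, thin >= 1, prop_scale_W > 0)
  structure(list(burnin = as.integer(burnin), samples = as.integer(samples),
                 thin = as.integer(thin), rng_seed = rng_seed,
                 prop_scale_N = prop_scale_N,
                 prop_scale_theta = prop_scale_theta,
                 prop_scale_meas = prop_scale_meas,
                 prop_scale_u = prop_scale_u,
                 prop_scale_W = prop_scale_W,
                 store_u = isTRUE(store_u)),
            class = "mcmc_config")
}

#' Fit the imputed-visibility successive sampling size model
#'
#' Bayesian estimation of the hidden population size `N` from the enrollment
#' order and self-reported degrees of an RDS sample. The sample is modelled
#' as sequential probability-proportional-to-visibility draws without
#' replacement from a finite population whose latent visibilities are i.i.d.
#' from a zero-truncated superpopulation distribution; reported degrees are
#' noisy, possibly inflated versions of visibility under a
#' Conway-Maxwell-Poisson measurement-error model with mean `tau * u` and
#' dispersion `1 / rho`.
#'
#' A Metropolis-within-Gibbs sampler cycles over (1) the imputed
#' visibilities, (2) the reporting parameters `(tau, rho)`, (3) the
#' superpopulation parameters, (4) the total visibility `W` of the unsampled
#' units, and (5) `N` on the discrete prior grid. The unsampled units enter
#' the likelihood only through `W`, whose conditional law given `(N, theta)`
#' is the `(N - n)`-fold convolution of the superpopulation distribution:
#' that density is evaluated exactly (by convolution) for the discrete
#' `table` family and by the saddlepoint (exponential-tilting) approximation
#' otherwise — the likelihood concentrates `W` far below its unconditional
#' mean, so tail-accurate evaluation is what carries the depletion signal.
#' Moves of `theta` and `N` transport `W` proportionally so the tilt is
#' preserved. With `impute_visibility = FALSE` the visibilities are fixed at
#' the reported degrees and blocks (1)-(2) are skipped, recovering the
#' original SS-PSE without measurement error.
#'
#' @param sample an [rds_sample()].
#' @param prior a [prior_spec()].
#' @param mcmc an [mcmc_config()].
#' @param impute_visibility jointly model visibility (default) or trust the
#'   reported degrees.
#' @param family superpopulation family: `"cmp"` (default), `"negbinom"`, or
#'   `"table"` (fixed, known distribution over support `1..K` — used for
#'   exact-oracle validation).
#' @param table_probs probabilities for `family = "table"`.
#' @param fix_theta fix the superpopulation parameters at `theta_init`
#'   (implied by `family = "table"`).
#' @param theta_init optional `c(mu, sigma)` initial/fixed superpopulation
#'   moments.
#' @param fix_meas fix the reporting parameters at `(tau_init, rho_init)`.
#' @param tau_init,rho_init initial (or fixed) reporting parameters.
#' @param min_n minimum sample size accepted (a warning is issued below 50).
#' @return an object of class `sspse_fit`: a list with `draws` (a tibble of
#'   posterior draws of `N`, `mu`, `sigma`, `tau`, `rho`, `W`), `quantiles`
#'   (5/25/50/75/95% of `N`), `visibility` (per-participant posterior mean
#'   and sd of imputed visibility), `prior` (the evaluated prior grid),
#'   `accept` (block acceptance rates), and the inputs.
#' @seealso [posterior_summary()], [tidy.sspse_fit()], [autoplot.sspse_fit()]
#' @export
fit_sspse <- function(sample, prior, mcmc = mcmc_config(),
                      impute_visibility = TRUE,
                      family = c("cmp", "negbinom", "table"),
                      table_probs = NULL,
                      fix_theta = FALSE, theta_init = NULL,
                      fix_meas = FALSE, tau_init = 1, rho_init = 0.2,
                      min_n = 20) {
  stopifnot(inherits(sample, "rds_sample"), inherits(prior, "prior_spec"),
            inherits(mcmc, "mcmc_config"))
  family <- rlang::arg_match(family)
  n <- nrow(sample)
  if (n < min_n) {
    rlang::abort(paste0("sample size ", n, " is below the minimum ", min_n),
                 class = "rdsize_error_fit")
  }
  if (n < 50) {
    rlang::warn(paste0("sample size ", n,
                       " is small; size estimates will lean on the prior"))
  }
  d <- effective_degree(sample)
  if (all(is.na(d))) {
    rlang::abort("all reported degrees are missing",
                 class = "rdsize_error_fit")
  }
  if (!impute_visibility && any(is.na(d))) {
    rlang::abort(
      "impute_visibility = FALSE requires a reported degree for every participant",
      class = "rdsize_error_fit")
  }

  prior_grid <- prior_pmf_N(prior, n) # errors if median_N < n
  logprior <- log(pmax(prior_grid$pmf, 1e-300))
  prior_cdf <- cumsum(prior_grid$pmf)

  dbar <- mean(d, na.rm = TRUE)
  dsd <- stats::sd(d, na.rm = TRUE)
  if (!is.finite(dsd) || is.na(dsd)) dsd <- 1
  hyper <- c(
    prior$mu_meanlog %||% log(max(dbar, 1.5)),
    prior$mu_sdlog,
    prior$sigma_scale %||% max(dsd, 1),
    prior$tau_meanlog, prior$tau_sdlog, prior$rho_scale)

  if (family == "table") {
    if (is.null(table_probs) || abs(sum(table_probs) - 1) > 1e-8) {
      rlang::abort("family 'table' needs table_probs summing to 1",
                   class = "rdsize_error_fit")
    }
    if (resolve_max_N(prior, n) - n > 2000) {
      rlang::abort(
        "family 'table' enumerates the unsampled total exactly; use max_N - n <= 2000",
        class = "rdsize_error_fit")
    }
    fix_theta <- TRUE
    th1 <- 0; th2 <- 0 # unused
  } else {
    mu0 <- if (!is.null(theta_init)) theta_init[1] else
      max(dbar / tau_init, 1.3)
    sig0 <- if (!is.null(theta_init)) theta_init[2] else max(dsd, 0.75)
    if (family == "cmp") {
      par <- tryCatch(
        cmp_params_from_moments(mu0, sig0, truncated = TRUE),
        error = function(e) c(lambda = cmp_lambda_from_mean(mu0, 1, TRUE),
                              nu = 1))
      th1 <- log(par[["lambda"]]); th2 <- par[["nu"]]
    } else {
      if (sig0^2 <= mu0) sig0 <- sqrt(mu0) * 1.5
      th1 <- mu0; th2 <- sig0
    }
  }

  u_max <- max(10L * max(c(d, 3L), na.rm = TRUE), 60L)
  sc_N <- mcmc$prop_scale_N %||% max(prior$median_N / 10, 2)

  if (!is.null(mcmc$rng_seed)) set.seed(mcmc$rng_seed)
  raw <- cpp_sspse_mcmc(
    d = as.integer(d), impute = impute_visibility,
    family = match(family, c("cmp", "negbinom", "table")) - 1L,
    table_probs = as.numeric(table_probs %||% numeric()),
    fix_theta = fix_theta, th1_init = th1, th2_init = th2,
    fix_meas = fix_meas || !impute_visibility,
    tau_init = tau_init, rho_init = max(rho_init, 1.5e-3),
    logprior = logprior, prior_cdf = prior_cdf,
    hyper = hyper,
    burnin = mcmc$burnin, samples = mcmc$samples, thin = mcmc$thin,
    prop_scales = c(sc_N, mcmc$prop_scale_theta, mcmc$prop_scale_meas,
                    mcmc$prop_scale_u, mcmc$prop_scale_W),
    u_max = as.integer(u_max), store_u = mcmc$store_u)

  if (any(!is.finite(raw$N))) {
    rlang::abort("non-finite draws; likelihood or prior is degenerate",
                 class = "rdsize_error_fit")
  }

  draws <- tibble::tibble(
    .iter = seq_along(raw$N), N = as.integer(raw$N),
    mu = raw$mu, sigma = raw$sigma, tau = raw$tau, rho = raw$rho, W = raw$W)
  qs <- quantile_table(draws$N)
  visibility <- tibble::tibble(
    id = sample$id, degree = d,
    u_mean = raw$u_mean, u_sd = raw$u_sd)

  structure(
    list(draws = draws, quantiles = qs, visibility = visibility,
         u_draws = if (mcmc$store_u) raw$u_draws else NULL,
         prior = prior_grid, prior_spec = prior, mcmc = mcmc,
         impute_visibility = impute_visibility, family = family,
         accept = raw$accept, prop_scales_final = raw$scales,
         n = n, sample = sample,
         label = attr(sample, "label") %||% ""),
    class = "sspse_fit")
}

quantile_table <- function(draws) {
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  # type-7 linear interpolation, the documented and fixed convention
  q <- stats::quantile(draws, probs = probs, type = 7, names = FALSE)
  tibble::tibble(quantile = probs, N = q)
}

#' Posterior quantile summary
#'
#' Empirical 5/25/50/75/95% quantiles of the population size draws (type-7
#' linear interpolation); the median is the point estimate.
#'
#' @param result an `sspse_fit`, or a numeric vector of posterior draws.
#' @return a tibble with columns `quantile` and `N`.
#' @export
posterior_summary <- function(result) {
  draws <- if (inherits(result, "sspse_fit")) result$draws$N else result
  if (length(draws) == 0) {
    rlang::abort("no posterior draws", class = "rdsize_error_fit")
  }
  if (length(draws) < 100) {
    rlang::warn("fewer than 100 retained draws; quantiles will be noisy")
  }
  quantile_table(draws)
}

#' @export
print.sspse_fit <- function(x, ...) {
  q <- x$quantiles$N
  cat("<sspse_fit>", if (x$impute_visibility) "imputed visibility" else
    "fixed degrees",
    if (nzchar(x$label)) paste0("| ", x$label) else "", "\n")
  cat(sprintf("  n = %d | posterior median N = %.0f | 90%% CrI [%.0f, %.0f]\n",
              x$n, q[3], q[1], q[5]))
  invisible(x)
}

#' Tidy posterior summaries of a fitted size model
#'
#' @param x an `sspse_fit`.
#' @param conf_level credible level for the central interval (default 0.90,
#'   the convention for size estimation).
#' @param ... unused.
#' @return `tidy()` one row per parameter with posterior median and central
#'   credible interval; `glance()` a one-row model summary.
#' @export
tidy.sspse_fit <- function(x, conf_level = 0.90, ...) {
  a <- (1 - conf_level) / 2
  pars <- c("N", "mu", "sigma", "tau", "rho")
  if (!x$impute_visibility) pars <- setdiff(pars, c("tau", "rho"))
  if (x$family == "table") pars <- setdiff(pars, c("mu", "sigma"))
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p,
                   estimate = stats::median(v),
                   conf.low = stats::quantile(v, a, names = FALSE),
                   conf.high = stats::quantile(v, 1 - a, names = FALSE))
  })
}

#' @rdname tidy.sspse_fit
#' @export
glance.sspse_fit <- function(x, ...) {
  q <- x$quantiles$N
  tibble::tibble(
    n = x$n, draws = nrow(x$draws),
    N_median = q[3], N_lo90 = q[1], N_hi90 = q[5],
    prior_median = x$prior_spec$median_N,
    impute_visibility = x$impute_visibility,
    accept_N = unname(x$accept["N"]))
}

#' Basic chain diagnostics
#'
#' Split-half quantile agreement for the population size draws: the first and
#' second halves of the retained chain are summarised separately and the
#' largest relative quantile discrepancy is reported. Values well under ~0.2
#' indicate adequate stationarity for the default settings.
#'
#' @param fit an `sspse_fit`.
#' @return a list with `split_half` (tibble of quantiles per half),
#'   `max_rel_diff`, and the block acceptance rates.
#' @export
mcmc_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "sspse_fit"))
  v <- fit$draws$N
  h <- length(v) %/% 2
  q1 <- quantile_table(v[seq_len(h)])
  q2 <- quantile_table(v[(h + 1):length(v)])
  rel <- abs(q1$N - q2$N) / pmax(abs(q1$N + q2$N) / 2, 1)
  list(split_half = dplyr::bind_rows(
    dplyr::mutate(q1, half = 1L), dplyr::mutate(q2, half = 2L)),
    max_rel_diff = max(rel),
    accept = fit$accept)
}

#' Sensitivity of the size estimate to the expert prior median
#'
#' Refits the model with each expert's prior median separately and with their
#' average (the headline analysis), returning aligned results for
#' superimposed plotting.
#'
#' @param sample an [rds_sample()].
#' @param expert_medians numeric vector of two expert prior medians.
#' @param prior a [prior_spec()] template; its `median_N` is replaced.
#' @param mcmc an [mcmc_config()]; each fit reuses its seed offset by the fit
#'   index so the three chains are independent but reproducible.
#' @param ... passed on to [fit_sspse()].
#' @return a list of class `sspse_sensitivity` with elements `fits` (named
#'   list of `sspse_fit`) and `summary` (tibble of quantiles per prior
#'   median).
#' @export
sensitivity_fit <- function(sample, expert_medians, prior, mcmc = mcmc_config(),
                            ...) {
  stopifnot(length(expert_medians) == 2, all(expert_medians > 0))
  medians <- c(expert_1 = expert_medians[1], expert_2 = expert_medians[2],
               average = mean(expert_medians))
  fits <- purrr::imap(medians, function(m, nm) {
    pr <- prior
    pr$median_N <- as.integer(round(m))
    mc <- mcmc
    if (!is.null(mc$rng_seed)) {
      mc$rng_seed <- mc$rng_seed + match(nm, names(medians)) - 1L
    }
    fit_sspse(sample, pr, mc, ...)
  })
  summary <- purrr::imap_dfr(fits, function(f, nm) {
    dplyr::mutate(f$quantiles, prior_median = f$prior_spec$median_N,
                  which = nm)
  })
  structure(list(fits = fits, summary = summary),
            class = "sspse_sensitivity")
}
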