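#' Prior specification for the population size
#'
#' The prior on `N` is parameterised by the expert prior median. The default
#' family, `beta_sample_fraction`, places a `Beta(1, beta)` law on the sample
#' fraction `n / N` and root-solves `beta` so that the induced prior median
#' over the grid `{n, ..., max_N}` equals `median_N`; it has the heavy right
#' tail characteristic of hidden-population size priors. `flat` is uniform on
#' the grid, and `lognormal` centres `log N` at `log(median_N)`.
#'
#' Hyperpriors for the superpopulation and reporting parameters may be
#' overridden; entries left `NULL` are set from the data at fit time (the
#' visibility mean prior is centred at the sample mean reported degree, its
#' spread prior scaled to the sample standard deviation, the inflation factor
#' prior centred at 1, i.e. no misreporting).
#'
#' @param median_N expert prior median for the population size.
#' @param family prior family for `N`.
#' @param max_N upper grid bound; default `max(20 * median_N, 10 * n)`,
#'   resolved at fit time when `NULL`.
#' @param lognormal_sdlog sd of `log N` for the lognormal family.
#' @param mu_meanlog,mu_sdlog lognormal hyperprior for the mean visibility.
#' @param sigma_scale half-normal scale for the visibility sd.
#' @param tau_meanlog,tau_sdlog lognormal hyperprior for the degree inflation
#'   factor.
#' @param rho_scale half-normal scale for the reporting dispersion.
#' @return a list of class `prior_spec`.
#' @export
prior_spec <- function(median_N,
                       family = c("beta_sample_fraction", "flat", "lognormal"),
                       max_N = NULL, lognormal_sdlog = 1,
                       mu_meanlog = NULL, mu_sdlog = 1,
                       sigma_scale = NULL,
                       tau_meanlog = 0, tau_sdlog = 0.5,
                       rho_scale = 0.5) {
  family <- rlang::arg_match(family)
  stopifnot(median_N >= 1)
  if (!is.null(max_N) && max_N <= median_N) {
    rlang::abort("max_N must exceed median_N", class = "rdsize_error_prior")
  }
  structure(
    list(median_N = as.integer(median_N), family = family, max_N = max_N,
         lognormal_sdlog = lognormal_sdlog,
         mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
         sigma_scale = sigma_scale,
         tau_meanlog = tau_meanlog, tau_sdlog = tau_sdlog,
         rho_scale = rho_scale),
    class = "prior_spec")
}

resolve_max_N <- function(spec, n) {
  as.integer(spec$max_N %||% max(20 * spec$median_N, 10 * n))
}

#' Evaluate the prior over the population size grid
#'
#' @param spec a [prior_spec()].
#' @param n observed sample size (lower bound for `N`).
#' @return a tibble with columns `N` and `pmf` (normalised over the grid
#'   `{n, ..., max_N}`); the grid median equals `median_N` up to grid
#'   resolution.
#' @export
prior_pmf_N <- function(spec, n) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  if (spec$family != "flat" && spec$median_N < n) {
    rlang::abort(
      paste0("prior median (", spec$median_N, ") is below the sample size (",
             n, "); revise median_N/max_N"),
      class = "rdsize_error_prior")
  }
  max_N <- resolve_max_N(spec, n)
  grid <- seq.int(n, max_N)
  pmf <- switch(
    spec$family,
    flat = rep(1 / length(grid), length(grid)),
    lognormal = {
      # solve the location so the grid-truncated median hits median_N
      pmf_at <- function(ml) {
        w <- stats::dlnorm(grid, meanlog = ml, sdlog = spec$lognormal_sdlog)
        w / sum(w)
      }
      med_at <- function(ml) grid[which(cumsum(pmf_at(ml)) >= 0.5)[1]]
      # truncation at n inflates the median, so the location may need to sit
      # well below log(n)
      lo <- log(n) - 6; hi <- log(max_N)
      if (med_at(hi) < spec$median_N) {
        rlang::abort("median_N not attainable below max_N; raise max_N",
                     class = "rdsize_error_prior")
      }
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (med_at(mid) < spec$median_N) lo <- mid else hi <- mid
      }
      pmf_at(hi)
    },
    beta_sample_fraction = {
      # Beta(1, beta) on the sample fraction; f = n / (N + 1) keeps the
      # density finite at N = n. Median is monotone increasing in beta.
      pmf_at <- function(logb) {
        b <- exp(logb)
        f <- n / (grid + 1)
        # log of dbeta(f, 1, b) * |df/dN|, stabilised for large b
        lw <- log(b) + (b - 1) * log1p(-f) + log(n) - 2 * log(grid + 1)
        w <- exp(lw - max(lw))
        w / sum(w)
      }
      med_at <- function(logb) {
        p <- pmf_at(logb)
        grid[which(cumsum(p) >= 0.5)[1]]
      }
      lo <- log(1e-3); hi <- log(1e8)
      if (med_at(hi) < spec$median_N) {
        rlang::abort("median_N not attainable below max_N; raise max_N",
                     class = "rdsize_error_prior")
      }
      for (it in 1:80) {
        mid <- (lo + hi) / 2
        if (med_at(mid) < spec$median_N) lo <- mid else hi <- mid
      }
      pmf_at(hi)
    })
  tibble::tibble(N = grid, pmf = pmf)
}
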