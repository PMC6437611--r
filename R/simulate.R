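#' Simulation configuration for synthetic RDS studies
#'
#' Bundles the ground-truth population and recruitment settings used by
#' [generate_population()] and [simulate_rds()]. Defaults mirror a small
#' urban key-population survey: a hidden population of `N = 1000`, target
#' sample of 100 (use 300 for a large-city study), at most 3 coupons per
#' participant, a handful of seeds, and an overdispersed visibility
#' distribution (mean 8, sd 6) with no degree misreporting beyond moderate
#' reporting noise.
#'
#' @param N true population size.
#' @param mu,sigma mean and standard deviation of the zero-truncated
#'   superpopulation visibility distribution; `sigma = 0` gives a point mass
#'   at `round(mu)`.
#' @param family superpopulation family: `"cmp"` (Conway-Maxwell-Poisson,
#'   default), `"negbinom"`, or `"table"` (explicit probabilities over
#'   support `1..K` via `table_probs`, used mainly for exact-oracle
#'   validation).
#' @param table_probs probability vector for `family = "table"`.
#' @param n_seeds number of seeds (the first draws of the process).
#' @param coupons coupons issued per participant (default 3).
#' @param target_n target sample size; recruitment stops there or when no
#'   coupons remain, whichever is first.
#' @param tau proportional inflation of reported degree relative to true
#'   visibility (1 = no inflation).
#' @param rho relative dispersion of reports around `tau * u`; `0` is the
#'   deterministic limit `d = round(tau * u)`.
#' @param heaping_rule `"none"`, `"round5"` or `"round10"`: round reports to
#'   the nearest multiple (half away from zero).
#' @param rng_seed optional integer seed; when set, the study-level helpers
#'   are bit-reproducible.
#' @param n_components number of disjoint network components (for bottleneck
#'   scenarios).
#' @param component_probs optional membership probabilities over components.
#' @param cross_component_rate probability that a recruitment draw crosses
#'   components (0 = perfect bottleneck).
#' @param seed_component optional component from which all seeds are drawn.
#' @param seed_mode `"pps"` (seeds are the first probability-proportional-
#'   to-size draws, favouring well-networked members) or `"top"` (the
#'   `n_seeds` most visible units).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(N = 1000, mu = 8, sigma = 6,
                       family = c("cmp", "negbinom", "table"),
                       table_probs = NULL,
                       n_seeds = 6, coupons = 3, target_n = 100,
                       tau = 1, rho = 0.3,
                       heaping_rule = c("none", "round5", "round10"),
                       rng_seed = NULL,
                       n_components = 1, component_probs = NULL,
                       cross_component_rate = 0,
                       seed_component = NULL,
                       seed_mode = c("pps", "top")) {
  family <- rlang::arg_match(family)
  heaping_rule <- rlang::arg_match(heaping_rule)
  seed_mode <- rlang::arg_match(seed_mode)
  stopifnot(N >= 1, n_seeds >= 1, coupons >= 1, target_n >= 1,
            n_components >= 1,
            cross_component_rate >= 0, cross_component_rate <= 1)
  if (target_n > N) {
    rlang::abort("target_n must not exceed N", class = "rdsize_error_config")
  }
  if (tau <= 0) {
    rlang::abort("tau must be positive", class = "rdsize_error_config")
  }
  if (rho < 0) {
    rlang::abort("rho must be non-negative", class = "rdsize_error_config")
  }
  if (family == "table") {
    if (is.null(table_probs) || any(table_probs < 0) ||
        abs(sum(table_probs) - 1) > 1e-8) {
      rlang::abort("family 'table' needs table_probs summing to 1",
                   class = "rdsize_error_config")
    }
  } else if (sigma > 0 && mu <= 1) {
    rlang::abort("superpopulation mean must exceed 1 on zero-truncated support",
                 class = "rdsize_error_config")
  }
  if (is.null(component_probs)) {
    component_probs <- rep(1 / n_components, n_components)
  }
  stopifnot(length(component_probs) == n_components)
  structure(
    list(N = as.integer(N), mu = mu, sigma = sigma, family = family,
         table_probs = table_probs,
         n_seeds = as.integer(n_seeds), coupons = as.integer(coupons),
         target_n = as.integer(target_n), tau = tau, rho = rho,
         heaping_rule = heaping_rule, rng_seed = rng_seed,
         n_components = as.integer(n_components),
         component_probs = component_probs,
         cross_component_rate = cross_component_rate,
         seed_component = seed_component, seed_mode = seed_mode),
    class = "sim_config")
}

#' Generate a finite population of latent visibilities
#'
#' Draws `N` visibilities i.i.d. from the configured zero-truncated
#' superpopulation distribution (the finite population is conceived as a
#' random sample from an infinite superpopulation), together with component
#' memberships for bottleneck scenarios.
#'
#' @param config a [sim_config()].
#' @return a tibble of class `rds_population` with columns `unit`,
#'   `visibility`, `component`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  N <- config$N
  vis <- switch(
    config$family,
    table = sample.int(length(config$table_probs), N, replace = TRUE,
                       prob = config$table_probs),
    {
      if (config$sigma == 0) {
        rep(as.integer(round(config$mu)), N)
      } else if (config$family == "cmp") {
        par <- cmp_params_from_moments(config$mu, config$sigma, truncated = TRUE)
        rcmp(N, par[["lambda"]], par[["nu"]], truncated = TRUE)
      } else {
        if (config$sigma^2 <= config$mu) {
          rlang::abort("negbinom family needs sigma^2 > mu",
                       class = "rdsize_error_config")
        }
        size <- config$mu^2 / (config$sigma^2 - config$mu)
        v <- stats::rnbinom(2L * N + 20L, size = size, mu = config$mu)
        v <- v[v >= 1][seq_len(N)] # zero-truncate by rejection
        while (anyNA(v)) {
          extra <- stats::rnbinom(N, size = size, mu = config$mu)
          v[is.na(v)] <- c(extra[extra >= 1], rep(NA, N))[seq_len(sum(is.na(v)))]
        }
        v
      }
    })
  comp <- if (config$n_components == 1) rep(1L, N) else
    sample.int(config$n_components, N, replace = TRUE,
               prob = config$component_probs)
  out <- tibble::tibble(unit = seq_len(N),
                        visibility = as.integer(vis),
                        component = comp)
  class(out) <- c("rds_population", class(out))
  out
}

round_to <- function(x, m) as.integer(m * floor(x / m + 0.5)) # half away from zero

#' Degree misreporting model
#'
#' Turns true visibilities into self-reported degrees: reports are drawn from
#' a Conway-Maxwell-Poisson distribution with mean `tau * u` and dispersion
#' `1 / rho` (so `rho -> 0` is the deterministic limit `d = round(tau * u)`),
#' then optionally heaped to the nearest multiple of 5 or 10, emulating the
#' rounding and misreporting that afflict self-reported network sizes.
#'
#' @param u integer vector of true visibilities (all `>= 1`).
#' @param tau proportional inflation factor (`> 0`).
#' @param rho relative reporting dispersion (`>= 0`).
#' @param heaping_rule `"none"`, `"round5"` or `"round10"`.
#' @param rng_seed optional seed for reproducibility.
#' @return integer vector of reported degrees (`>= 0`).
#' @examples
#' apply_measurement_error(c(3, 7, 12), tau = 1, rho = 0) # identity
#' @export
apply_measurement_error <- function(u, tau = 1, rho = 0.3,
                                    heaping_rule = c("none", "round5", "round10"),
                                    rng_seed = NULL) {
  heaping_rule <- rlang::arg_match(heaping_rule)
  if (tau <= 0) {
    rlang::abort("tau must be positive", class = "rdsize_error_config")
  }
  if (rho < 0) {
    rlang::abort("rho must be non-negative", class = "rdsize_error_config")
  }
  stopifnot(all(u >= 1))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  u <- as.integer(u)
  if (rho == 0) {
    d <- as.integer(floor(tau * u + 0.5))
  } else {
    nu <- 1 / rho
    d <- integer(length(u))
    for (uu in unique(u)) {
      idx <- which(u == uu)
      lam <- cmp_lambda_from_mean(tau * uu, nu, truncated = FALSE)
      d[idx] <- rcmp(length(idx), lam, nu, truncated = FALSE)
    }
  }
  if (heaping_rule == "round5") d <- round_to(d, 5)
  if (heaping_rule == "round10") d <- round_to(d, 10)
  d
}

#' Simulate RDS recruitment from a known population
#'
#' Sequential probability-proportional-to-size sampling without replacement:
#' at every step the next participant is drawn from the remaining units with
#' probability proportional to visibility, which is exactly the successive
#' sampling approximation of RDS that the size model assumes. Seeds are the
#' first `n_seeds` draws (or the most visible units under
#' `seed_mode = "top"`). Each later participant is attached to a recruiter
#' chosen uniformly among earlier participants with unused coupons; draws
#' stay within the recruiter's network component with probability
#' `1 - cross_component_rate`, so a two-component population with rate 0 and
#' seeds confined to one component reproduces a recruitment bottleneck.
#' Recruitment stops at `target_n` or when no coupons remain (a shorter
#' sample is returned with a warning, as happens in real surveys).
#'
#' Reported degrees are generated from the true visibilities via
#' [apply_measurement_error()] and stored in `degree_known`/`degree_seen`;
#' ground truth is kept in `true_visibility`.
#'
#' @param pop an `rds_population` from [generate_population()].
#' @param config the [sim_config()] used.
#' @param label optional sample label.
#' @return an [rds_sample()] with ground-truth columns `unit`,
#'   `true_visibility` and `component`.
#' @export
simulate_rds <- function(pop, config, label = NULL) {
  stopifnot(inherits(pop, "rds_population"), inherits(config, "sim_config"))
  N <- nrow(pop)
  stopifnot(config$target_n <= N)
  vis <- as.numeric(pop$visibility)
  comp <- pop$component
  remaining <- rep(TRUE, N)

  order_drawn <- integer(config$target_n)
  recruiter <- integer(config$target_n) # 0 = seed
  n_children <- integer(config$target_n)

  draw_pps <- function(pool) {
    if (length(pool) == 0) return(NA_integer_)
    if (length(pool) == 1) return(pool)
    pool[sample.int(length(pool), 1L, prob = vis[pool])]
  }

  # --- seeds ---
  seed_pool <- which(remaining &
                       (if (is.null(config$seed_component)) TRUE
                        else comp == config$seed_component))
  n_seeds <- min(config$n_seeds, length(seed_pool), config$target_n)
  if (config$seed_mode == "top") {
    seeds <- seed_pool[order(-vis[seed_pool])][seq_len(n_seeds)]
    for (s in seq_along(seeds)) {
      order_drawn[s] <- seeds[s]
      remaining[seeds[s]] <- FALSE
    }
  } else {
    for (s in seq_len(n_seeds)) {
      pick <- draw_pps(seed_pool[remaining[seed_pool]])
      order_drawn[s] <- pick
      remaining[pick] <- FALSE
    }
  }
  k <- n_seeds

  # --- peer recruitment ---
  while (k < config$target_n) {
    open <- which(n_children[seq_len(k)] < config$coupons)
    if (length(open) == 0) {
      rlang::warn(paste0("recruitment died out at n = ", k,
                         " (no open coupons); returning a shorter sample"),
                  class = "rdsize_warning_dieout")
      break
    }
    rec <- open[sample.int(length(open), 1L)]
    rec_comp <- comp[order_drawn[rec]]
    same <- config$cross_component_rate == 0 ||
      runif(1) >= config$cross_component_rate
    pool <- if (same) which(remaining & comp == rec_comp) else
      which(remaining & comp != rec_comp)
    if (length(pool) == 0 && config$cross_component_rate > 0) {
      pool <- which(remaining) # soft fallback when preferred pool is empty
    }
    if (length(pool) == 0) {
      # recruiter's component exhausted under a hard bottleneck: the
      # recruiter keeps an unusable coupon; retire them and try another
      n_children[rec] <- config$coupons
      if (all(n_children[seq_len(k)] >= config$coupons)) {
        rlang::warn(paste0("recruitment died out at n = ", k,
                           " (reachable units exhausted)"),
                    class = "rdsize_warning_dieout")
        break
      }
      next
    }
    pick <- draw_pps(pool)
    k <- k + 1
    order_drawn[k] <- pick
    recruiter[k] <- rec
    n_children[rec] <- n_children[rec] + 1L
    remaining[pick] <- FALSE
  }

  order_drawn <- order_drawn[seq_len(k)]
  recruiter <- recruiter[seq_len(k)]
  true_u <- pop$visibility[order_drawn]
  d <- apply_measurement_error(true_u, tau = config$tau, rho = config$rho,
                               heaping_rule = config$heaping_rule)
  ids <- sprintf("P%04d", seq_len(k))
  out <- tibble::tibble(
    id = ids,
    recruiter_id = ifelse(recruiter == 0L, NA_character_, ids[pmax(recruiter, 1L)]),
    enrollment_index = seq_len(k),
    degree_known = d,
    degree_seen = d,
    coupons_issued = config$coupons,
    unit = pop$unit[order_drawn],
    true_visibility = true_u,
    component = comp[order_drawn])
  rds_sample(out, label = label)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper seeding the generator once (`config$rng_seed`) and
#' running population generation, recruitment and degree misreporting in one
#' reproducible stream.
#'
#' @param config a [sim_config()].
#' @param label optional sample label.
#' @return a list with elements `population` (tibble) and `sample`
#'   (an `rds_sample`).
#' @export
simulate_rds_study <- function(config, label = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  config_noseed <- config
  config_noseed$rng_seed <- NULL
  pop <- generate_population(config_noseed)
  smp <- simulate_rds(pop, config_noseed, label = label)
  list(population = pop, sample = smp)
}
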