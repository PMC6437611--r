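#' Successive sampling ordered log-likelihood
#'
#' Log-probability of observing visibilities `u[1], ..., u[n]` in that
#' enrollment order under sequential probability-proportional-to-size
#' sampling without replacement, when the units never sampled have total
#' visibility `W`:
#' `sum_k [ log u_k - log(W + u_k + u_{k+1} + ... + u_n) ]`.
#' The unsampled units enter only through their total, which is what makes
#' an O(n) per-sweep MCMC possible.
#'
#' This is the ordered-selection factor only; the model-level posterior for
#' the population size additionally carries the `N! / (N - n)!` labelling
#' term and the superpopulation density of the unsampled total (see
#' [fit_sspse()]).
#'
#' @param u numeric vector of visibilities in enrollment order (all `>= 1`).
#' @param W total visibility of unsampled units (`>= 0`).
#' @return the log-likelihood (0 for a single certain selection).
#' @examples
#' # population {1,2,3}, observe (3, 1): (3/6) * (1/3) = 1/6
#' exp(ss_log_likelihood(c(3, 1), W = 2))
#' @export
ss_log_likelihood <- function(u, W) {
  stopifnot(length(u) >= 1, all(is.finite(u)), is.finite(W))
  if (any(u < 1)) {
    rlang::abort("all visibilities must be >= 1",
                 class = "rdsize_error_likelihood")
  }
  if (W < 0) {
    rlang::abort("unsampled total W must be non-negative",
                 class = "rdsize_error_likelihood")
  }
  cpp_ss_loglik(as.numeric(u), as.numeric(W))
}
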