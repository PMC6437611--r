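#' Multiplier population size estimates
#'
#' The service multiplier divides a count of non-duplicated clients who
#' accessed a service by the proportion of the probability-based survey
#' reporting use of that service; the unique-object multiplier does the same
#' with objects distributed to the population. When a standard error for the
#' proportion is supplied, an optional delta-method interval is attached
#' (`var(count / p) ~ count^2 * se^2 / p^4`), truncated below at the count
#' itself (the estimate can never be smaller than the enumerated clients).
#' Published applications report point estimates only; the interval is an
#' extension.
#'
#' @param unique_count non-negative count of non-duplicated service users or
#'   objects distributed.
#' @param proportion survey proportion in (0, 1] reporting the service or
#'   object (RDS-weighted where available; the weighting itself is out of
#'   scope and accepted as computed).
#' @param proportion_se optional standard error of the proportion.
#' @param method label: `"service_multiplier"` or `"object_multiplier"`.
#' @param level confidence level for the optional interval.
#' @return a one-row tibble with `method`, `point`, and (if `proportion_se`
#'   given) `low`, `high`.
#' @examples
#' multiplier_estimate(50, 0.5) # 100
#' @export
multiplier_estimate <- function(unique_count, proportion, proportion_se = NULL,
                                method = c("service_multiplier",
                                           "object_multiplier"),
                                level = 0.95) {
  method <- rlang::arg_match(method)
  stopifnot(unique_count >= 0)
  if (!is.finite(proportion) || proportion <= 0 || proportion > 1) {
    rlang::abort("proportion must lie in (0, 1]; a zero proportion leaves the estimate undefined",
                 class = "rdsize_error_multiplier")
  }
  point <- unique_count / proportion
  out <- tibble::tibble(method = method, point = point,
                        low = NA_real_, high = NA_real_)
  if (!is.null(proportion_se)) {
    se <- unique_count * proportion_se / proportion^2
    z <- stats::qnorm(1 - (1 - level) / 2)
    out$low <- max(point - z * se, unique_count)
    out$high <- point + z * se
  }
  out
}

#' Wisdom-of-the-crowds size estimate
#'
#' Participants are asked for their best guess of their population's size;
#' the estimate is the arithmetic mean of the retained guesses. Non-positive,
#' missing, or non-finite guesses are dropped (with a message reporting how
#' many).
#'
#' @param guesses numeric vector of participant guesses.
#' @return a one-row tibble with `method = "wisdom_of_crowds"`, `point`, and
#'   `n_used`.
#' @examples
#' wisdom_of_crowds(c(10, 20, 30)) # 20
#' @export
wisdom_of_crowds <- function(guesses) {
  keep <- is.finite(guesses) & guesses > 0
  dropped <- sum(!keep)
  if (dropped > 0) {
    rlang::inform(paste0("dropped ", dropped,
                         " non-positive/missing guesses"))
  }
  g <- guesses[keep]
  if (length(g) == 0) {
    rlang::abort("no valid guesses", class = "rdsize_error_woc")
  }
  tibble::tibble(method = "wisdom_of_crowds", point = mean(g),
                 n_used = length(g))
}

#' Compare size estimates across methods
#'
#' Assembles a comparison table of point estimates from different methods
#' against the expert reference range, flagging estimates outside
#' `[min(lows), max(highs)]` as implausible.
#'
#' @param estimates a data frame with columns `method` and `point` (rows from
#'   [multiplier_estimate()], [wisdom_of_crowds()], or an SS-PSE posterior
#'   median added manually).
#' @param bounds an [expert_bounds()].
#' @return the estimates tibble with reference columns `min_low`, `max_high`
#'   and a logical `implausible` flag.
#' @export
compare_methods <- function(estimates, bounds) {
  estimates <- tibble::as_tibble(estimates)
  if (nrow(estimates) == 0) {
    rlang::abort("no estimates to compare", class = "rdsize_error_compare")
  }
  stopifnot(all(c("method", "point") %in% names(estimates)),
            inherits(bounds, "expert_bounds"))
  dplyr::mutate(
    estimates,
    min_low = min(bounds$lows), max_high = max(bounds$highs),
    implausible = .data$point < .data$min_low | .data$point > .data$max_high)
}
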