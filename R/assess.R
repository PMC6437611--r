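#' Expert benchmark bounds
#'
#' Two local experts each provide a low, median, and high plausible value for
#' the population size. The classification cutpoints are derived from these:
#' max/avg/min of the lows and min/avg/max of the highs.
#'
#' @param lows,medians,highs numeric vectors of length 2 (one value per
#'   expert); each expert's values must satisfy low <= median <= high.
#' @return a list of class `expert_bounds`.
#' @export
expert_bounds <- function(lows, medians, highs) {
  stopifnot(length(lows) == 2, length(medians) == 2, length(highs) == 2)
  if (any(lows > medians) || any(medians > highs)) {
    rlang::abort("each expert needs low <= median <= high",
                 class = "rdsize_error_bounds")
  }
  structure(list(lows = as.numeric(lows), medians = as.numeric(medians),
                 highs = as.numeric(highs)),
            class = "expert_bounds")
}

#' Classify a size estimate against expert benchmarks
#'
#' The posterior median is compared with cutpoints derived from two experts'
#' low/high values: *Great* if it lies between the maximum expert low and the
#' minimum expert high; *Good* if between the average low and average high;
#' *Okay* if between the minimum low and maximum high; otherwise *Bad*.
#' Rules are applied in that order and "between" is inclusive at both
#' endpoints (ties favour the better verdict).
#'
#' @param posterior_median the point estimate.
#' @param bounds an [expert_bounds()].
#' @return a tibble with the verdict (ordered factor Great > Good > Okay >
#'   Bad), the posterior median, and the six derived cutpoints.
#' @examples
#' b <- expert_bounds(lows = c(120, 180), medians = c(200, 250),
#'                    highs = c(250, 400))
#' classify_fit(200, b) # Great: 180 <= 200 <= 250
#' @export
classify_fit <- function(posterior_median, bounds) {
  stopifnot(inherits(bounds, "expert_bounds"), is.finite(posterior_median))
  cl <- list(max_low = max(bounds$lows), avg_low = mean(bounds$lows),
             min_low = min(bounds$lows), min_high = min(bounds$highs),
             avg_high = mean(bounds$highs), max_high = max(bounds$highs))
  m <- posterior_median
  verdict <- if (m >= cl$max_low && m <= cl$min_high) "Great"
  else if (m >= cl$avg_low && m <= cl$avg_high) "Good"
  else if (m >= cl$min_low && m <= cl$max_high) "Okay"
  else "Bad"
  tibble::tibble(
    verdict = factor(verdict, levels = c("Great", "Good", "Okay", "Bad")),
    posterior_median = m,
    max_low = cl$max_low, avg_low = cl$avg_low, min_low = cl$min_low,
    min_high = cl$min_high, avg_high = cl$avg_high, max_high = cl$max_high)
}

#' Bad-fit rule from the published range
#'
#' Published benchmark tables print only the minimum expert low and maximum
#' expert high per population, which determines the Bad/not-Bad split (but
#' not the Great/Good/Okay distinction): a fit is *Bad* when the posterior
#' median falls strictly below the minimum expert low or strictly above the
#' maximum expert high.
#'
#' @param posterior_median the point estimate.
#' @param min_low minimum of the expert lows.
#' @param max_high maximum of the expert highs.
#' @return logical.
#' @examples
#' is_bad_from_range(445, 1500, 9900)  # TRUE
#' is_bad_from_range(3734, 1500, 9900) # FALSE
#' @export
is_bad_from_range <- function(posterior_median, min_low, max_high) {
  stopifnot(all(min_low <= max_high))
  posterior_median < min_low | posterior_median > max_high
}

#' Assess a table of size estimates
#'
#' Applies [is_bad_from_range()] row-wise and aggregates the Bad count and
#' percentage (rounded to a whole percent).
#'
#' @param rows a data frame with columns `label`, `posterior_median`,
#'   `min_low`, `max_high`.
#' @return a list with `rows` (the input plus a logical `bad` column) and
#'   `summary` (tibble with `n`, `n_bad`, `pct_bad`).
#' @export
assess_table <- function(rows) {
  rows <- tibble::as_tibble(rows)
  stopifnot(nrow(rows) >= 1,
            all(c("label", "posterior_median", "min_low", "max_high")
                %in% names(rows)))
  rows <- dplyr::mutate(
    rows, bad = is_bad_from_range(.data$posterior_median, .data$min_low,
                                  .data$max_high))
  list(rows = rows,
       summary = tibble::tibble(
         n = nrow(rows), n_bad = sum(rows$bad),
         pct_bad = round(100 * sum(rows$bad) / nrow(rows))))
}

#' Is a Great verdict attainable?
#'
#' When the experts disagree so much that the maximum expert low exceeds the
#' minimum expert high, the Great range is empty and no estimate can earn it.
#'
#' @param bounds an [expert_bounds()].
#' @return logical: `TRUE` when `max(lows) <= min(highs)`.
#' @export
great_fit_feasible <- function(bounds) {
  stopifnot(inherits(bounds, "expert_bounds"))
  max(bounds$lows) <= min(bounds$highs)
}

#' Degree trend over the enrollment period
#'
#' Least-squares slope of the effective reported degree on the standardised
#' enrollment order, labelled by a two-sided permutation test. Under
#' successive sampling, a large sample fraction depletes the high-visibility
#' members first and produces a *decreasing* trend; a roughly *constant*
#' trend suggests a small sample fraction; an *increasing* trend indicates
#' the recruitment process is not behaving as the model assumes and the size
#' estimate merits caution.
#'
#' @param sample an [rds_sample()].
#' @param n_perm number of permutations (default 2000).
#' @param alpha significance level for the trend label.
#' @return a tibble with `slope` (per sd of enrollment order), `p_value`,
#'   and `trend` (`"decreasing"`, `"constant"`, or `"increasing"`).
#' @export
degree_trend <- function(sample, n_perm = 2000, alpha = 0.05) {
  stopifnot(inherits(sample, "rds_sample"))
  d <- effective_degree(sample)
  keep <- !is.na(d)
  d <- as.numeric(d[keep])
  ord <- sample$enrollment_index[keep]
  if (length(d) < 10) {
    rlang::abort("degree_trend needs at least 10 non-missing degrees",
                 class = "rdsize_error_trend")
  }
  x <- as.numeric(scale(ord))
  if (stats::sd(d) == 0) {
    return(tibble::tibble(slope = 0, p_value = 1, trend = "constant"))
  }
  slope_of <- function(y) sum(x * (y - mean(y))) / sum(x^2)
  obs <- slope_of(d)
  perm <- vapply(seq_len(n_perm), function(i) slope_of(d[sample.int(length(d))]),
                 numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  trend <- if (p > alpha) "constant" else if (obs < 0) "decreasing" else "increasing"
  if (trend == "increasing") {
    rlang::warn(paste0(
      "reported degrees increase over the enrollment period; ",
      "RDS assumptions may be violated and size estimates merit caution"),
      class = "rdsize_warning_increasing_trend")
  }
  tibble::tibble(slope = obs, p_value = p, trend = trend)
}
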