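#' Data behind the posterior plot
#'
#' Returns the values an [autoplot.sspse_fit()] figure draws, so reports and
#' tests can work with numbers rather than rendered pixels.
#'
#' @param fit an `sspse_fit`.
#' @return a list with `posterior` (tibble `N`, `density`), `prior` (tibble
#'   `N`, `density`), `median`, and `ci` (the central 90% interval).
#' @export
posterior_plot_data <- function(fit) {
  stopifnot(inherits(fit, "sspse_fit"))
  draws <- fit$draws$N
  q <- fit$quantiles$N
  if (stats::sd(draws) == 0) {
    post <- tibble::tibble(N = draws[1], density = 1)
  } else {
    dd <- stats::density(draws, from = min(fit$prior$N),
                         to = max(max(draws), stats::quantile(draws, 0.999)))
    post <- tibble::tibble(N = dd$x, density = dd$y)
  }
  step <- if (nrow(fit$prior) > 1) diff(fit$prior$N[1:2]) else 1
  prior <- tibble::tibble(N = fit$prior$N,
                          density = fit$prior$pmf / step)
  list(posterior = post, prior = prior,
       median = q[3], ci = c(q[1], q[5]))
}

#' Plot the posterior distribution of the population size
#'
#' Overlaid prior and posterior densities with the central 90% credible
#' interval shaded and the posterior median marked by a vertical line.
#'
#' @param object an `sspse_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sspse_fit
#' @export
autoplot.sspse_fit <- function(object, ...) {
  pd <- posterior_plot_data(object)
  shade <- dplyr::filter(pd$posterior, .data$N >= pd$ci[1],
                         .data$N <= pd$ci[2])
  ggplot2::ggplot(pd$posterior, ggplot2::aes(x = .data$N, y = .data$density)) +
    ggplot2::geom_line(data = pd$prior, linetype = "dashed",
                       colour = "grey40") +
    ggplot2::geom_area(data = shade, fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = pd$median, colour = "red") +
    ggplot2::labs(
      x = "population size N", y = "density",
      title = paste0("Posterior population size",
                     if (nzchar(object$label)) paste0(": ", object$label)),
      subtitle = sprintf("median %.0f, 90%% CrI [%.0f, %.0f]; dashed = prior",
                         pd$median, pd$ci[1], pd$ci[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.sspse_fit
#' @param fit an `sspse_fit`.
#' @export
plot_posterior <- function(fit, ...) autoplot.sspse_fit(fit, ...)

#' Plot reported degree against enrollment order
#'
#' Scatter of the effective reported degree over the enrollment period with a
#' least-squares trend line, annotated with the permutation-test trend label
#' from [degree_trend()]. Depletion of high-degree participants (a decreasing
#' trend) signals a large sample fraction; an increasing trend signals
#' recruitment dynamics at odds with the model.
#'
#' @param sample an [rds_sample()].
#' @param n_perm permutations for the trend label.
#' @return a ggplot object; the computed trend row is attached as attribute
#'   `"trend"`.
#' @export
plot_enrollment_degree <- function(sample, n_perm = 2000) {
  stopifnot(inherits(sample, "rds_sample"))
  tr <- suppressWarnings(degree_trend(sample, n_perm = n_perm))
  df <- tibble::tibble(order = sample$enrollment_index,
                       degree = effective_degree(sample))
  p <- ggplot2::ggplot(df[!is.na(df$degree), ],
                       ggplot2::aes(x = .data$order, y = .data$degree)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue4") +
    ggplot2::labs(x = "enrollment order", y = "reported degree",
                  title = "Reported degree over the enrollment period",
                  subtitle = sprintf("trend: %s (p = %.3f)",
                                     tr$trend, tr$p_value)) +
    ggplot2::theme_minimal()
  attr(p, "trend") <- tr
  p
}

#' Data behind the multi-year trend plot
#'
#' @param fits named list of `sspse_fit` objects (names are years or labels).
#' @return a list with `shapes` (tibble `year`, `N`, `density`, `source`) and
#'   `medians` (tibble `year`, `median`, `lo90`, `hi90`).
#' @export
trend_plot_data <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  shapes <- purrr::imap_dfr(fits, function(f, yr) {
    draws <- f$draws$N
    post <- if (stats::sd(draws) == 0) {
      tibble::tibble(N = draws[1] + c(-0.5, 0.5), density = c(1, 1))
    } else {
      dd <- stats::density(draws)
      tibble::tibble(N = dd$x, density = dd$y)
    }
    step <- if (nrow(f$prior) > 1) diff(f$prior$N[1:2]) else 1
    dplyr::bind_rows(
      dplyr::mutate(post, source = "posterior"),
      tibble::tibble(N = f$prior$N, density = f$prior$pmf / step,
                     source = "prior"))  |>
      dplyr::mutate(year = yr)
  })
  medians <- purrr::imap_dfr(fits, function(f, yr) {
    q <- f$quantiles$N
    tibble::tibble(year = yr, median = q[3], lo90 = q[1], hi90 = q[5])
  })
  list(shapes = shapes, medians = medians)
}

#' Mirrored prior/posterior trend plot across survey years
#'
#' For each year the prior density is drawn to the left and the posterior
#' density to the right of the year's axis position (a mirrored violin); the
#' posterior medians are connected by a line and the shared prior median is
#' shown as a horizontal dotted line. Year-to-year movement small relative to
#' the posterior spread should not be read as a population trend.
#'
#' @param fits named list of `sspse_fit` objects, one per year.
#' @param width half-width of each mirrored shape in year units.
#' @return a ggplot object.
#' @export
plot_size_trend <- function(fits, width = 0.35) {
  pd <- trend_plot_data(fits)
  yrs <- names(fits)
  pos <- stats::setNames(seq_along(yrs), yrs)
  shapes <- dplyr::group_by(pd$shapes, .data$year, .data$source)  |>
    dplyr::mutate(
      offset = .data$density / max(.data$density) * width *
        ifelse(.data$source == "prior", -1, 1),
      x = pos[.data$year] + .data$offset)  |>
    dplyr::arrange(.data$N, .by_group = TRUE)  |>
    # anchor each shape to the year's axis so the polygon closes cleanly
    dplyr::group_modify(function(g, key) {
      anchor <- g[c(1, nrow(g)), ]
      anchor$x <- pos[[key$year]]
      dplyr::bind_rows(anchor[1, ], g, anchor[2, ])
    })  |>
    dplyr::ungroup()
  med <- dplyr::mutate(pd$medians, x = pos[.data$year])
  prior_median <- fits[[1]]$prior_spec$median_N
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = shapes,
      ggplot2::aes(x = .data$x, y = .data$N,
                   group = interaction(.data$year, .data$source),
                   fill = .data$source),
      alpha = 0.45, colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_line(data = med, ggplot2::aes(x = .data$x, y = .data$median),
                       colour = "red") +
    ggplot2::geom_point(data = med, ggplot2::aes(x = .data$x, y = .data$median),
                        colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = prior_median, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = pos, labels = yrs) +
    ggplot2::scale_fill_manual(values = c(prior = "grey70",
                                          posterior = "steelblue")) +
    ggplot2::labs(x = NULL, y = "population size N",
                  title = "Size estimates across survey years",
                  subtitle = "left shape: prior; right shape: posterior; dotted: shared prior median") +
    ggplot2::theme_minimal()
}
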