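fit_for_plots <- function() {
  st <- sim_study(seed = 12)
  fit_sspse(st$sample, prior_spec(400),
            mcmc_config(burnin = 300, samples = 800, thin = 1, rng_seed = 4))
}

test_that("posterior plot data carries prior, posterior, median and interval", {
  fit <- fit_for_plots()
  pd <- posterior_plot_data(fit)
  expect_equal(pd$median, fit$quantiles$N[3])
  expect_equal(pd$ci, fit$quantiles$N[c(1, 5)])
  # prior overlay integrates to ~1 on the plotted grid
  step <- diff(pd$prior$N[1:2])
  expect_equal(sum(pd$prior$density) * step, 1, tolerance = 1e-6)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("enrollment-degree plot annotates the permutation trend", {
  st <- sim_study(seed = 13)
  p <- plot_enrollment_degree(st$sample, n_perm = 200)
  expect_s3_class(p, "ggplot")
  tr <- attr(p, "trend")
  expect_true(tr$trend %in% c("decreasing", "constant", "increasing"))
  # monotone-decreasing toy data: negative slope, decreasing label
  n <- 30
  toy <- rds_sample(data.frame(
    id = sprintf("P%02d", 1:n), recruiter_id = c(NA, sprintf("P%02d", 1:(n - 1))),
    enrollment_index = 1:n, degree_known = seq(60, 2, by = -2),
    degree_seen = NA_integer_, coupons_issued = n))
  p2 <- plot_enrollment_degree(toy, n_perm = 300)
  tr2 <- attr(p2, "trend")
  expect_lt(tr2$slope, 0)
  expect_equal(tr2$trend, "decreasing")
})

test_that("trend plot data connects per-year medians over mirrored shapes", {
  st <- sim_study(seed = 14)
  mc <- function(s) mcmc_config(burnin = 200, samples = 600, thin = 1,
                                rng_seed = s)
  fits <- list(`2012` = fit_sspse(st$sample, prior_spec(400), mc(1)),
               `2014` = fit_sspse(st$sample, prior_spec(400), mc(2)),
               `2016` = fit_sspse(st$sample, prior_spec(400), mc(3)))
  pd <- trend_plot_data(fits)
  expect_equal(nrow(pd$medians), 3)
  expect_setequal(unique(pd$shapes$source), c("prior", "posterior"))
  # same data, same prior: median line variation stays inside pooled 90% CIs
  expect_true(all(pd$medians$median >= min(pd$medians$lo90) &
                    pd$medians$median <= max(pd$medians$hi90)))
  p <- plot_size_trend(fits)
  expect_s3_class(p, "ggplot")
})
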