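test_that("a point-mass superpopulation yields constant visibilities", {
  cfg <- sim_config(N = 10, mu = 5, sigma = 0, target_n = 5, rng_seed = 1)
  pop <- generate_population(cfg)
  expect_equal(pop$visibility, rep(5L, 10))
})

test_that("generated visibilities match the configured moments", {
  cfg <- sim_config(N = 1e5, mu = 8, sigma = 6, target_n = 10, rng_seed = 2)
  pop <- generate_population(cfg)
  se <- 6 / sqrt(1e5)
  expect_lt(abs(mean(pop$visibility) - 8), 3 * se)
  expect_lt(abs(sd(pop$visibility) - 6), 0.15)
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- sim_config(N = 500, rng_seed = 33)
  expect_identical(generate_population(cfg), generate_population(cfg))
  st1 <- simulate_rds_study(sim_config(N = 300, target_n = 80, rng_seed = 9))
  st2 <- simulate_rds_study(sim_config(N = 300, target_n = 80, rng_seed = 9))
  expect_identical(st1$sample$unit, st2$sample$unit)
  expect_identical(effective_degree(st1$sample), effective_degree(st2$sample))
})

test_that("sampling the whole population is a permutation of it", {
  cfg <- sim_config(N = 30, target_n = 30, n_seeds = 3, coupons = 30,
                    rng_seed = 4)
  st <- simulate_rds_study(cfg)
  expect_setequal(st$sample$unit, 1:30)
  expect_equal(st$sample$enrollment_index, 1:30)
})

test_that("simulated samples satisfy the recruitment-forest invariants", {
  for (seed in 1:3) {
    st <- sim_study(seed = seed)
    s <- st$sample
    expect_s3_class(s, "rds_sample") # construction re-validates everything
    expect_false(any(duplicated(s$unit)))
    seeds <- is.na(s$recruiter_id)
    expect_equal(s$wave[seeds], rep(0L, sum(seeds)))
  }
})

test_that("equal visibilities reduce to simple random sampling (hypergeometric)", {
  # N = 10, n = 4: first-draw identity must be uniform, and per-unit
  # inclusion Binomial(R, 4/10)
  R <- 4000
  cfg <- sim_config(N = 10, mu = 5, sigma = 0, target_n = 4, n_seeds = 1,
                    coupons = 3)
  pop <- generate_population(cfg)
  set.seed(77)
  first <- integer(R)
  incl <- matrix(0L, R, 10)
  for (r in seq_len(R)) {
    s <- simulate_rds(pop, cfg)
    first[r] <- s$unit[1]
    incl[r, s$unit] <- 1L
  }
  expect_gt(chisq.test(tabulate(first, 10))$p.value, 0.01)
  p <- colMeans(incl)
  se <- sqrt(0.4 * 0.6 / R)
  expect_true(all(abs(p - 0.4) < 4.5 * se))
})

test_that("large sample fractions deplete mean visibility over the draw order", {
  # depletion property: mean true visibility of the first enrollment quartile
  # exceeds that of the last, on average over replicates
  set.seed(5)
  cfg <- sim_config(N = 100, target_n = 80, n_seeds = 4, mu = 8, sigma = 6)
  pop <- generate_population(sim_config(N = 100, mu = 8, sigma = 6,
                                        target_n = 80, rng_seed = 11))
  diffs <- replicate(60, {
    s <- suppressWarnings(simulate_rds(pop, cfg))
    q <- ceiling(nrow(s) / 4)
    mean(s$true_visibility[1:q]) - mean(s$true_visibility[(nrow(s) - q + 1):nrow(s)])
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs) / (sd(diffs) / sqrt(length(diffs))), 3) # clearly > 0
})

test_that("a hard bottleneck never reaches the other component", {
  cfg <- sim_config(N = 200, target_n = 150, n_seeds = 3, coupons = 3,
                    n_components = 2, cross_component_rate = 0,
                    seed_component = 1, rng_seed = 21)
  pop <- generate_population(cfg)
  s <- suppressWarnings(simulate_rds(pop, cfg))
  expect_true(all(s$component == 1))
  # and recruitment dies out short of target_n with a warning
  expect_warning(simulate_rds(pop, cfg), class = "rdsize_warning_dieout")
})

test_that("top-k seed mode picks the most visible units", {
  cfg <- sim_config(N = 50, target_n = 20, n_seeds = 3, seed_mode = "top",
                    rng_seed = 3)
  pop <- generate_population(cfg)
  s <- simulate_rds(pop, cfg)
  top3 <- sort(pop$visibility, decreasing = TRUE)[3]
  expect_true(all(s$true_visibility[1:3] >= top3))
})

test_that("measurement error: identity limit, heaping, and CMP mean", {
  expect_equal(apply_measurement_error(c(3L, 7L, 12L), tau = 1, rho = 0),
               c(3L, 7L, 12L))
  expect_equal(
    apply_measurement_error(c(12L, 13L, 18L), tau = 1, rho = 0,
                            heaping_rule = "round5"),
    c(10L, 15L, 20L))
  expect_equal(
    apply_measurement_error(c(14L, 15L, 26L), tau = 1, rho = 0,
                            heaping_rule = "round10"),
    c(10L, 20L, 30L))
  set.seed(8)
  d <- apply_measurement_error(rep(10L, 2e4), tau = 1.5, rho = 0.3)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 15), 3 * se)
  expect_error(apply_measurement_error(1:3, tau = 0),
               class = "rdsize_error_config")
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(N = 50, target_n = 100), class = "rdsize_error_config")
  expect_error(sim_config(mu = 0.5, sigma = 2), class = "rdsize_error_config")
  expect_error(sim_config(cross_component_rate = 1.5))
})

test_that("negative binomial superpopulation matches its moments", {
  cfg <- sim_config(N = 3e4, mu = 8, sigma = 6, family = "negbinom",
                    target_n = 10, rng_seed = 12)
  pop <- generate_population(cfg)
  # zero-truncation shifts the raw negbinom moments slightly upward
  expect_gt(mean(pop$visibility), 8)
  expect_lt(mean(pop$visibility), 9.5)
  expect_true(all(pop$visibility >= 1))
  expect_error(
    generate_population(sim_config(N = 10, mu = 8, sigma = 2,
                                   family = "negbinom", target_n = 5)),
    class = "rdsize_error_config")
})
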