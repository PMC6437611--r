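test_that("classification follows the Great/Good/Okay/Bad rules in order", {
  # identical experts collapse all three ranges
  b <- expert_bounds(c(100, 100), c(200, 200), c(300, 300))
  expect_equal(as.character(classify_fit(150, b)$verdict), "Great")
  expect_equal(as.character(classify_fit(99, b)$verdict), "Bad")
  expect_equal(as.character(classify_fit(100, b)$verdict), "Great") # inclusive
  expect_equal(as.character(classify_fit(300, b)$verdict), "Great")

  # hand-enumerated cutpoints: lows (120, 180), highs (250, 400)
  # max-low 180, avg-low 150, min-low 120; min-high 250, avg-high 325,
  # max-high 400
  b2 <- expert_bounds(c(120, 180), c(200, 250), c(250, 400))
  expect_equal(as.character(classify_fit(200, b2)$verdict), "Great")
  expect_equal(as.character(classify_fit(160, b2)$verdict), "Good")
  expect_equal(as.character(classify_fit(300, b2)$verdict), "Good")
  expect_equal(as.character(classify_fit(130, b2)$verdict), "Okay")
  expect_equal(as.character(classify_fit(390, b2)$verdict), "Okay")
  expect_equal(as.character(classify_fit(110, b2)$verdict), "Bad")
  expect_equal(as.character(classify_fit(450, b2)$verdict), "Bad")
})

test_that("verdicts are monotone in range width and consistent with Bad rule", {
  set.seed(14)
  lv <- c("Great", "Good", "Okay", "Bad")
  for (i in 1:50) {
    lows <- sort(sample(50:150, 2))
    highs <- sort(sample(200:400, 2))
    meds <- pmax(lows, c(160, 170))
    b <- expert_bounds(lows, meds, pmin(pmax(highs, meds), highs + 400))
    m <- sample(30:500, 1)
    v <- classify_fit(m, b)
    # widening every expert range never worsens the verdict
    b_wide <- expert_bounds(lows - 20, meds, b$highs + 50)
    v_wide <- classify_fit(m, b_wide)
    expect_lte(match(as.character(v_wide$verdict), lv),
               match(as.character(v$verdict), lv))
    # Bad verdict coincides with the published-range rule
    expect_equal(is_bad_from_range(m, min(b$lows), max(b$highs)),
                 as.character(v$verdict) == "Bad")
  }
})

test_that("published-range Bad rule reproduces printed assessments", {
  expect_true(is_bad_from_range(445, 1500, 9900))   # well below expert low
  expect_false(is_bad_from_range(3734, 1500, 9900)) # inside the range
  expect_true(is_bad_from_range(666, 123, 339))     # above expert high
})

test_that("assess_table counts and percentage match row-wise rule", {
  t1 <- armenia_table1()
  res <- assess_table(data.frame(
    label = paste(t1$population, t1$city, t1$year),
    posterior_median = t1$q50, min_low = t1$expert_low,
    max_high = t1$expert_high))
  expect_equal(res$summary$n_bad, 6)
  expect_equal(res$summary$pct_bad, 40)
  expect_equal(res$rows$bad, t1$assessment == "Bad")

  one <- assess_table(data.frame(label = "x", posterior_median = 5,
                                 min_low = 10, max_high = 20))
  expect_equal(one$summary$pct_bad, 100)
  none <- assess_table(data.frame(label = "x", posterior_median = 15,
                                  min_low = 10, max_high = 20))
  expect_equal(none$summary$n_bad, 0)
  expect_equal(none$summary$pct_bad, 0)
})

test_that("a Great fit is infeasible when expert ranges do not overlap", {
  expect_false(great_fit_feasible(
    expert_bounds(c(100, 180), c(140, 200), c(150, 300))))
  expect_true(great_fit_feasible(
    expert_bounds(c(100, 100), c(200, 200), c(300, 300))))
})

test_that("degree trend labels monotone, shuffled, and constant data", {
  mk <- function(deg) {
    n <- length(deg)
    rds_sample(data.frame(
      id = sprintf("P%03d", 1:n), recruiter_id = c(NA, sprintf("P%03d", 1:(n - 1))),
      enrollment_index = 1:n, degree_known = deg, degree_seen = deg,
      coupons_issued = n))
  }
  dec <- degree_trend(mk(50:11), n_perm = 500)
  expect_equal(dec$trend, "decreasing")
  expect_lte(dec$p_value, 0.05)

  expect_warning(
    inc <- degree_trend(mk(11:50), n_perm = 500),
    class = "rdsize_warning_increasing_trend")
  expect_equal(inc$trend, "increasing")

  const <- degree_trend(mk(rep(7L, 40)))
  expect_equal(const$trend, "constant")
  expect_equal(const$p_value, 1)

  # i.i.d. shuffled degrees: constant label in >= 90% of replicates
  set.seed(31)
  labs <- replicate(40, {
    degree_trend(mk(sample(rpois(40, 8) + 1L)), n_perm = 300)$trend
  })
  expect_gte(mean(labs == "constant"), 0.9)

  expect_error(degree_trend(mk(rep(7L, 40))[1:5, ] |> rds_sample()),
               class = "rdsize_error_trend")
})

test_that("simulated depletion scenarios drive the trend label", {
  set.seed(9)
  # large sample fraction: decreasing dominates
  labs_dep <- replicate(20, {
    cfg <- sim_config(N = 100, target_n = 80, n_seeds = 4)
    st <- list(population = generate_population(cfg))
    s <- suppressWarnings(simulate_rds(st$population, cfg))
    degree_trend(s, n_perm = 300)$trend
  })
  expect_gt(mean(labs_dep == "decreasing"), 0.5)
  # small sample fraction: constant dominates
  labs_sm <- replicate(20, {
    cfg <- sim_config(N = 2000, target_n = 100, n_seeds = 4)
    s <- suppressWarnings(simulate_rds(generate_population(cfg), cfg))
    suppressWarnings(degree_trend(s, n_perm = 300)$trend)
  })
  expect_gt(mean(labs_sm == "constant"), 0.5)
})
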