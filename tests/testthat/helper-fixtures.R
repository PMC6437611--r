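# Small hand-built samples used across test files.

toy_sample_df <- function() {
  data.frame(
    id = c("A", "B", "C"),
    recruiter_id = c(NA, "A", "A"),
    enrollment_index = 1:3,
    degree_known = c(10L, 5L, 7L),
    degree_seen = c(4L, NA, 7L),
    coupons_issued = 3L)
}

# a moderately sized simulated study with known truth
sim_study <- function(N = 400, target_n = 120, seed = 1, ...) {
  cfg <- sim_config(N = N, target_n = target_n, n_seeds = 4,
                    rng_seed = seed, ...)
  simulate_rds_study(cfg)
}

# exact distribution of W = sum of m iid draws on support 1..3
conv_table <- function(m, probs) {
  v <- 1
  for (r in seq_len(m)) {
    nv <- numeric(length(v) + length(probs))
    for (s in seq_along(v)) {
      for (k in seq_along(probs)) nv[s + k] <- nv[s + k] + v[s] * probs[k]
    }
    v <- nv
  }
  v # v[w + 1] = P(W = w)
}

# exact posterior over N for the tiny discrete case (known theta, u observed)
tiny_exact_posterior <- function(u, probs, maxN, prior = NULL) {
  n <- length(u)
  grid <- n:maxN
  if (is.null(prior)) prior <- rep(1 / length(grid), length(grid))
  post <- vapply(seq_along(grid), function(gi) {
    N <- grid[gi]
    m <- N - n
    EW <- if (m == 0) exp(ss_log_likelihood(u, 0)) else {
      pw <- conv_table(m, probs)
      sum(vapply(seq_along(pw) - 1, function(w) {
        if (pw[w + 1] > 0) pw[w + 1] * exp(ss_log_likelihood(u, w)) else 0
      }, numeric(1)))
    }
    prior[gi] * exp(lgamma(N + 1) - lgamma(N - n + 1)) * EW
  }, numeric(1))
  post / sum(post)
}

# all permutations of a vector (tiny inputs only)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
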