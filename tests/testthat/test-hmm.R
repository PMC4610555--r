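test_that("left-right transition matrices follow the duration formula", {
  expect_equal(build_left_right_A(1, 5), matrix(1, 1, 1))
  expect_equal(build_left_right_A(2, c(10, 10)),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2))
  A <- build_left_right_A(6, c(3, 7, 11, 4, 9, 20))
  expect_equal(rowSums(A), rep(1, 6))
  expect_equal(diag(A), 1 - 1 / c(3, 7, 11, 4, 9, 20))
  # only self and next-state (cyclic) entries are populated
  off <- A; diag(off) <- 0
  for (i in 1:6) {
    expect_equal(sum(off[i, ] > 0), 1)
    expect_gt(off[i, i %% 6 + 1], 0)
  }
  expect_error(build_left_right_A(3, 0.5), "durations")

  acyc <- build_left_right_A(3, 5, cyclic = FALSE)
  expect_equal(acyc[3, ], c(0, 0, 1))
})

test_that("the uniform initial distribution spreads mass equally", {
  expect_equal(uniform_pi(2), c(0.5, 0.5))
  expect_equal(uniform_pi(6), rep(1 / 6, 6))
  for (n in 1:8) expect_equal(sum(uniform_pi(n)), 1)
})

test_that("hmm_params validates stochasticity and structural zeros", {
  p <- toy_hmm(3)
  expect_silent(validate_hmm_params(p))
  bad <- p; bad$A[1, ] <- c(0.5, 0.4, 0.2)
  expect_error(validate_hmm_params(bad), "sum to 1")
  bad2 <- p; bad2$sigma[2] <- 0
  expect_error(validate_hmm_params(bad2), "sigma")
  bad3 <- p; bad3$A <- matrix(1 / 3, 3, 3)
  expect_error(validate_hmm_params(bad3), "structural")
})

test_that("Viterbi equals exhaustive path enumeration on small instances", {
  set.seed(11)
  for (rep_i in 1:5) {
    A <- matrix(stats::runif(4) + 0.1, 2, 2)
    A <- A / rowSums(A)
    p <- hmm_params(A = A, pi = c(0.6, 0.4), mu = c(0, 2), sigma = c(1, 1.5))
    obs <- stats::rnorm(8, sample(c(0, 2), 8, replace = TRUE))
    dec <- viterbi(p, obs)
    bf <- brute_force_viterbi(p, obs)
    expect_identical(dec$states, bf$path)
    expect_equal(dec$log_joint, bf$log_joint, tolerance = 1e-10)
  }
})

test_that("Viterbi recovers a noise-free state script and degenerate cases", {
  p <- toy_hmm(3, sep = 10, sd = 1, d = 10)
  script <- rep(rep(1:3, 4), each = 10)
  obs <- p$mu[script, 1]
  dec <- viterbi(p, obs)
  expect_identical(dec$states, as.integer(script))
  expect_equal(rowSums(dec$gamma), rep(1, length(obs)), tolerance = 1e-8)

  one <- hmm_params(A = matrix(1, 1, 1), pi = 1, mu = 0, sigma = 1)
  expect_true(all(viterbi(one, stats::rnorm(20))$states == 1L))

  expect_error(viterbi(p, c(1, NA, 3)), "finite")
  # far-out observations are floored, never NaN
  dec2 <- viterbi(p, c(1e6, -1e6, 5))
  expect_false(any(is.na(dec2$states)))
  expect_false(any(is.nan(dec2$gamma)))
})

test_that("the Viterbi path beats random valid paths", {
  set.seed(7)
  p <- toy_hmm(4, sep = 3, sd = 2, d = 8)
  obs <- simulate_hmm(p, 60)$obs
  dec <- viterbi(p, obs)
  for (k in 1:1000) {
    rnd <- integer(60)
    rnd[1] <- sample.int(4, 1)
    for (t in 2:60)
      rnd[t] <- sample.int(4, 1, prob = p$A[rnd[t - 1], ] + 1e-12)
    expect_gte(dec$log_joint, path_logjoint(p, rnd, obs) - 1e-9)
  }
})

test_that("Baum-Welch log-likelihood is non-decreasing and respects structure", {
  set.seed(21)
  truth <- toy_hmm(4, sep = 6, sd = 1.5, d = 12)
  obs <- simulate_hmm(truth, 800)$obs
  init <- toy_hmm(4, sep = 5, sd = 3, d = 9)

  expect_identical(baum_welch(init, obs, max_iter = 0)$params$mu, init$mu)

  fit <- baum_welch(init, obs, max_iter = 40)
  expect_true(all(diff(fit$loglik) >= -1e-8 * abs(fit$loglik[-1])))
  validate_hmm_params(fit$params, tol = 1e-8)
  expect_true(all(fit$params$A[init$struct_zero] == 0))

  # multiple sequences are pooled
  fit2 <- baum_welch(init, list(obs[1:400], obs[401:800]), max_iter = 5)
  expect_length(fit2$loglik, 5)

  expect_error(baum_welch(init, list()), "empty")
  expect_error(baum_welch(init, c(1, NaN, 2)), "finite")
})

test_that("Baum-Welch recovers emission means from simulated data", {
  set.seed(33)
  truth <- hmm_params(A = build_left_right_A(4, c(15, 20, 12, 25)),
                      pi = uniform_pi(4),
                      mu = c(-40, 0, 60, 140), sigma = c(8, 8, 10, 12))
  obs <- simulate_hmm(truth, 5000)$obs
  init <- hmm_params(A = build_left_right_A(4, rep(15, 4)), pi = uniform_pi(4),
                     mu = c(-60, 10, 40, 170), sigma = rep(25, 4))
  fit <- baum_welch(init, obs, max_iter = 100)$params
  # align states to truth by nearest mean, then require 5% relative accuracy
  per <- apply(abs(outer(fit$mu[, 1], truth$mu[, 1], "-")), 2, which.min)
  expect_equal(sort(per), 1:4)
  rel_err <- abs(fit$mu[per, 1] - truth$mu[, 1]) /
    pmax(abs(truth$mu[, 1]), 20)
  expect_true(all(rel_err < 0.05))
})

test_that("fixed-lag decoding converges to the offline path", {
  set.seed(5)
  p <- toy_hmm(4, sep = 12, sd = 1.5, d = 15)
  obs <- simulate_hmm(p, 400)$obs
  off <- viterbi(p, obs)

  expect_identical(fixed_lag_viterbi(p, obs, 400)$states, off$states)
  expect_identical(fixed_lag_viterbi(p, obs, 1000)$states, off$states)

  lag5 <- fixed_lag_viterbi(p, obs, 5)
  expect_gte(mean(lag5$states == off$states), 0.99)

  expect_error(fixed_lag_viterbi(p, obs, 0), "lag")
})

test_that("model JSON files round-trip losslessly", {
  p <- toy_hmm(4, sep = 7, sd = 2, d = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_hmm_json(p, path, metadata = list(code = "SST_4P_ft_SC", fs_hz = 50))
  q <- read_hmm_json(path)
  expect_equal(q$A, p$A)
  expect_equal(q$mu, p$mu)
  expect_equal(q$sigma, p$sigma)
  expect_equal(q$pi, p$pi)
  expect_equal(attr(q, "metadata")$code, "SST_4P_ft_SC")
})
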