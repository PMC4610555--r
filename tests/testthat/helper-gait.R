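# Shared fixtures, all built in code.

# A clean (no jitter, no noise) trial: the generator's script is then an exact
# ground truth for every partitioning model.
clean_trial <- function(duration_s = 20, repetition = 1, seed = 1,
                        template = gait_template(), ...) {
  set.seed(seed)
  generate_trial(template, duration_s = duration_s,
                 timing_jitter_sd = 0, amp_jitter_sd = 0, noise_sd = 0,
                 repetition = repetition, ...)
}

noisy_trial <- function(duration_s = 30, repetition = 1, seed = 1, ...) {
  set.seed(seed)
  generate_trial(gait_template(), duration_s = duration_s,
                 repetition = repetition, ...)
}

trial_ref <- function(trial, model_id)
  partition_trial(trial$footswitch, model_id,
                  target_fs_hz = trial$gyro_foot$fs_hz,
                  t_grid = signal_times(trial$gyro_foot))

# Small, well-separated HMM for decoder tests.
toy_hmm <- function(n = 2, sep = 10, sd = 1, d = 10) {
  hmm_params(A = build_left_right_A(n, d), pi = uniform_pi(n),
             mu = seq(0, by = sep, length.out = n), sigma = rep(sd, n))
}

# Brute-force joint log-probability of one path.
path_logjoint <- function(p, path, obs) {
  lp <- log(p$pi[path[1]]) + stats::dnorm(obs[1], p$mu[path[1], 1],
                                          p$sigma[path[1], 1], log = TRUE)
  for (t in seq_along(obs)[-1])
    lp <- lp + log(p$A[path[t - 1], path[t]]) +
      stats::dnorm(obs[t], p$mu[path[t], 1], p$sigma[path[t], 1], log = TRUE)
  lp
}

# Exhaustive best path over all n^T assignments.
brute_force_viterbi <- function(p, obs) {
  n <- p$n_states
  T_ <- length(obs)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  lps <- apply(grid, 1, function(path) path_logjoint(p, path, obs))
  list(path = as.integer(grid[which.max(lps), ]), log_joint = max(lps))
}
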