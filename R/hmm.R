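#' Continuous-emission HMM parameter set
#'
#' The full parameter set of one gait-phase classifier: transition matrix `A`
#' (left-right, cyclic), initial distribution `pi`, and per-state Gaussian
#' mixture emissions with weights `w`, means `mu` and standard deviations
#' `sigma` (deg/s). Entries of `A` that are exactly zero at construction are
#' treated as structural zeros and stay zero through training.
#'
#' @param A n x n row-stochastic transition matrix.
#' @param pi Length-n initial distribution.
#' @param mu,sigma n x n_mix matrices (vectors accepted for n_mix = 1).
#' @param w n x n_mix mixture-weight matrix; default a single degenerate
#'   component per state.
#' @param phase_labels Optional character vector of length n.
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(A, pi, mu, sigma, w = NULL, phase_labels = NULL) {
  A <- as.matrix(A)
  n <- nrow(A)
  mu <- matrix(mu, nrow = n)
  sigma <- matrix(sigma, nrow = n)
  if (is.null(w)) w <- matrix(1, n, ncol(mu)) / ncol(mu)
  w <- matrix(w, nrow = n)
  obj <- structure(list(n_states = n, A = A, pi = as.numeric(pi),
                        n_mix = ncol(mu), w = w, mu = mu, sigma = sigma,
                        struct_zero = A == 0,
                        phase_labels = phase_labels),
                   class = "hmm_params")
  validate_hmm_params(obj)
  obj
}

#' Validate an `hmm_params` object
#' @param p An `hmm_params`.
#' @param tol Stochasticity tolerance. Default 1e-10.
#' @return Invisibly `p`; stops on violation.
#' @export
validate_hmm_params <- function(p, tol = 1e-10) {
  n <- p$n_states
  stopifnot(nrow(p$A) == n, ncol(p$A) == n, length(p$pi) == n)
  if (any(abs(rowSums(p$A) - 1) > tol)) stop("hmm_params: rows of A must sum to 1")
  if (abs(sum(p$pi) - 1) > tol) stop("hmm_params: pi must sum to 1")
  if (any(abs(rowSums(p$w) - 1) > tol)) stop("hmm_params: rows of w must sum to 1")
  if (any(p$A < 0) || any(p$pi < 0) || any(p$w < 0))
    stop("hmm_params: probabilities must be nonnegative")
  if (any(p$sigma <= 0)) stop("hmm_params: all sigma must be > 0")
  if (any(p$A[p$struct_zero] != 0)) stop("hmm_params: structural zeros violated")
  invisible(p)
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> %d states, %d mixture(s)/state%s\n", x$n_states, x$n_mix,
              if (!is.null(x$phase_labels))
                paste0(" [", paste(x$phase_labels, collapse = " "), "]") else ""))
  cat("  state means (deg/s):", sprintf("%.1f", rowSums(x$w * x$mu)), "\n")
  invisible(x)
}

#' Left-right (cyclic) transition matrix from expected phase durations
#'
#' Self-transition probability of state i is `1 - 1/d_i` and the step to the
#' next state `1/d_i`, where `d_i` is the expected duration in samples; the
#' last state wraps to the first when `cyclic`, reflecting continuous treadmill
#' walking over many cycles.
#'
#' @param n_states Number of states (>= 1).
#' @param expected_durations_samples Length-n (or scalar) expected durations,
#'   each >= 1 sample.
#' @param cyclic Wrap the last state to the first? Default TRUE.
#' @return n x n row-stochastic matrix with only self/next entries nonzero.
#' @export
build_left_right_A <- function(n_states, expected_durations_samples, cyclic = TRUE) {
  stopifnot(n_states >= 1)
  d <- rep_len(as.numeric(expected_durations_samples), n_states)
  if (any(d < 1)) stop("build_left_right_A: durations must be >= 1 sample")
  A <- matrix(0, n_states, n_states)
  if (n_states == 1L) { A[1, 1] <- 1; return(A) }
  for (i in seq_len(n_states)) {
    A[i, i] <- 1 - 1 / d[i]
    j <- if (i < n_states) i + 1L else if (cyclic) 1L else i
    A[i, j] <- A[i, j] + 1 / d[i]
  }
  A
}

#' Uniform initial state distribution
#' @param n_states Number of states (>= 1).
#' @return Length-n vector of `1/n` (the initial phase is unknown).
#' @export
uniform_pi <- function(n_states) {
  stopifnot(n_states >= 1)
  rep(1 / n_states, n_states)
}

# Per-sample emission log-densities under each state's Gaussian mixture.
# Returns a length(obs) x n_states matrix.
emission_loglik <- function(p, obs) {
  T_ <- length(obs)
  logB <- matrix(-Inf, T_, p$n_states)
  for (j in seq_len(p$n_states)) {
    comp <- vapply(seq_len(p$n_mix), function(k)
      log(p$w[j, k] + 1e-300) +
        stats::dnorm(obs, p$mu[j, k], p$sigma[j, k], log = TRUE),
      numeric(T_))
    comp <- matrix(comp, nrow = T_)
    m <- apply(comp, 1, max)
    logB[, j] <- m + log(rowSums(exp(comp - m)))
  }
  pmax(logB, log(1e-300))
}

safe_log <- function(x) log(pmax(x, 1e-300))

check_obs <- function(obs) {
  if (length(obs) == 0L) stop("empty observation sequence")
  if (any(is.na(obs)) || any(!is.finite(obs)))
    stop("observations must be finite and non-NA")
  as.numeric(obs)
}

#' Baum-Welch (EM) training of a continuous HMM
#'
#' Maximum-likelihood re-estimation of `A`, `pi`, `w`, `mu`, `sigma` from one
#' or more observation sequences. Structural zeros of `A` are preserved, every
#' per-iteration total log-likelihood is non-decreasing, and variances are
#' clamped to a floor so that no state collapses onto a single sample.
#'
#' @param init An `hmm_params` starting point.
#' @param sequences A numeric vector or a list of numeric vectors (deg/s).
#' @param tol Relative log-likelihood change below which iteration stops.
#'   Default 1e-6.
#' @param max_iter Maximum EM iterations. Default 100 (0 returns `init`).
#' @param var_floor Variance floor: a scalar, or a length-n vector giving a
#'   per-state floor. Default `1e-4 * var(unlist(sequences))`.
#' @param update_pi Re-estimate the initial distribution? Default TRUE.
#' @return List with `params` (trained `hmm_params`) and `loglik` (per-
#'   iteration trace, one value per completed E-step).
#' @export
baum_welch <- function(init, sequences, tol = 1e-6, max_iter = 100,
                       var_floor = NULL, update_pi = TRUE) {
  if (is.numeric(sequences)) sequences <- list(sequences)
  if (length(sequences) == 0L) stop("baum_welch: empty sequence set")
  sequences <- lapply(sequences, check_obs)
  if (any(vapply(sequences, length, integer(1)) < init$n_states))
    stop("baum_welch: every sequence must be at least n_states long")
  if (is.null(var_floor))
    var_floor <- 1e-4 * stats::var(unlist(sequences))
  if (!length(var_floor) %in% c(1L, init$n_states))
    stop("baum_welch: var_floor must be scalar or one value per state")
  var_floor <- matrix(pmax(var_floor, 1e-12), init$n_states, init$n_mix)

  p <- init
  p$sigma <- pmax(p$sigma, sqrt(var_floor))
  trace <- numeric(0)
  if (max_iter == 0) return(list(params = p, loglik = trace))

  n <- p$n_states
  for (iter in seq_len(max_iter)) {
    logA <- safe_log(p$A)
    logA[p$struct_zero] <- -Inf
    logpi <- safe_log(p$pi)

    ll <- 0
    xi_tot <- matrix(0, n, n)
    gamma1 <- numeric(n)
    r_sum <- matrix(0, n, p$n_mix)          # sum_t r[t,j,k]
    r_obs <- matrix(0, n, p$n_mix)          # sum_t r * o_t
    r_obs2 <- matrix(0, n, p$n_mix)         # sum_t r * o_t^2
    gamma_sum <- numeric(n)

    for (obs in sequences) {
      logB <- emission_loglik(p, obs)
      fb <- hmm_forward_backward_cpp(logpi, logA, logB)
      ll <- ll + fb$loglik
      xi_tot <- xi_tot + fb$xi_sum
      gamma1 <- gamma1 + fb$gamma[1, ]
      gamma_sum <- gamma_sum + colSums(fb$gamma)
      for (j in seq_len(n)) {
        # per-component responsibilities within state j
        compd <- vapply(seq_len(p$n_mix), function(k)
          p$w[j, k] * stats::dnorm(obs, p$mu[j, k], p$sigma[j, k]),
          numeric(length(obs)))
        compd <- matrix(compd, nrow = length(obs))
        den <- rowSums(compd)
        den[den <= 0] <- 1e-300
        r <- fb$gamma[, j] * compd / den
        r_sum[j, ] <- r_sum[j, ] + colSums(r)
        r_obs[j, ] <- r_obs[j, ] + colSums(r * obs)
        r_obs2[j, ] <- r_obs2[j, ] + colSums(r * obs^2)
      }
    }
    trace <- c(trace, ll)

    # M-step
    A_new <- xi_tot
    A_new[p$struct_zero] <- 0
    rs <- rowSums(A_new)
    for (i in seq_len(n))
      A_new[i, ] <- if (rs[i] > 0) A_new[i, ] / rs[i] else p$A[i, ]
    p$A <- A_new
    if (update_pi) p$pi <- gamma1 / sum(gamma1)
    ok <- r_sum > 1e-12
    p$mu[ok] <- r_obs[ok] / r_sum[ok]
    v <- p$sigma^2
    v[ok] <- r_obs2[ok] / r_sum[ok] - p$mu[ok]^2
    p$sigma <- sqrt(pmax(v, var_floor))
    w_new <- r_sum / pmax(gamma_sum, 1e-300)
    p$w <- w_new / rowSums(w_new)

    if (iter > 1) {
      prev <- trace[iter - 1]
      if (abs(ll - prev) < tol * abs(prev)) break
    }
  }
  validate_hmm_params(p, tol = 1e-8)
  list(params = p, loglik = trace)
}

#' Viterbi decoding with state posteriors
#'
#' Exact offline maximum a posteriori path in log space, plus the per-sample
#' state posteriors `gamma` from the forward-backward recursion on the same
#' observations. All recursions are log-scaled; an observation that is
#' improbable under every state is floored, never NaN.
#'
#' @param params An `hmm_params`.
#' @param obs Numeric observation vector (finite).
#' @return A list of class `decode_result`: `states` (1-based indices),
#'   `gamma` (T x n, rows sum to 1), `loglik` (sequence log-likelihood) and
#'   `log_joint` (log joint probability of the returned path).
#' @export
viterbi <- function(params, obs) {
  obs <- check_obs(obs)
  validate_hmm_params(params, tol = 1e-8)
  logB <- emission_loglik(params, obs)
  logA <- safe_log(params$A); logA[params$struct_zero] <- -Inf
  logpi <- safe_log(params$pi)
  vit <- hmm_viterbi_cpp(logpi, logA, logB)
  fb <- hmm_forward_backward_cpp(logpi, logA, logB)
  structure(list(states = as.integer(vit$path), gamma = fb$gamma,
                 loglik = fb$loglik, log_joint = vit$log_joint),
            class = "decode_result")
}

#' Fixed-lag (online) Viterbi decoding
#'
#' Emits, at each step, the best-path state `lag` samples in the past; the
#' trailing `lag` samples are resolved from the final best path, so
#' `lag >= length(obs)` reproduces the offline Viterbi path exactly.
#'
#' @inheritParams viterbi
#' @param lag_samples Decision delay in samples (>= 1).
#' @return A `decode_result` (gamma and loglik from forward-backward).
#' @export
fixed_lag_viterbi <- function(params, obs, lag_samples) {
  if (lag_samples < 1) stop("fixed_lag_viterbi: lag must be >= 1")
  obs <- check_obs(obs)
  logB <- emission_loglik(params, obs)
  logA <- safe_log(params$A); logA[params$struct_zero] <- -Inf
  logpi <- safe_log(params$pi)
  path <- hmm_fixed_lag_viterbi_cpp(logpi, logA, logB, as.integer(lag_samples))
  fb <- hmm_forward_backward_cpp(logpi, logA, logB)
  structure(list(states = as.integer(path), gamma = fb$gamma,
                 loglik = fb$loglik, log_joint = NA_real_),
            class = "decode_result")
}

#' Simulate observations from an HMM
#'
#' Draws a state path from (`pi`, `A`) and Gaussian-mixture emissions per
#' state. Used for simulate-then-fit checks of the training code.
#'
#' @param params An `hmm_params`.
#' @param n_samples Sequence length.
#' @return List with `states` and `obs`.
#' @export
simulate_hmm <- function(params, n_samples) {
  n <- params$n_states
  states <- integer(n_samples)
  states[1] <- sample.int(n, 1, prob = params$pi)
  for (t in seq_len(n_samples)[-1])
    states[t] <- sample.int(n, 1, prob = params$A[states[t - 1], ])
  comp <- vapply(states, function(s) sample.int(params$n_mix, 1, prob = params$w[s, ]),
                 integer(1))
  obs <- stats::rnorm(n_samples,
                      params$mu[cbind(states, comp)],
                      params$sigma[cbind(states, comp)])
  list(states = states, obs = obs)
}

# ---- model JSON I/O ---------------------------------------------------------

#' Write / read an HMM model file (JSON)
#'
#' The file stores `n_states`, `phase_labels`, `A`, `pi`, `w`, `mu`, `sigma`
#' and a free-form `metadata` list (classifier code, training procedure,
#' sampling rate, filter settings); values round-trip losslessly.
#'
#' @param params An `hmm_params`.
#' @param path Output path.
#' @param metadata Optional list.
#' @return Invisibly, `path`.
#' @export
write_hmm_json <- function(params, path, metadata = list()) {
  jsonlite::write_json(
    list(n_states = params$n_states, phase_labels = params$phase_labels,
         A = params$A, pi = params$pi, w = params$w, mu = params$mu,
         sigma = params$sigma, metadata = metadata),
    path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- hmm_params(A = x$A, pi = x$pi, mu = x$mu, sigma = x$sigma, w = x$w,
                  phase_labels = x$phase_labels)
  attr(p, "metadata") <- x$metadata
  p
}
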