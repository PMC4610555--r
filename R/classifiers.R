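#' Scalar gait-phase classifier
#'
#' One HMM decoding one segment's sagittal angular velocity into the phases of
#' a gait model.
#'
#' @param signal_source `"ft"` (foot) or `"sh"` (shank).
#' @param model_id `"2P"`, `"4P"` or `"6P"`.
#' @param params An `hmm_params` whose state count equals the model's phase
#'   count, states ordered as the model's phases.
#' @param meta Free-form training metadata list.
#' @return An object of class `scalar_classifier`.
#' @export
scalar_classifier <- function(signal_source = c("ft", "sh"), model_id, params,
                              meta = list()) {
  signal_source <- match.arg(signal_source)
  model <- phase_model(model_id)
  if (params$n_states != length(model$phases))
    stop("scalar_classifier: params.n_states must equal the model phase count")
  params$phase_labels <- model$phases
  structure(list(signal_source = signal_source, model_id = model$model_id,
                 params = params, meta = meta),
            class = "scalar_classifier")
}

#' @export
print.scalar_classifier <- function(x, ...) {
  cat(sprintf("<scalar_classifier> %s %s (%s)\n", x$model_id, x$signal_source,
              if (length(x$meta)) paste(names(x$meta), unlist(lapply(x$meta, format)),
                                        sep = "=", collapse = " ") else "untagged"))
  invisible(x)
}

segment_of <- function(signal_source) c(ft = "foot", sh = "shank")[[signal_source]]

#' Decode a gyro signal with a scalar classifier
#'
#' @param clf A `scalar_classifier`.
#' @param gyro A `gyro_signal` whose segment matches the classifier's source
#'   (foot for `ft`, shank for `sh`); expected already low-pass filtered.
#' @param decoder `"viterbi"` (offline, default) or `"fixed_lag"`.
#' @param lag_samples Lag for the fixed-lag decoder.
#' @return List with `sequence` (a predicted `phase_sequence` at the gyro
#'   rate) and `gamma` (T x n state posteriors).
#' @export
classify_scalar <- function(clf, gyro, decoder = c("viterbi", "fixed_lag"),
                            lag_samples = 25) {
  decoder <- match.arg(decoder)
  stopifnot(inherits(clf, "scalar_classifier"), inherits(gyro, "gyro_signal"))
  if (gyro$segment != segment_of(clf$signal_source))
    stop(sprintf("classify_scalar: classifier expects %s but gyro segment is %s",
                 segment_of(clf$signal_source), gyro$segment))
  dec <- if (decoder == "viterbi") viterbi(clf$params, gyro$values)
         else fixed_lag_viterbi(clf$params, gyro$values, lag_samples)
  list(sequence = phase_sequence(dec$states, clf$model_id, fs_hz = gyro$fs_hz,
                                 source = "predicted", t0 = gyro$t0),
       gamma = dec$gamma)
}

#' Fusion transition matrix (right-left-right)
#'
#' Transition structure of the distributed classifier: each phase may stay,
#' advance one phase, or step back one phase (to correct a premature member
#' transition), cyclically.
#'
#' @param n_states Number of phases (>= 2).
#' @param stay_prob Self-transition probability in (0, 1). Default 0.9;
#'   forward and backward steps share the remainder equally.
#' @return n x n row-stochastic matrix, zero outside the cyclic tridiagonal.
#' @export
build_A_dc <- function(n_states, stay_prob = 0.9) {
  if (n_states < 2) stop("build_A_dc: n_states must be >= 2")
  if (stay_prob <= 0 || stay_prob >= 1) stop("build_A_dc: stay_prob must be in (0,1)")
  A <- matrix(0, n_states, n_states)
  step <- (1 - stay_prob) / 2
  for (i in seq_len(n_states)) {
    A[i, i] <- A[i, i] + stay_prob
    A[i, (i %% n_states) + 1L] <- A[i, (i %% n_states) + 1L] + step
    A[i, ((i - 2L) %% n_states) + 1L] <- A[i, ((i - 2L) %% n_states) + 1L] + step
  }
  A
}

#' Distributed (two-signal) gait-phase classifier
#'
#' Weighted hierarchical fusion of a foot and a shank scalar classifier
#' sharing one phase model: per-sample state posteriors of the members are
#' combined convexly and the fused scores decoded through a right-left-right
#' transition matrix.
#'
#' @param member_ft,member_sh Foot/shank `scalar_classifier`s with a common
#'   `model_id`.
#' @param weights Length-2 nonnegative member weights (normalized to sum 1).
#' @param A_dc Fusion transition matrix; default [build_A_dc()] at the shared
#'   phase count.
#' @param stay_prob Used when `A_dc` is not supplied.
#' @return An object of class `distributed_classifier`.
#' @export
distributed_classifier <- function(member_ft, member_sh, weights = c(0.5, 0.5),
                                   A_dc = NULL, stay_prob = 0.9) {
  stopifnot(inherits(member_ft, "scalar_classifier"),
            inherits(member_sh, "scalar_classifier"))
  if (member_ft$signal_source != "ft" || member_sh$signal_source != "sh")
    stop("distributed_classifier: members must be an ft and an sh classifier")
  if (member_ft$model_id != member_sh$model_id)
    stop("distributed_classifier: members must share model_id")
  if (length(weights) != 2 || any(weights < 0) || sum(weights) <= 0)
    stop("distributed_classifier: weights must be two nonnegative values")
  n <- member_ft$params$n_states
  if (is.null(A_dc)) A_dc <- build_A_dc(n, stay_prob)
  if (any(abs(rowSums(A_dc) - 1) > 1e-10)) stop("distributed_classifier: A_dc not row-stochastic")
  structure(list(members = list(ft = member_ft, sh = member_sh),
                 model_id = member_ft$model_id,
                 weights = weights / sum(weights), A_dc = A_dc),
            class = "distributed_classifier")
}

#' @export
print.distributed_classifier <- function(x, ...) {
  cat(sprintf("<distributed_classifier> %s ft+sh, weights %.2f/%.2f\n",
              x$model_id, x$weights[1], x$weights[2]))
  invisible(x)
}

#' Decode foot and shank signals with a distributed classifier
#'
#' Each member produces per-sample state posteriors; the fused score
#' `s_j(t) = sum_k weight_k * gamma_kj(t)` is normalized per sample and used
#' as the emission likelihood in a Viterbi decode through the fusion matrix
#' `A_dc` (uniform initial distribution).
#'
#' @param dc A `distributed_classifier`.
#' @param gyro_ft,gyro_sh Equal-length, same-rate foot and shank
#'   `gyro_signal`s.
#' @return List with `sequence` (predicted `phase_sequence`) and `scores`
#'   (T x n fused, per-sample-normalized posteriors).
#' @export
classify_distributed <- function(dc, gyro_ft, gyro_sh) {
  stopifnot(inherits(dc, "distributed_classifier"))
  if (length(gyro_ft$values) != length(gyro_sh$values) ||
      abs(gyro_ft$fs_hz - gyro_sh$fs_hz) > 1e-9)
    stop("classify_distributed: inputs must be equal-length and same-rate")
  g_ft <- classify_scalar(dc$members$ft, gyro_ft)$gamma
  g_sh <- classify_scalar(dc$members$sh, gyro_sh)$gamma
  s <- dc$weights[1] * g_ft + dc$weights[2] * g_sh
  s <- s / rowSums(s)
  logA <- safe_log(dc$A_dc); logA[dc$A_dc == 0] <- -Inf
  vit <- hmm_viterbi_cpp(safe_log(uniform_pi(ncol(s))), logA, safe_log(s))
  list(sequence = phase_sequence(as.integer(vit$path), dc$model_id,
                                 fs_hz = gyro_ft$fs_hz, source = "predicted",
                                 t0 = gyro_ft$t0),
       scores = s)
}

#' Write / read a distributed classifier model file (JSON)
#'
#' Embeds both member models, the weights and `A_dc`.
#'
#' @param dc A `distributed_classifier`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dc_json <- function(dc, path) {
  member_js <- function(m)
    list(signal_source = m$signal_source, model_id = m$model_id,
         n_states = m$params$n_states, A = m$params$A, pi = m$params$pi,
         w = m$params$w, mu = m$params$mu, sigma = m$params$sigma,
         metadata = m$meta)
  jsonlite::write_json(list(model_id = dc$model_id, weights = dc$weights,
                            A_dc = dc$A_dc,
                            members = list(ft = member_js(dc$members$ft),
                                           sh = member_js(dc$members$sh))),
                       path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_dc_json
#' @export
read_dc_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  member <- function(m, src)
    scalar_classifier(src, x$model_id,
                      hmm_params(m$A, m$pi, m$mu, m$sigma, m$w),
                      meta = as.list(m$metadata))
  distributed_classifier(member(x$members$ft, "ft"), member(x$members$sh, "sh"),
                         weights = x$weights, A_dc = x$A_dc)
}
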