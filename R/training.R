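#' Study configuration defaults
#'
#' Central knob set shared by the training protocols and the study runner.
#'
#' @param cutoff_hz,filter_order,zero_phase Low-pass filter settings
#'   ([lowpass_filter()]); 15 Hz, order 4, zero-phase.
#' @param L_norm Samples per time-normalized phase occurrence in emission
#'   initialization. Default 100.
#' @param L_cycle Samples per time-normalized gait cycle in the inter-subject
#'   template. Default 200.
#' @param tol_ms Evaluation tolerance window (ms). Default 60.
#' @param refine Run Baum-Welch after supervised initialization? Default TRUE.
#' @param bw_max_iter,bw_tol Baum-Welch stopping rule used by the protocols.
#' @param dc_weighting `"uniform"` or `"performance"` (weights proportional to
#'   `sqrt(2) - G` of each member on its training data).
#' @param stay_prob Self-transition probability of the fusion matrix.
#' @param decoder `"viterbi"` or `"fixed_lag"`; `lag_samples` for the latter.
#' @param spt_cycles Number of concatenated template cycles used to refine the
#'   inter-subject model. Default 10.
#' @return A named list.
#' @export
study_config <- function(cutoff_hz = 15, filter_order = 4, zero_phase = TRUE,
                         L_norm = 100, L_cycle = 200, tol_ms = 60,
                         refine = TRUE, bw_max_iter = 30, bw_tol = 1e-6,
                         dc_weighting = c("uniform", "performance"),
                         stay_prob = 0.9, decoder = c("viterbi", "fixed_lag"),
                         lag_samples = 25, spt_cycles = 10) {
  list(cutoff_hz = cutoff_hz, filter_order = filter_order,
       zero_phase = zero_phase, L_norm = L_norm, L_cycle = L_cycle,
       tol_ms = tol_ms, refine = refine, bw_max_iter = bw_max_iter,
       bw_tol = bw_tol, dc_weighting = match.arg(dc_weighting),
       stay_prob = stay_prob, decoder = match.arg(decoder),
       lag_samples = lag_samples, spt_cycles = spt_cycles)
}

#' The 18 classifier configurations of the factorial study
#'
#' Every combination of training procedure (SST, SPT), gait-phase model
#' (2P, 4P, 6P) and input signal (foot SC, shank SC, foot+shank DC).
#'
#' @return Data.frame with `procedure`, `model_id`, `signal`, `kind`, a
#'   canonical `code` (e.g. `"SPT_4P_ftsh_DC"`) and the compact `short_code`
#'   (e.g. `"S4pPTftshDC"`).
#' @export
enumerate_classifiers <- function() {
  grid <- expand.grid(signal = c("ft", "sh", "ftsh"),
                      model_id = c("2P", "4P", "6P"),
                      procedure = c("SST", "SPT"),
                      stringsAsFactors = FALSE)[, 3:1]
  grid$kind <- ifelse(grid$signal == "ftsh", "DC", "SC")
  grid$code <- paste(grid$procedure, grid$model_id, grid$signal, grid$kind, sep = "_")
  grid$short_code <- sprintf("S%s%s%s%s", tolower(grid$model_id),
                             ifelse(grid$procedure == "SST", "ST", "PT"),
                             grid$signal, grid$kind)
  rownames(grid) <- NULL
  grid
}

#' One classifier configuration
#'
#' @param procedure `"SST"` or `"SPT"`.
#' @param model_id `"2P"`, `"4P"` or `"6P"`.
#' @param signal `"ft"`, `"sh"` or `"ftsh"`.
#' @return A list of class `classifier_spec`; `kind` is `"DC"` iff
#'   `signal == "ftsh"`.
#' @export
classifier_spec <- function(procedure = c("SST", "SPT"),
                            model_id = c("2P", "4P", "6P"),
                            signal = c("ft", "sh", "ftsh")) {
  procedure <- match.arg(procedure)
  model_id <- match.arg(model_id)
  signal <- match.arg(signal)
  kind <- if (signal == "ftsh") "DC" else "SC"
  structure(list(procedure = procedure, model_id = model_id, signal = signal,
                 kind = kind,
                 code = paste(procedure, model_id, signal, kind, sep = "_")),
            class = "classifier_spec")
}

as_classifier_spec <- function(x) {
  if (inherits(x, "classifier_spec")) return(x)
  if (is.character(x) && length(x) == 1L) {
    parts <- strsplit(x, "_", fixed = TRUE)[[1]]
    if (length(parts) != 4L) stop("unrecognized classifier code: ", x)
    return(classifier_spec(parts[1], parts[2], parts[3]))
  }
  classifier_spec(x$procedure, x$model_id, x$signal)
}

resample_linear <- function(x, L) {
  if (length(x) == 1L) return(rep(x, L))
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = L))$y
}

resample_nearest <- function(labels, L)
  labels[pmin(pmax(round(seq(1, length(labels), length.out = L)), 1L),
              length(labels))]

phase_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(phase = r$values, start = ends - r$lengths + 1L, len = r$lengths,
             stringsAsFactors = FALSE)
}

#' Phase-wise emission initialization with time normalization
#'
#' Every occurrence of a phase in the reference labeling is resampled to
#' `L_norm` points by linear interpolation (so long and short occurrences
#' weigh equally), the per-phase mean and standard deviation are computed
#' over the pooled normalized ensemble, and the mean raw duration per phase
#' is retained for the transition-matrix initialization.
#'
#' @param gyro A (filtered) `gyro_signal`.
#' @param ref A reference `phase_sequence` of equal length and rate.
#' @param L_norm Normalization length per occurrence. Default 100.
#' @param var_floor Variance floor; default `1e-4 * var(gyro$values)`.
#' @return List with per-phase `mu`, `sigma` (deg/s), `durations` (samples)
#'   and `L_norm`; entries ordered as the model's phases.
#' @export
init_emissions <- function(gyro, ref, L_norm = 100, var_floor = NULL) {
  stopifnot(inherits(gyro, "gyro_signal"), inherits(ref, "phase_sequence"))
  if (length(gyro$values) != length(ref$labels))
    stop("init_emissions: gyro and reference must have equal length")
  if (is.null(var_floor)) var_floor <- 1e-4 * stats::var(gyro$values)
  var_floor <- max(var_floor, 1e-12)
  phases <- phase_model(ref$model_id)$phases
  runs <- phase_runs(ref$labels)
  mu <- sigma <- dur <- stats::setNames(numeric(length(phases)), phases)
  for (ph in phases) {
    rs <- runs[runs$phase == ph, , drop = FALSE]
    if (!nrow(rs))
      stop(sprintf("init_emissions: phase '%s' absent from reference", ph))
    pooled <- unlist(lapply(seq_len(nrow(rs)), function(k)
      resample_linear(gyro$values[rs$start[k]:(rs$start[k] + rs$len[k] - 1L)],
                      L_norm)))
    mu[ph] <- mean(pooled)
    s <- stats::sd(pooled)
    sigma[ph] <- if (is.na(s)) sqrt(var_floor) else max(s, sqrt(var_floor))
    dur[ph] <- mean(rs$len)
  }
  list(mu = mu, sigma = sigma, durations = dur, L_norm = L_norm)
}

# Supervised initialization + optional Baum-Welch refinement of one scalar
# member on one (filtered) gyro signal and its reference labeling.
fit_scalar_member <- function(model_id, signal_source, gyro_filt, ref, config,
                              meta = list()) {
  n <- length(phase_model(model_id)$phases)
  em <- init_emissions(gyro_filt, ref, L_norm = config$L_norm)
  params <- hmm_params(A = build_left_right_A(n, pmax(em$durations, 1)),
                       pi = uniform_pi(n), mu = em$mu, sigma = em$sigma)
  if (config$refine)
    params <- baum_welch(params, gyro_filt$values, tol = config$bw_tol,
                         max_iter = config$bw_max_iter)$params
  scalar_classifier(signal_source, model_id, params, meta = meta)
}

filter_trial_gyros <- function(trial, config) {
  list(ft = lowpass_filter(trial$gyro_foot, config$cutoff_hz,
                           config$filter_order, config$zero_phase),
       sh = lowpass_filter(trial$gyro_shank, config$cutoff_hz,
                           config$filter_order, config$zero_phase))
}

trial_reference <- function(trial, model_id) {
  partition_trial(trial$footswitch, model_id,
                  target_fs_hz = trial$gyro_foot$fs_hz,
                  t_grid = signal_times(trial$gyro_foot))
}

member_goodness <- function(member, gyro_filt, ref, config) {
  pred <- classify_scalar(member, gyro_filt, decoder = config$decoder,
                          lag_samples = config$lag_samples)$sequence
  evaluate_sequences(pred, ref, config$tol_ms)$g
}

dc_weights_for <- function(members, gyros, ref, config) {
  if (config$dc_weighting == "uniform") return(c(0.5, 0.5))
  g <- c(member_goodness(members$ft, gyros$ft, ref, config),
         member_goodness(members$sh, gyros$sh, ref, config))
  w <- pmax(sqrt(2) - g, 1e-6)
  w / sum(w)
}

#' Subject-specific training (SST)
#'
#' Trains a classifier on a subject's own first repetition of a walking
#' condition: the footswitch-derived reference partitions the filtered
#' angular velocity, phase-wise statistics initialize the emissions and the
#' left-right transition matrix, and Baum-Welch refines the parameters.
#' The second repetition is never read here.
#'
#' @param spec A `classifier_spec` (or code / list) with `procedure = "SST"`.
#' @param trial_rep1 The subject's repetition-1 `gait_trial`.
#' @param config A [study_config()] list.
#' @return A `scalar_classifier` or `distributed_classifier`.
#' @export
train_sst <- function(spec, trial_rep1, config = study_config()) {
  spec <- as_classifier_spec(spec)
  if (spec$procedure != "SST") stop("train_sst: spec procedure must be SST")
  stopifnot(inherits(trial_rep1, "gait_trial"))
  if (trial_rep1$repetition != 1L)
    stop("train_sst: training uses repetition 1 only")
  gyros <- filter_trial_gyros(trial_rep1, config)
  ref <- trial_reference(trial_rep1, spec$model_id)
  meta <- list(procedure = "SST", code = spec$code,
               subject = trial_rep1$subject_id, condition = trial_rep1$condition)
  fit1 <- function(src) fit_scalar_member(spec$model_id, src, gyros[[src]],
                                          ref, config, meta)
  if (spec$kind == "SC") return(fit1(spec$signal))
  members <- list(ft = fit1("ft"), sh = fit1("sh"))
  distributed_classifier(members$ft, members$sh,
                         weights = dc_weights_for(members, gyros, ref, config),
                         stay_prob = config$stay_prob)
}

#' Averaged healthy-gait template for inter-subject training
#'
#' Builds the standardized training waveform for one walking condition: each
#' included typically-developed subject's repetition-1 gait cycles are
#' time-normalized to `L_cycle` samples and averaged within subject, then
#' across subjects; per-point cross-subject dispersion is retained. The
#' evaluated subject can be excluded (leave-one-out); the exclusion is
#' recorded in the returned `included` field for auditing.
#'
#' @param cohort A `gait_cohort`.
#' @param condition Walking condition.
#' @param exclude_subject TD subject id to leave out, or `NULL` (all TD).
#' @param L_cycle Normalized cycle length. Default 200.
#' @param config A [study_config()] list.
#' @return An object of class `spt_template` with the averaged foot/shank
#'   waveforms, per-point cross-subject SDs, majority phase scripts for the
#'   three models, the mean raw cycle duration in samples and the included
#'   subject ids.
#' @export
build_spt_template <- function(cohort, condition, exclude_subject = NULL,
                               L_cycle = 200, config = study_config()) {
  td <- cohort$subjects$subject_id[cohort$subjects$group == "TD"]
  if (!is.null(exclude_subject) && !exclude_subject %in% cohort$subjects$subject_id)
    stop("build_spt_template: exclude_subject not in cohort")
  included <- setdiff(td, exclude_subject)
  if (length(included) < 2L)
    stop("build_spt_template: fewer than 2 TD subjects available for the template")

  per_subject <- lapply(included, function(sid) {
    tr <- get_trial(cohort, sid, condition, 1L)
    if (is.null(tr)) return(NULL)
    gyros <- filter_trial_gyros(tr, config)
    refs <- lapply(c("2P" = "2P", "4P" = "4P", "6P" = "6P"),
                   function(m) trial_reference(tr, m))
    starts <- segment_cycles(refs[["2P"]])
    if (length(starts) < 2L) return(NULL)
    idx <- lapply(seq_len(length(starts) - 1L),
                  function(i) starts[i]:(starts[i + 1L] - 1L))
    foot_mat <- do.call(rbind, lapply(idx, function(ii)
      resample_linear(gyros$ft$values[ii], L_cycle)))
    shank_mat <- do.call(rbind, lapply(idx, function(ii)
      resample_linear(gyros$sh$values[ii], L_cycle)))
    list(
      foot = colMeans(foot_mat), shank = colMeans(shank_mat),
      foot_var = apply(foot_mat, 2, stats::var),
      shank_var = apply(shank_mat, 2, stats::var),
      scripts = lapply(refs, function(r) {
        mat <- do.call(rbind, lapply(idx, function(ii)
          resample_nearest(r$labels[ii], L_cycle)))
        apply(mat, 2, function(col) names(which.max(table(col))))
      }),
      cycle_len = mean(lengths(idx)))
  })
  per_subject <- Filter(Negate(is.null), per_subject)
  if (length(per_subject) < 2L)
    stop("build_spt_template: fewer than 2 subjects contributed usable cycles")

  foot_mat <- do.call(rbind, lapply(per_subject, `[[`, "foot"))
  shank_mat <- do.call(rbind, lapply(per_subject, `[[`, "shank"))
  # dispersion seen by an unseen subject: spread of subject means plus the
  # average within-subject stride-to-stride variance
  foot_sd <- sqrt(apply(foot_mat, 2, stats::var) +
                  colMeans(do.call(rbind, lapply(per_subject, `[[`, "foot_var"))))
  shank_sd <- sqrt(apply(shank_mat, 2, stats::var) +
                   colMeans(do.call(rbind, lapply(per_subject, `[[`, "shank_var"))))
  scripts <- lapply(c("2P" = "2P", "4P" = "4P", "6P" = "6P"), function(m) {
    mat <- do.call(rbind, lapply(per_subject, function(s) s$scripts[[m]]))
    apply(mat, 2, function(col) names(which.max(table(col))))
  })
  structure(list(condition = condition, included = included,
                 L_cycle = L_cycle,
                 foot = colMeans(foot_mat), shank = colMeans(shank_mat),
                 foot_sd = foot_sd, shank_sd = shank_sd,
                 scripts = scripts,
                 mean_cycle_samples = mean(vapply(per_subject, `[[`,
                                                  numeric(1), "cycle_len"))),
            class = "spt_template")
}

#' @export
print.spt_template <- function(x, ...) {
  cat(sprintf("<spt_template> %s: %d TD subjects, cycle ~%.0f samples (L_cycle %d)\n",
              x$condition, length(x$included), x$mean_cycle_samples, x$L_cycle))
  invisible(x)
}

# One scalar member from a template: emissions from the template's phase
# segments, sigma pooling within-phase waveform spread with cross-subject
# dispersion, refined on concatenated template cycles.
fit_spt_member <- function(model_id, signal_source, template, config, meta) {
  wave <- if (signal_source == "ft") template$foot else template$shank
  disp <- if (signal_source == "ft") template$foot_sd else template$shank_sd
  script <- template$scripts[[model_id]]
  phases <- phase_model(model_id)$phases
  var_floor <- max(1e-4 * stats::var(wave), 1e-12)
  mu <- sigma <- dur <- stats::setNames(numeric(length(phases)), phases)
  for (ph in phases) {
    pos <- which(script == ph)
    if (!length(pos))
      stop(sprintf("fit_spt_member: phase '%s' absent from template script", ph))
    mu[ph] <- mean(wave[pos])
    within <- if (length(pos) > 1) stats::var(wave[pos]) else 0
    sigma[ph] <- sqrt(max(within + mean(disp[pos]^2), var_floor))
    dur[ph] <- max(length(pos) / template$L_cycle * template$mean_cycle_samples, 1)
  }
  n <- length(phases)
  params <- hmm_params(A = build_left_right_A(n, dur), pi = uniform_pi(n),
                       mu = mu, sigma = sigma)
  if (config$refine) {
    cyc <- resample_linear(wave, max(round(template$mean_cycle_samples), n))
    # refinement runs on the averaged waveform, whose within-phase variance is
    # far below the spread of unseen subjects; flooring each state's variance
    # at its dispersion-informed initialization keeps the model from
    # overfitting the mean waveform
    params <- baum_welch(params, rep(cyc, config$spt_cycles),
                         tol = config$bw_tol, max_iter = config$bw_max_iter,
                         var_floor = sigma^2)$params
  }
  scalar_classifier(signal_source, model_id, params, meta = meta)
}

#' Standardized-parameter (inter-subject) training (SPT)
#'
#' Trains a classifier from the averaged healthy-gait template of a walking
#' condition rather than from the evaluated subject's own data. For
#' typically-developed subjects the evaluated subject is left out of the
#' template (pass `exclude_subject`); for hemiplegic subjects the template
#' uses all TD subjects (`exclude_subject = NULL`).
#'
#' @inheritParams build_spt_template
#' @param spec A `classifier_spec` with `procedure = "SPT"`.
#' @param template Optional precomputed [build_spt_template()] result.
#' @return A `scalar_classifier` or `distributed_classifier`; training
#'   metadata records the excluded and included subjects.
#' @export
train_spt <- function(spec, cohort, condition, exclude_subject = NULL,
                      config = study_config(), template = NULL) {
  spec <- as_classifier_spec(spec)
  if (spec$procedure != "SPT") stop("train_spt: spec procedure must be SPT")
  if (is.null(template))
    template <- build_spt_template(cohort, condition, exclude_subject,
                                   L_cycle = config$L_cycle, config = config)
  meta <- list(procedure = "SPT", code = spec$code, condition = condition,
               excluded = if (is.null(exclude_subject)) NA_character_
                          else exclude_subject,
               included = template$included)
  if (spec$kind == "SC")
    return(fit_spt_member(spec$model_id, spec$signal, template, config, meta))
  members <- list(ft = fit_spt_member(spec$model_id, "ft", template, config, meta),
                  sh = fit_spt_member(spec$model_id, "sh", template, config, meta))
  distributed_classifier(members$ft, members$sh, weights = c(0.5, 0.5),
                         stay_prob = config$stay_prob)
}

#' Run the factorial classifier study on a cohort
#'
#' For every classifier configuration, subject and walking condition: train on
#' repetition 1 (the subject's own trial for SST; the healthy-cohort template,
#' leave-one-out for TD subjects, for SPT), classify the filtered repetition-2
#' signals, and evaluate against the repetition-2 footswitch reference.
#' Scalar members are trained once and shared with the distributed
#' classifiers. Trial pairs with a missing repetition are skipped with a
#' warning.
#'
#' @param cohort A `gait_cohort` with both repetitions per subject/condition.
#' @param specs Data.frame from [enumerate_classifiers()] (or a subset).
#' @param config A [study_config()] list.
#' @return Data.frame with one row per (spec, subject, condition):
#'   identification columns, TP/FP/TN/FN, TPR, TNR, G and ROC category.
#'   The attribute `"spt_audit"` records, per template, the included subject
#'   ids (never containing the evaluated TD subject).
#' @export
run_study <- function(cohort, specs = enumerate_classifiers(),
                      config = study_config()) {
  specs <- specs[order(specs$procedure, specs$model_id, specs$signal), ,
                 drop = FALSE]
  template_cache <- new.env(parent = emptyenv())
  spt_cache <- new.env(parent = emptyenv())
  audit <- list()
  rows <- list()

  conditions <- sort(unique(vapply(cohort$trials, function(t) t$condition,
                                   character(1))))
  for (si in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$subject_id[si]
    grp <- cohort$subjects$group[si]
    for (cond in conditions) {
      rep1 <- get_trial(cohort, sid, cond, 1L)
      rep2 <- get_trial(cohort, sid, cond, 2L)
      if (is.null(rep1) || is.null(rep2)) {
        if (!is.null(rep1) || !is.null(rep2))
          warning(sprintf("run_study: missing repetition for %s/%s, skipped",
                          sid, cond))
        next
      }
      gyros2 <- filter_trial_gyros(rep2, config)
      refs2 <- lapply(c("2P" = "2P", "4P" = "4P", "6P" = "6P"),
                      function(m) trial_reference(rep2, m))
      sst_members <- new.env(parent = emptyenv())
      gyros1 <- NULL
      refs1 <- list()

      get_sst_member <- function(model_id, src) {
        key <- paste(model_id, src)
        if (!is.null(sst_members[[key]])) return(sst_members[[key]])
        if (is.null(gyros1)) gyros1 <<- filter_trial_gyros(rep1, config)
        if (is.null(refs1[[model_id]]))
          refs1[[model_id]] <<- trial_reference(rep1, model_id)
        m <- fit_scalar_member(model_id, src, gyros1[[src]], refs1[[model_id]],
                               config,
                               meta = list(procedure = "SST", subject = sid,
                                           condition = cond))
        sst_members[[key]] <- m
        m
      }
      get_spt_member <- function(model_id, src, exclude) {
        exc <- if (is.null(exclude)) "none" else exclude
        tkey <- paste(cond, exc)
        if (is.null(template_cache[[tkey]])) {
          template_cache[[tkey]] <- build_spt_template(
            cohort, cond, exclude, L_cycle = config$L_cycle, config = config)
          audit[[tkey]] <<- template_cache[[tkey]]$included
        }
        mkey <- paste(tkey, model_id, src)
        if (is.null(spt_cache[[mkey]]))
          spt_cache[[mkey]] <- fit_spt_member(
            model_id, src, template_cache[[tkey]], config,
            meta = list(procedure = "SPT", condition = cond, excluded = exc))
        spt_cache[[mkey]]
      }

      for (k in seq_len(nrow(specs))) {
        sp <- specs[k, ]
        exclude <- if (sp$procedure == "SPT" && grp == "TD") sid else NULL
        member <- function(src) {
          if (sp$procedure == "SST") get_sst_member(sp$model_id, src)
          else get_spt_member(sp$model_id, src, exclude)
        }
        pred <- if (sp$kind == "SC") {
          classify_scalar(member(sp$signal), gyros2[[sp$signal]],
                          decoder = config$decoder,
                          lag_samples = config$lag_samples)$sequence
        } else {
          dc <- distributed_classifier(member("ft"), member("sh"),
                                       weights = c(0.5, 0.5),
                                       stay_prob = config$stay_prob)
          classify_distributed(dc, gyros2$ft, gyros2$sh)$sequence
        }
        ev <- evaluate_sequences(pred, refs2[[sp$model_id]], config$tol_ms)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(spec = sp$code, procedure = sp$procedure,
                     model_id = sp$model_id, signal = sp$signal,
                     kind = sp$kind, subject = sid, group = grp,
                     condition = cond, stringsAsFactors = FALSE),
          ev)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  attr(results, "spt_audit") <- audit
  results
}

#' Write study results / aggregates as CSV
#' @param x Data.frame ([run_study()] or [aggregate_study()] output).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
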