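#' Parametric gait-cycle template
#'
#' Defines the deterministic skeleton of a synthetic stride: cadence, the
#' duration fractions of the six-phase script, smooth per-phase foot/shank
#' angular-velocity waveforms (periodic splines through per-phase control
#' points, continuous at phase boundaries, with the characteristic
#' double-peaked shank swing), and the footswitch onset/offset progression
#' {heel} -> {heel,m5} -> {heel,m5,m1} -> {all four} -> {m5,m1,toe} ->
#' {toe} -> {} whose combos map back, under the partitioning rules, exactly
#' to the emitted phase script. A `strict` progression emitting only
#' exact-rule combos ({m5,m1} instead of the three/four-switch stance combos)
#' is available for exact-match testing.
#'
#' @param cadence_spm Strides per minute. Default 35 (slow treadmill walking).
#' @param fractions Named 6-vector of phase duration fractions
#'   (IC, LR, MS, TS, PS, SW), positive, summing to 1.
#' @param foot_phases,shank_phases Per-phase waveform parameters: a named
#'   list (IC..SW) of lists with `start` and `end` levels (deg/s, held just
#'   inside the phase boundaries), an optional `shape` data.frame
#'   (`rel` position within the phase, `value`) for interior structure such
#'   as the swing peaks, and an optional `lead_start` (cycle fraction) that
#'   advances the start anchor ahead of the contact boundary (the push-off
#'   velocity surge begins just before the toe actually leaves the ground).
#' @param edge_frac Distance (cycle fraction) from each phase boundary at
#'   which the start/end levels are anchored; the waveform ramps between
#'   phases over `2 * edge_frac`, centered on the boundary (the sharp
#'   velocity changes that accompany the contact events). Default 0.01.
#' @param toe_onset_frac Position of the toe-switch onset within MS (0-1).
#' @param offaxis_scale Length-2 multipliers (frontal, transverse) applied to
#'   shifted copies of the sagittal waveform in 3-axis mode; `c(0, 0)` gives
#'   zero off-sagittal components.
#' @param strict_switches Use the exact-rule-only footswitch progression?
#' @return An object of class `gait_template`.
#' @export
gait_template <- function(cadence_spm = 35,
                          fractions = c(IC = 0.04, LR = 0.12, MS = 0.19,
                                        TS = 0.15, PS = 0.10, SW = 0.40),
                          foot_phases = list(
                            IC = list(start = -80, end = -80),
                            LR = list(start = -15, end = -15),
                            MS = list(start = 5, end = 30,
                                      shape = data.frame(rel = c(0.44, 0.56),
                                                         value = c(5, 30))),
                            TS = list(start = 60, end = 60),
                            PS = list(start = -160, end = -160),
                            SW = list(start = 220, end = 160, lead_start = 0.015,
                                      shape = data.frame(rel = c(0.30, 0.70),
                                                         value = c(190, 150)))),
                          shank_phases = list(
                            IC = list(start = -50, end = -50),
                            LR = list(start = -10, end = -10),
                            MS = list(start = 15, end = 45,
                                      shape = data.frame(rel = c(0.44, 0.56),
                                                         value = c(15, 45))),
                            TS = list(start = 75, end = 75),
                            PS = list(start = -100, end = -100),
                            SW = list(start = 220, end = 170, lead_start = 0.015,
                                      shape = data.frame(
                                        rel = c(0.25, 0.50, 0.75),
                                        value = c(195, 140, 200)))),
                          edge_frac = 0.01,
                          toe_onset_frac = 0.5,
                          offaxis_scale = c(0.2, 0.15),
                          strict_switches = FALSE) {
  stopifnot(cadence_spm > 0, length(fractions) == 6L, all(fractions > 0),
            edge_frac > 0)
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("gait_template: phase fractions must sum to 1")
  names(fractions) <- c("IC", "LR", "MS", "TS", "PS", "SW")
  stopifnot(identical(names(foot_phases), names(fractions)),
            identical(names(shank_phases), names(fractions)))
  structure(list(cadence_spm = cadence_spm, fractions = fractions,
                 foot_phases = foot_phases, shank_phases = shank_phases,
                 edge_frac = edge_frac, toe_onset_frac = toe_onset_frac,
                 offaxis_scale = offaxis_scale,
                 strict_switches = isTRUE(strict_switches)),
            class = "gait_template")
}

#' @export
print.gait_template <- function(x, ...) {
  cat(sprintf("<gait_template> %g strides/min; fractions %s\n", x$cadence_spm,
              paste(sprintf("%s=%.2f", names(x$fractions), x$fractions),
                    collapse = " ")))
  invisible(x)
}

# Waveform evaluated at cycle fractions phi in [0, 1): monotone-cubic
# (Fritsch-Carlson) interpolation through the per-phase control points,
# replicated over adjacent cycles for periodic continuity. Monotone segments
# avoid overshoot at the sharp boundary ramps.
template_wave <- function(template, segment, phi) {
  defs <- if (segment == "foot") template$foot_phases else template$shank_phases
  b_end <- cumsum(template$fractions)
  b_start <- c(0, b_end[-6])
  pos <- val <- numeric(0)
  for (i in seq_len(6L)) {
    d <- defs[[i]]
    len <- template$fractions[i]
    delta <- min(template$edge_frac, len / 4)
    lead <- if (is.null(d$lead_start)) 0 else d$lead_start
    p <- c(b_start[i] + delta - min(lead, delta / 2 + template$edge_frac / 2),
           if (!is.null(d$shape)) b_start[i] + d$shape$rel * len,
           b_end[i] - delta)
    v <- c(d$start, if (!is.null(d$shape)) d$shape$value, d$end)
    o <- order(p)
    pos <- c(pos, p[o]); val <- c(val, v[o])
  }
  f <- stats::splinefun(c(pos - 1, pos, pos + 1), rep(val, 3),
                        method = "monoH.FC")
  f(phi)
}

# Footswitch channel states (heel, m5, m1, toe) at cycle fractions phi.
template_switches <- function(template, phi) {
  b <- cumsum(template$fractions)       # IC LR MS TS PS SW ends
  toe_on <- if (template$strict_switches) b["TS"]
            else b["LR"] + template$toe_onset_frac * (b["MS"] - b["LR"])
  cbind(heel = as.numeric(phi < b["MS"]),
        m5 = as.numeric(phi >= b["IC"] & phi < b["TS"]),
        m1 = as.numeric(phi >= b["LR"] & phi < b["TS"]),
        toe = as.numeric(phi >= toe_on & phi < b["PS"]))
}

#' Generate one synthetic gait cycle
#'
#' Emits one stride: foot and shank angular velocity at the gyro rate, the
#' six-phase script (derived from the footswitch combos through the
#' partitioning rules, so generator and partitioner agree by construction),
#' and the four-channel footswitch trace at the footswitch rate.
#'
#' @param template A `gait_template`.
#' @param stride_s Stride duration (s); default from the template cadence.
#' @param amp_scale Length-2 amplitude multipliers (foot, shank).
#' @param fs_gyro,fs_fsw Sampling rates (Hz).
#' @return List with `foot`, `shank` (numeric), `script` (6P labels at the
#'   gyro rate), `fsw` (4-column 0/1 matrix at the footswitch rate) and
#'   `stride_samples`.
#' @export
generate_cycle <- function(template, stride_s = 60 / template$cadence_spm,
                           amp_scale = c(1, 1), fs_gyro = 50, fs_fsw = 200) {
  stride_samples <- round(stride_s * fs_gyro)
  if (any(template$fractions * stride_samples < 2))
    stop(sprintf("generate_cycle: phase '%s' shorter than 2 samples at %g Hz",
                 names(template$fractions)[
                   which.min(template$fractions * stride_samples)], fs_gyro))
  ratio <- round(fs_fsw / fs_gyro)
  phi_g <- (seq_len(stride_samples) - 1L) / stride_samples
  phi_f <- (seq_len(stride_samples * ratio) - 1L) / (stride_samples * ratio)

  sw_g <- template_switches(template, phi_g)
  codes <- 1L + sw_g[, "heel"] + 2L * sw_g[, "m5"] + 4L * sw_g[, "m1"] +
    8L * sw_g[, "toe"]
  script <- combo_table(phase_model("6P"))[codes]   # never NA by construction

  list(foot = amp_scale[1] * template_wave(template, "foot", phi_g),
       shank = amp_scale[2] * template_wave(template, "shank", phi_g),
       script = script,
       fsw = template_switches(template, phi_f),
       stride_samples = stride_samples)
}

#' Generate one synthetic walking trial
#'
#' Chains jittered cycles until the requested duration is reached, adds
#' measurement noise, and returns the trial together with its exact phase
#' script (ground truth).
#'
#' @param template A `gait_template` (already subject-perturbed).
#' @param duration_s Trial duration (s).
#' @param timing_jitter_sd,amp_jitter_sd Per-stride relative SD of stride
#'   duration and waveform amplitude.
#' @param noise_sd Additive Gaussian noise on the gyro channels (deg/s).
#' @param subject_id,group,condition,repetition Trial metadata.
#' @param mode `"sagittal"` (default) or `"3axis"` (adds frontal/transverse
#'   components for rotation-sensitivity studies).
#' @param fs_gyro,fs_fsw Sampling rates (Hz).
#' @return A `gait_trial`; attribute `"script"` holds the emitted 6P
#'   `phase_sequence`.
#' @export
generate_trial <- function(template, duration_s = 60, timing_jitter_sd = 0.03,
                           amp_jitter_sd = 0.05, noise_sd = 2,
                           subject_id = "S01", group = "TD",
                           condition = "L1.0", repetition = 1,
                           mode = c("sagittal", "3axis"),
                           fs_gyro = 50, fs_fsw = 200) {
  mode <- match.arg(mode)
  n_target <- round(duration_s * fs_gyro)
  foot <- shank <- numeric(0)
  script <- character(0)
  fsw <- NULL
  while (length(foot) < n_target) {
    stride_s <- (60 / template$cadence_spm) *
      max(1 + stats::rnorm(1, 0, timing_jitter_sd), 0.5)
    # keep every phase at >= 2 samples whatever the jitter draw
    stride_s <- max(stride_s, 2.2 / (min(template$fractions) * fs_gyro))
    amp <- pmax(1 + stats::rnorm(2, 0, amp_jitter_sd), 0.2)
    cyc <- generate_cycle(template, stride_s, amp_scale = amp,
                          fs_gyro = fs_gyro, fs_fsw = fs_fsw)
    foot <- c(foot, cyc$foot)
    shank <- c(shank, cyc$shank)
    script <- c(script, cyc$script)
    fsw <- rbind(fsw, cyc$fsw)
  }
  ratio <- round(fs_fsw / fs_gyro)
  foot <- foot[seq_len(n_target)]
  shank <- shank[seq_len(n_target)]
  script <- script[seq_len(n_target)]
  fsw <- fsw[seq_len(n_target * ratio), , drop = FALSE]

  noisy <- function(v) v + stats::rnorm(length(v), 0, noise_sd)
  mk_gyro <- function(v, segment, offaxis) {
    v_n <- noisy(v)
    v3 <- if (mode == "3axis") {
      shift <- round(length(v) * 0.05)
      roll <- function(x, k) if (k == 0) x else c(x[-seq_len(k)], x[seq_len(k)])
      cbind(v_n,
            noisy(offaxis[1] * roll(v, shift)),
            noisy(offaxis[2] * roll(v, 2 * shift)))
    } else NULL
    gyro_signal(v_n, segment = segment, fs_hz = fs_gyro, values_3d = v3)
  }
  trial <- gait_trial(
    subject_id = subject_id, group = group, condition = condition,
    repetition = repetition,
    gyro_foot = mk_gyro(foot, "foot", template$offaxis_scale),
    gyro_shank = mk_gyro(shank, "shank", template$offaxis_scale),
    footswitch = footswitch_signal(fsw[, "heel"], fsw[, "m5"], fsw[, "m1"],
                                   fsw[, "toe"], fs_hz = fs_fsw),
    min_span_s = min(10, duration_s - 1 / fs_gyro))
  attr(trial, "script") <- phase_sequence(script, "6P", fs_hz = fs_gyro,
                                          source = "reference")
  trial
}

#' Specification of a synthetic cohort
#'
#' Study-design parameters for one subject group. Defaults emulate the
#' emulated study: 10 subjects per group, four treadmill conditions (level /
#' 8 percent incline at 1.0 / 1.5 km/h), two repetitions of at least 60 s.
#' Hemiplegic (HC) subjects carry strictly higher intra-subject stride
#' variability than typically developed (TD) ones, and a reduced, more
#' heterogeneous amplitude on the affected side.
#'
#' @param n_subjects Subjects in the group. Default 10.
#' @param group `"TD"` or `"HC"`.
#' @param conditions Subset of `c("L1.0","L1.5","I1.0","I1.5")`.
#' @param duration_s Trial duration (s). Default 60.
#' @param inter_subject_sd Named list: `timing` (relative SD of cadence and
#'   of the phase-fraction perturbation) and `amplitude` (relative SD of the
#'   per-subject waveform scale). Defaults: timing 0.05 for TD and 0.075 for
#'   HC (pathological gait differs more from child to child in its timing
#'   structure); amplitude 0.10 for both groups.
#' @param intra_subject_sd Named list: per-stride `timing` and `amplitude`
#'   relative SDs (stride-to-stride variability; amplitude CV of about 10
#'   percent is typical of typically developed children and roughly doubles
#'   in hemiplegia). Defaults: TD 0.03 / 0.10, HC 0.06 / 0.18.
#' @param noise_sd Additive gyro noise (deg/s). Default 2.
#' @param seed RNG seed.
#' @param mode `"sagittal"` or `"3axis"`.
#' @param template Base `gait_template`.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10, group = c("TD", "HC"),
                        conditions = c("L1.0", "L1.5", "I1.0", "I1.5"),
                        duration_s = 60,
                        inter_subject_sd = NULL,
                        intra_subject_sd = NULL,
                        noise_sd = 2, seed = 1, mode = "sagittal",
                        template = gait_template()) {
  group <- match.arg(group)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(inter_subject_sd))
    inter_subject_sd <- if (group == "HC") list(timing = 0.075, amplitude = 0.10)
                        else list(timing = 0.05, amplitude = 0.10)
  if (is.null(intra_subject_sd))
    intra_subject_sd <- if (group == "HC") list(timing = 0.06, amplitude = 0.18)
                        else list(timing = 0.03, amplitude = 0.10)
  stopifnot(inter_subject_sd$timing >= 0, inter_subject_sd$amplitude >= 0,
            intra_subject_sd$timing >= 0, intra_subject_sd$amplitude >= 0,
            noise_sd >= 0, duration_s > 0, n_subjects >= 1)
  structure(list(n_subjects = n_subjects, group = group,
                 conditions = conditions, duration_s = duration_s,
                 inter_subject_sd = inter_subject_sd,
                 intra_subject_sd = intra_subject_sd, noise_sd = noise_sd,
                 seed = seed, mode = mode, template = template),
            class = "cohort_spec")
}

condition_modifiers <- function(condition) {
  speed <- if (grepl("1.5", condition, fixed = TRUE)) 1.25 else 1.0
  incline <- grepl("^I", condition)
  list(cadence = speed * if (incline) 0.95 else 1.0,
       amp_foot = if (speed > 1) 1.10 else 1.0,
       amp_shank = (if (speed > 1) 1.10 else 1.0) * if (incline) 1.15 else 1.0)
}

scale_phase_defs <- function(defs, f) {
  lapply(defs, function(d) {
    d$start <- d$start * f
    d$end <- d$end * f
    if (!is.null(d$shape)) d$shape$value <- d$shape$value * f
    d
  })
}

# Per-subject template perturbation: cadence, amplitude scale and mild
# phase-fraction redistribution; HC additionally walk with a reduced affected-
# side amplitude.
perturb_template <- function(spec) {
  tpl <- spec$template
  tpl$cadence_spm <- tpl$cadence_spm *
    max(1 + stats::rnorm(1, 0, spec$inter_subject_sd$timing), 0.6)
  amp <- max(1 + stats::rnorm(1, 0, spec$inter_subject_sd$amplitude), 0.3)
  fr <- tpl$fractions *
    pmax(1 + stats::rnorm(6, 0, 0.5 * spec$inter_subject_sd$timing), 0.5)
  tpl$fractions <- fr / sum(fr)
  tpl$foot_phases <- scale_phase_defs(tpl$foot_phases, amp)
  tpl$shank_phases <- scale_phase_defs(tpl$shank_phases, amp)
  tpl
}

#' Generate a synthetic cohort
#'
#' Per subject, a perturbed template; per condition, speed/incline modifiers
#' (speed scales cadence and amplitude, incline the shank amplitude); two
#' repetitions with independent per-stride jitter. Fully reproducible from
#' the spec seed.
#'
#' @param spec A `cohort_spec`, or a list of them (e.g. one TD and one HC
#'   group) sharing a seed sequence.
#' @return A `gait_cohort`.
#' @export
generate_cohort <- function(spec) {
  specs <- if (inherits(spec, "cohort_spec")) list(spec) else spec
  set.seed(specs[[1]]$seed)
  trials <- list()
  for (sp in specs) {
    for (s in seq_len(sp$n_subjects)) {
      sid <- sprintf("%s%02d", sp$group, s)
      tpl <- perturb_template(sp)
      for (cond in sp$conditions) {
        mod <- condition_modifiers(cond)
        tpl_c <- tpl
        tpl_c$cadence_spm <- tpl$cadence_spm * mod$cadence
        tpl_c$foot_phases <- scale_phase_defs(tpl$foot_phases, mod$amp_foot)
        tpl_c$shank_phases <- scale_phase_defs(tpl$shank_phases, mod$amp_shank)
        for (rep_i in 1:2) {
          trials[[length(trials) + 1L]] <- generate_trial(
            tpl_c, duration_s = sp$duration_s,
            timing_jitter_sd = sp$intra_subject_sd$timing,
            amp_jitter_sd = sp$intra_subject_sd$amplitude,
            noise_sd = sp$noise_sd, subject_id = sid, group = sp$group,
            condition = cond, repetition = rep_i, mode = sp$mode)
        }
      }
    }
  }
  gait_cohort(trials)
}

#' Rotate the 3-axis angular-velocity vector of a trial
#'
#' Emulates an IMU mounting error: applies a fixed rotation (degrees) about
#' the frontal and/or transverse axis to the 3-axis angular-velocity vector
#' and re-extracts the sagittal component. The footswitch trace is unchanged.
#'
#' @param trial A `gait_trial` generated in 3-axis mode.
#' @param angles_deg Length-2 vector `(frontal, transverse)` in degrees.
#' @return The rotated `gait_trial`.
#' @export
perturb_rotation <- function(trial, angles_deg) {
  stopifnot(inherits(trial, "gait_trial"), length(angles_deg) == 2)
  rot1 <- function(gyro) {
    if (is.null(gyro$values_3d))
      stop("perturb_rotation: trial was not generated in 3-axis mode; ",
           "regenerate with mode = '3axis'")
    a <- angles_deg[1] * pi / 180   # about frontal axis: mixes sagittal/transverse
    b <- angles_deg[2] * pi / 180   # about transverse axis: mixes sagittal/frontal
    Rf <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
    Rt <- matrix(c(cos(b), -sin(b), 0, sin(b), cos(b), 0, 0, 0, 1), 3, 3)
    v3 <- gyro$values_3d %*% t(Rt %*% Rf)
    gyro$values_3d <- v3
    gyro$values <- v3[, 1]
    gyro
  }
  trial$gyro_foot <- rot1(trial$gyro_foot)
  trial$gyro_shank <- rot1(trial$gyro_shank)
  trial
}
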