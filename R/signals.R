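#' Sagittal angular-velocity signal of one body segment
#'
#' Container for the gyroscope channel used throughout the pipeline: the
#' sagittal-plane angular velocity (deg/s) of either the foot or the shank,
#' sampled at a fixed rate (50 Hz for the devices emulated here).
#'
#' @param values Numeric vector of angular velocities (deg/s), length >= 2,
#'   all finite.
#' @param segment `"foot"` or `"shank"`.
#' @param fs_hz Sampling rate in Hz (> 0). Default 50.
#' @param t0 Start time in seconds. Default 0.
#' @param values_3d Optional 3-column matrix (sagittal, frontal, transverse
#'   components, deg/s) for rotation-sensitivity studies; when supplied its
#'   first column must equal `values`.
#' @return An object of class `gyro_signal`.
#' @export
gyro_signal <- function(values, segment = c("foot", "shank"), fs_hz = 50,
                        t0 = 0, values_3d = NULL) {
  segment <- match.arg(segment)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("gyro_signal: length >= 2 violated")
  if (!all(is.finite(values))) stop("gyro_signal: all values must be finite")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("gyro_signal: fs_hz must be a positive scalar")
  if (!is.null(values_3d)) {
    values_3d <- as.matrix(values_3d)
    if (ncol(values_3d) != 3L || nrow(values_3d) != length(values))
      stop("gyro_signal: values_3d must be a length(values) x 3 matrix")
  }
  structure(list(segment = segment, fs_hz = fs_hz, t0 = t0,
                 values = values, values_3d = values_3d),
            class = "gyro_signal")
}

#' @export
print.gyro_signal <- function(x, ...) {
  cat(sprintf("<gyro_signal> %s, %d samples @ %g Hz (%.2f s), range [%.1f, %.1f] deg/s\n",
              x$segment, length(x$values), x$fs_hz,
              length(x$values) / x$fs_hz, min(x$values), max(x$values)))
  invisible(x)
}

#' Time stamps of a signal
#' @param x A `gyro_signal`, `footswitch_signal` or `phase_sequence`.
#' @return Numeric vector of sample times (s).
#' @export
signal_times <- function(x) {
  n <- if (inherits(x, "footswitch_signal")) nrow(x$channels)
       else if (inherits(x, "phase_sequence")) length(x$labels)
       else length(x$values)
  x$t0 + (seq_len(n) - 1L) / x$fs_hz
}

#' Four-channel binary footswitch trace
#'
#' Binary on/off state of the four pressure switches placed under the heel,
#' the fifth and first metatarsal heads and the toe, typically sampled at
#' 200 Hz. These traces are the reference from which gait phases are derived.
#'
#' @param heel,m5,m1,toe Equal-length vectors of 0/1 values.
#' @param fs_hz Sampling rate in Hz (> 0). Default 200.
#' @param t0 Start time in seconds.
#' @return An object of class `footswitch_signal`; channel matrix in column
#'   order heel, m5, m1, toe.
#' @export
footswitch_signal <- function(heel, m5, m1, toe, fs_hz = 200, t0 = 0) {
  ch <- cbind(heel = as.numeric(heel), m5 = as.numeric(m5),
              m1 = as.numeric(m1), toe = as.numeric(toe))
  if (length(unique(c(length(heel), length(m5), length(m1), length(toe)))) != 1L)
    stop("footswitch_signal: all four channels must have equal length")
  bad <- which(!(ch %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("footswitch_signal: non-binary value at row %d",
                 ((bad[1] - 1L) %% nrow(ch)) + 1L))
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("footswitch_signal: fs_hz must be > 0")
  structure(list(fs_hz = fs_hz, t0 = t0, channels = ch),
            class = "footswitch_signal")
}

#' @export
print.footswitch_signal <- function(x, ...) {
  cat(sprintf("<footswitch_signal> %d samples @ %g Hz (%.2f s), activation %s\n",
              nrow(x$channels), x$fs_hz, nrow(x$channels) / x$fs_hz,
              paste(sprintf("%s=%.0f%%", colnames(x$channels),
                            100 * colMeans(x$channels)), collapse = " ")))
  invisible(x)
}

#' One walking-trial recording
#'
#' Bundles the foot and shank gyro signals and the footswitch trace for one
#' subject, walking condition (treadmill level/incline at 1.0 or 1.5 km/h)
#' and repetition.
#'
#' @param subject_id Subject identifier (character).
#' @param group `"TD"` (typically developed) or `"HC"` (hemiplegic).
#' @param condition One of `"L1.0"`, `"L1.5"`, `"I1.0"`, `"I1.5"`.
#' @param repetition 1 or 2.
#' @param gyro_foot,gyro_shank `gyro_signal` objects with matching segments.
#' @param footswitch A `footswitch_signal`.
#' @param min_span_s Minimum overlapping time span (s) required across the
#'   three signals. Default 10.
#' @return An object of class `gait_trial`.
#' @export
gait_trial <- function(subject_id, group = c("TD", "HC"),
                       condition = c("L1.0", "L1.5", "I1.0", "I1.5"),
                       repetition, gyro_foot, gyro_shank, footswitch,
                       min_span_s = 10) {
  group <- match.arg(group)
  condition <- match.arg(condition)
  repetition <- as.integer(repetition)
  if (!repetition %in% c(1L, 2L)) stop("gait_trial: repetition must be 1 or 2")
  if (!inherits(gyro_foot, "gyro_signal") || gyro_foot$segment != "foot")
    stop("gait_trial: gyro_foot must be a foot gyro_signal")
  if (!inherits(gyro_shank, "gyro_signal") || gyro_shank$segment != "shank")
    stop("gait_trial: gyro_shank must be a shank gyro_signal")
  if (!inherits(footswitch, "footswitch_signal"))
    stop("gait_trial: footswitch must be a footswitch_signal")
  spans <- vapply(list(gyro_foot, gyro_shank, footswitch), function(s)
    c(min(signal_times(s)), max(signal_times(s))), numeric(2))
  overlap <- min(spans[2, ]) - max(spans[1, ])
  if (overlap < min_span_s)
    stop(sprintf("gait_trial: overlapping span %.2f s < required %g s",
                 overlap, min_span_s))
  structure(list(subject_id = as.character(subject_id), group = group,
                 condition = condition, repetition = repetition,
                 gyro_foot = gyro_foot, gyro_shank = gyro_shank,
                 footswitch = footswitch),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> subject %s (%s), %s rep %d; foot/shank gyro @ %g Hz, footswitch @ %g Hz\n",
              x$subject_id, x$group, x$condition, x$repetition,
              x$gyro_foot$fs_hz, x$footswitch$fs_hz))
  invisible(x)
}

trial_key <- function(trial)
  paste(trial$subject_id, trial$condition, trial$repetition, sep = "|")

#' Cohort of walking trials
#'
#' @param trials List of `gait_trial` objects. Keys
#'   (subject, condition, repetition) must be unique and each subject's group
#'   tag consistent across its trials.
#' @return An object of class `gait_cohort` (list with `trials` indexed by
#'   key and a `subjects` table).
#' @export
gait_cohort <- function(trials) {
  stopifnot(length(trials) > 0)
  keys <- vapply(trials, trial_key, character(1))
  if (anyDuplicated(keys))
    stop("gait_cohort: duplicate (subject, condition, repetition) keys: ",
         paste(keys[duplicated(keys)], collapse = ", "))
  subj <- vapply(trials, function(t) t$subject_id, character(1))
  grp <- vapply(trials, function(t) t$group, character(1))
  if (any(tapply(grp, subj, function(g) length(unique(g))) > 1L))
    stop("gait_cohort: inconsistent group tag within a subject")
  names(trials) <- keys
  structure(list(trials = trials,
                 subjects = unique(data.frame(subject_id = subj, group = grp,
                                              stringsAsFactors = FALSE))),
            class = "gait_cohort")
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("<gait_cohort> %d trials, %d subjects (%s)\n",
              length(x$trials), nrow(x$subjects),
              paste(sprintf("%s n=%d", names(table(x$subjects$group)),
                            as.integer(table(x$subjects$group))), collapse = ", ")))
  invisible(x)
}

#' Retrieve one trial from a cohort
#' @param cohort A `gait_cohort`.
#' @param subject_id,condition,repetition Trial key.
#' @return The `gait_trial`, or `NULL` if absent.
#' @export
get_trial <- function(cohort, subject_id, condition, repetition) {
  cohort$trials[[paste(subject_id, condition, repetition, sep = "|")]]
}

# ---- CSV / manifest I/O -----------------------------------------------------

read_timed_csv <- function(path, required_cols) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    stop(sprintf("%s: malformed header, missing column '%s'", path, missing[1]))
  if (any(diff(df$time_s) <= 0))
    stop(sprintf("%s: time_s must be strictly increasing", path))
  df
}

infer_fs <- function(time_s) 1 / stats::median(diff(time_s))

#' Read a gyro CSV (`time_s,gyro_sagittal_dps`)
#' @param path File path.
#' @param segment `"foot"` or `"shank"`.
#' @return A `gyro_signal`.
#' @export
read_gyro_csv <- function(path, segment) {
  df <- read_timed_csv(path, c("time_s", "gyro_sagittal_dps"))
  gyro_signal(df$gyro_sagittal_dps, segment = segment,
              fs_hz = infer_fs(df$time_s), t0 = df$time_s[1])
}

#' Read a footswitch CSV (`time_s,heel,m5,m1,toe`)
#' @param path File path.
#' @return A `footswitch_signal`.
#' @export
read_footswitch_csv <- function(path) {
  df <- read_timed_csv(path, c("time_s", "heel", "m5", "m1", "toe"))
  for (ch in c("heel", "m5", "m1", "toe")) {
    bad <- which(!df[[ch]] %in% c(0, 1))
    if (length(bad))
      stop(sprintf("%s: non-binary footswitch value in '%s' at row %d",
                   path, ch, bad[1]))
  }
  footswitch_signal(df$heel, df$m5, df$m1, df$toe,
                    fs_hz = infer_fs(df$time_s), t0 = df$time_s[1])
}

#' Read one trial from its three CSV files
#'
#' @param gyro_foot_path,gyro_shank_path,footswitch_path CSV paths conforming
#'   to the package's dialects (see [read_gyro_csv()], [read_footswitch_csv()]).
#' @param metadata List with `subject_id`, `group`, `condition`, `repetition`.
#' @return A validated `gait_trial`.
#' @export
read_trial <- function(gyro_foot_path, gyro_shank_path, footswitch_path, metadata) {
  gait_trial(subject_id = metadata$subject_id, group = metadata$group,
             condition = metadata$condition, repetition = metadata$repetition,
             gyro_foot = read_gyro_csv(gyro_foot_path, "foot"),
             gyro_shank = read_gyro_csv(gyro_shank_path, "shank"),
             footswitch = read_footswitch_csv(footswitch_path))
}

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write one trial to a directory as three CSV files
#'
#' Writers are deterministic: identical inputs give bit-identical files.
#'
#' @param trial A `gait_trial`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of paths written.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s_rep%d", trial$subject_id, gsub("\\.", "", trial$condition),
                  trial$repetition)
  paths <- c(gyro_foot = file.path(dir, paste0(stem, "_gyro_foot.csv")),
             gyro_shank = file.path(dir, paste0(stem, "_gyro_shank.csv")),
             footswitch = file.path(dir, paste0(stem, "_footswitch.csv")))
  for (seg in c("gyro_foot", "gyro_shank")) {
    g <- trial[[seg]]
    writeLines(c("time_s,gyro_sagittal_dps",
                 paste(fmt_num(signal_times(g)), fmt_num(g$values), sep = ",")),
               paths[[seg]])
  }
  fs <- trial$footswitch
  writeLines(c("time_s,heel,m5,m1,toe",
               paste(fmt_num(signal_times(fs)),
                     fs$channels[, "heel"], fs$channels[, "m5"],
                     fs$channels[, "m1"], fs$channels[, "toe"], sep = ",")),
             paths[["footswitch"]])
  invisible(paths)
}

#' Write a cohort to disk (per-trial CSVs + YAML manifest)
#' @param cohort A `gait_cohort`.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(cohort$trials, function(tr) {
    p <- write_trial(tr, dir)
    list(subject_id = tr$subject_id, group = tr$group,
         condition = tr$condition, repetition = tr$repetition,
         gyro_foot = basename(p[["gyro_foot"]]),
         gyro_shank = basename(p[["gyro_shank"]]),
         footswitch = basename(p[["footswitch"]]))
  })
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(trials = unname(manifest)), path)
  invisible(path)
}

#' Read a cohort from a YAML manifest
#' @param manifest_path Path to `manifest.yaml` as written by [write_cohort()].
#' @return A `gait_cohort`.
#' @export
read_cohort <- function(manifest_path) {
  m <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  gait_cohort(lapply(m$trials, function(e)
    read_trial(file.path(base, e$gyro_foot), file.path(base, e$gyro_shank),
               file.path(base, e$footswitch), e)))
}

# ---- preprocessing ----------------------------------------------------------

#' Low-pass Butterworth filter for gyro signals
#'
#' Applies a Butterworth low-pass filter (default 4th order, zero-phase via
#' forward-backward filtering) to the angular-velocity trace. Zero-phase
#' filtering is used because phase-transition timing feeds a tolerance-windowed
#' evaluation and a causal filter would bias every detected transition late.
#'
#' @param signal A `gyro_signal`.
#' @param cutoff_hz Cut-off frequency in Hz; must satisfy 0 < cutoff < fs/2.
#'   Default 15.
#' @param order Filter order (of the one-pass prototype). Default 4.
#' @param zero_phase Apply forward-backward (`signal::filtfilt`)? Default TRUE.
#' @return A `gyro_signal` of the same length and rate.
#' @export
lowpass_filter <- function(signal, cutoff_hz = 15, order = 4, zero_phase = TRUE) {
  stopifnot(inherits(signal, "gyro_signal"))
  if (cutoff_hz <= 0 || cutoff_hz >= signal$fs_hz / 2)
    stop(sprintf("lowpass_filter: cutoff %g Hz not in (0, Nyquist %g Hz)",
                 cutoff_hz, signal$fs_hz / 2))
  bf <- signal::butter(order, 2 * cutoff_hz / signal$fs_hz, type = "low")
  filt1 <- function(v) {
    if (zero_phase) as.numeric(signal::filtfilt(bf, v))
    else as.numeric(signal::filter(bf, v))
  }
  out <- signal
  out$values <- filt1(signal$values)
  if (!is.null(signal$values_3d)) {
    out$values_3d <- apply(signal$values_3d, 2, filt1)
    out$values_3d[, 1] <- out$values
  }
  out
}

#' Align a footswitch trace to the gyro time base
#'
#' Resamples the (typically 200 Hz) footswitch channels onto the gyro rate by
#' taking, at each target timestamp, the state of the nearest original sample.
#' This keeps values binary and preserves phase-onset timing to within half an
#' original sample period (2.5 ms at 200 Hz).
#'
#' @param fs_sig A `footswitch_signal`.
#' @param target_fs_hz Target rate (Hz), e.g. 50.
#' @param t_grid Optional explicit vector of target timestamps (s); overrides
#'   the regular grid derived from `target_fs_hz`.
#' @return A `footswitch_signal` at the target rate.
#' @export
align_footswitch_to_gyro <- function(fs_sig, target_fs_hz = 50, t_grid = NULL) {
  stopifnot(inherits(fs_sig, "footswitch_signal"))
  t_src <- signal_times(fs_sig)
  if (is.null(t_grid)) {
    n_out <- floor((max(t_src) - fs_sig$t0) * target_fs_hz) + 1L
    t_grid <- fs_sig$t0 + (seq_len(n_out) - 1L) / target_fs_hz
  }
  if (min(t_grid) > max(t_src) || max(t_grid) < min(t_src))
    stop("align_footswitch_to_gyro: non-overlapping time spans")
  idx <- pmin(pmax(round((t_grid - fs_sig$t0) * fs_sig$fs_hz) + 1L, 1L),
              nrow(fs_sig$channels))
  ch <- fs_sig$channels[idx, , drop = FALSE]
  footswitch_signal(ch[, "heel"], ch[, "m5"], ch[, "m1"], ch[, "toe"],
                    fs_hz = 1 / stats::median(diff(t_grid)), t0 = t_grid[1])
}
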