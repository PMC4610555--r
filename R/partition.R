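SWITCHES <- c("heel", "m5", "m1", "toe")

#' Gait-phase vocabulary and footswitch partitioning rules
#'
#' Encodes the three gait partitioning models and the combination-of-active-
#' footswitches logic that maps a switch combo to a phase:
#'
#' * `2P`: stance (SP: at least one switch pressed), swing (SW: none).
#' * `4P`: flat foot (FF: all four pressed), heel off (HO: heel released and
#'   at least one forefoot switch pressed), swing (SW: none), heel strike
#'   (HS: heel only).
#' * `6P`: initial contact (IC: heel), loading response (LR: heel + 5th
#'   metatarsus), mid stance (MS: heel + 5th + 1st), terminal stance (TS:
#'   5th + 1st), pre swing (PS: toe), swing (SW: none).
#'
#' Each phase carries a required-active set (`required`, switches that must be
#' pressed), an any-of set (`any_of`, at least one pressed when non-empty) and
#' an implied-inactive set (every other switch released) used for exact
#' matching.
#'
#' @param model_id `"2P"`, `"4P"` or `"6P"`.
#' @return An object of class `phase_model` with `model_id`, `phases` (labels
#'   in cycle order) and `rules`.
#' @export
phase_model <- function(model_id = c("2P", "4P", "6P")) {
  model_id <- match.arg(model_id)
  rule <- function(required = character(), any_of = character())
    list(required = required, any_of = any_of,
         inactive = setdiff(SWITCHES, c(required, any_of)))
  rules <- switch(model_id,
    "2P" = list(SP = rule(any_of = SWITCHES),
                SW = rule()),
    "4P" = list(FF = rule(required = SWITCHES),
                HO = rule(any_of = c("m5", "m1", "toe")),
                SW = rule(),
                HS = rule(required = "heel")),
    "6P" = list(IC = rule(required = "heel"),
                LR = rule(required = c("heel", "m5")),
                MS = rule(required = c("heel", "m5", "m1")),
                TS = rule(required = c("m5", "m1")),
                PS = rule(required = "toe"),
                SW = rule()))
  structure(list(model_id = model_id, phases = names(rules), rules = rules),
            class = "phase_model")
}

#' @export
print.phase_model <- function(x, ...) {
  cat(sprintf("<phase_model> %s: %s\n", x$model_id, paste(x$phases, collapse = " -> ")))
  invisible(x)
}

as_phase_model <- function(model) {
  if (inherits(model, "phase_model")) model else phase_model(model)
}

#' Map an active-footswitch combo to a gait phase
#'
#' Total, deterministic resolution in four tiers: (1) exact rule match
#' (required switches pressed, implied-inactive released, any-of satisfied
#' where defined); (2) most-specific subset match — the phase whose
#' required-active set is the unique largest subset of the active set;
#' (3) hold the previous phase (covers combos outside the table, and
#' specificity ties, which are physically transient states); (4) with no
#' previous phase, the model's first phase.
#'
#' @param active_switches Character vector, subset of
#'   `c("heel","m5","m1","toe")` (or a named binary vector over those four).
#' @param model A `phase_model` or model id.
#' @param previous_phase Previously assigned label, or `NULL`.
#' @return A phase label of the model.
#' @export
classify_combo <- function(active_switches, model, previous_phase = NULL) {
  model <- as_phase_model(model)
  lab <- combo_resolution(active_switches, model)
  if (!is.na(lab)) return(lab)
  if (!is.null(previous_phase)) return(previous_phase)
  model$phases[1L]
}

# Tiers 1-2 of classify_combo; NA when the combo can only be resolved by the
# previous-phase hold (tier 3/4).
combo_resolution <- function(active_switches, model) {
  if (is.numeric(active_switches))
    active_switches <- SWITCHES[as.logical(active_switches)]
  active <- intersect(SWITCHES, active_switches)

  # tier 1: exact
  for (ph in model$phases) {
    r <- model$rules[[ph]]
    if (all(r$required %in% active) &&
        !any(r$inactive %in% active) &&
        (length(r$any_of) == 0L || any(r$any_of %in% active)))
      return(ph)
  }
  # tier 2: unique most-specific subset (non-vacuous required sets only)
  sizes <- vapply(model$phases, function(ph) {
    r <- model$rules[[ph]]
    if (length(r$required) > 0L && all(r$required %in% active))
      length(r$required) else -1L
  }, integer(1))
  if (max(sizes) > 0L && sum(sizes == max(sizes)) == 1L)
    return(model$phases[which.max(sizes)])
  NA_character_
}

# Labels for all 16 switch combos (index = 1 + heel + 2*m5 + 4*m1 + 8*toe);
# NA marks hold-previous combos.
combo_table <- function(model) {
  vapply(0:15, function(code)
    combo_resolution(SWITCHES[bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0], model),
    character(1))
}

#' Per-sample gait-phase labeling
#'
#' @param labels Character vector of phase labels (all in the model's
#'   vocabulary) or integer indices into it.
#' @param model A `phase_model` or model id.
#' @param fs_hz Sampling rate (Hz).
#' @param source `"reference"` (footswitch-derived) or `"predicted"`.
#' @param t0 Start time (s).
#' @return An object of class `phase_sequence`; `labels` stored as character.
#' @export
phase_sequence <- function(labels, model, fs_hz = 50,
                           source = c("reference", "predicted"), t0 = 0) {
  model <- as_phase_model(model)
  source <- match.arg(source)
  if (is.numeric(labels)) labels <- model$phases[labels]
  if (length(labels) < 1L) stop("phase_sequence: length >= 1 violated")
  if (!all(labels %in% model$phases))
    stop("phase_sequence: label outside the model vocabulary: ",
         paste(unique(setdiff(labels, model$phases)), collapse = ", "))
  structure(list(model_id = model$model_id, fs_hz = fs_hz, t0 = t0,
                 labels = as.character(labels), source = source),
            class = "phase_sequence")
}

#' @export
print.phase_sequence <- function(x, ...) {
  tab <- table(factor(x$labels, levels = phase_model(x$model_id)$phases))
  cat(sprintf("<phase_sequence> %s %s, %d samples @ %g Hz: %s\n",
              x$source, x$model_id, length(x$labels), x$fs_hz,
              paste(sprintf("%s %.0f%%", names(tab), 100 * tab / length(x$labels)),
                    collapse = " ")))
  invisible(x)
}

#' Reference phase sequence from a footswitch trace
#'
#' Aligns the trace to the target rate (gyro rate, so prediction and reference
#' share a time base) and labels every sample with [classify_combo()], carrying
#' the running previous phase.
#'
#' @param fs_sig A `footswitch_signal`.
#' @param model A `phase_model` or model id.
#' @param target_fs_hz Output rate (Hz), default 50.
#' @param t_grid Optional explicit target timestamps (see
#'   [align_footswitch_to_gyro()]).
#' @return A `phase_sequence` with `source = "reference"`.
#' @export
partition_trial <- function(fs_sig, model, target_fs_hz = 50, t_grid = NULL) {
  model <- as_phase_model(model)
  if (nrow(fs_sig$channels) == 0L) stop("partition_trial: empty footswitch trace")
  if (abs(fs_sig$fs_hz - target_fs_hz) > 1e-9 || !is.null(t_grid))
    fs_sig <- align_footswitch_to_gyro(fs_sig, target_fs_hz, t_grid)
  ch <- fs_sig$channels
  codes <- 1L + ch[, "heel"] + 2L * ch[, "m5"] + 4L * ch[, "m1"] + 8L * ch[, "toe"]
  labels <- combo_table(model)[codes]
  # hold-previous combos: carry the last resolved label forward
  if (anyNA(labels)) {
    known <- !is.na(labels)
    carried <- cummax(ifelse(known, seq_along(labels), 0L))
    labels <- ifelse(carried > 0L, labels[pmax(carried, 1L)], model$phases[1L])
  }
  phase_sequence(labels, model, fs_hz = fs_sig$fs_hz, source = "reference",
                 t0 = fs_sig$t0)
}

#' Phase-transition events of a labeling
#'
#' @param seq A `phase_sequence`.
#' @return A data.frame with `sample_index` (1-based index of the first sample
#'   of the new phase), `from_phase`, `to_phase`; zero rows if constant.
#' @export
transitions <- function(seq) {
  stopifnot(inherits(seq, "phase_sequence"))
  l <- seq$labels
  idx <- which(l[-1] != l[-length(l)]) + 1L
  data.frame(sample_index = idx, from_phase = l[idx - 1L], to_phase = l[idx],
             stringsAsFactors = FALSE)
}

#' Gait-cycle start indices
#'
#' Cycle boundaries are the transitions into the model's first phase (the
#' heel-contact side of the cycle).
#'
#' @param seq A reference `phase_sequence`.
#' @return Integer vector of 1-based start indices (possibly empty).
#' @export
segment_cycles <- function(seq) {
  first <- phase_model(seq$model_id)$phases[1L]
  tr <- transitions(seq)
  starts <- tr$sample_index[tr$to_phase == first]
  if (length(starts) < 2L) {
    warning("segment_cycles: fewer than 2 cycle boundaries found")
    return(integer(0))
  }
  starts
}

#' Write / read a phase sequence as CSV (`time_s,phase_label`)
#' @param seq A `phase_sequence`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phase_csv <- function(seq, path) {
  writeLines(c("time_s,phase_label",
               paste(fmt_num(signal_times(seq)), seq$labels, sep = ",")), path)
  invisible(path)
}

#' @rdname write_phase_csv
#' @param model,source Passed to [phase_sequence()] when reading.
#' @export
read_phase_csv <- function(path, model, source = "reference") {
  df <- read_timed_csv(path, c("time_s", "phase_label"))
  phase_sequence(df$phase_label, model, fs_hz = infer_fs(df$time_s),
                 source = source, t0 = df$time_s[1])
}
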