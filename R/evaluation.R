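# Half-width of the centered tolerance window, in samples. Half-down rounding:
# 60 ms at 50 Hz gives 1.5 samples -> 1 (i.e. +-1 sample = +-20 ms).
tolerance_halfwidth <- function(tol_ms, fs_hz) {
  as.integer(floor(tol_ms / 2 * fs_hz / 1000 + 0.5 - 1e-9))
}

#' Transition-event confusion counts under a tolerance window
#'
#' The positive event is a phase transition. A reference transition is a true
#' positive when a predicted transition with the identical (from, to) phase
#' pair lies within the centered tolerance window (greedy nearest-first,
#' one-to-one matching); unmatched reference transitions are false negatives,
#' unmatched predicted transitions false positives, and every remaining
#' non-transition sample a true negative.
#'
#' @param pred,ref Predicted and reference `phase_sequence`s of equal length,
#'   rate and model.
#' @param tol_ms Full width of the centered tolerance window (ms). Default 60.
#' @return List with integer counts `tp`, `fp`, `tn`, `fn` and the
#'   `halfwidth_samples` used.
#' @export
transition_confusion <- function(pred, ref, tol_ms = 60) {
  stopifnot(inherits(pred, "phase_sequence"), inherits(ref, "phase_sequence"))
  if (pred$model_id != ref$model_id)
    stop("transition_confusion: phase-model mismatch")
  if (length(pred$labels) != length(ref$labels) ||
      abs(pred$fs_hz - ref$fs_hz) > 1e-9)
    stop("transition_confusion: sequences must share length and rate")
  hw <- tolerance_halfwidth(tol_ms, ref$fs_hz)
  tr_ref <- transitions(ref)
  tr_pred <- transitions(pred)

  matched_ref <- rep(FALSE, nrow(tr_ref))
  matched_pred <- rep(FALSE, nrow(tr_pred))
  if (nrow(tr_ref) && nrow(tr_pred)) {
    cand <- do.call(rbind, lapply(seq_len(nrow(tr_ref)), function(i) {
      j <- which(tr_pred$from_phase == tr_ref$from_phase[i] &
                 tr_pred$to_phase == tr_ref$to_phase[i] &
                 abs(tr_pred$sample_index - tr_ref$sample_index[i]) <= hw)
      if (!length(j)) return(NULL)
      data.frame(i = i, j = j,
                 d = abs(tr_pred$sample_index[j] - tr_ref$sample_index[i]))
    }))
    if (!is.null(cand)) {
      cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
      for (r in seq_len(nrow(cand))) {
        i <- cand$i[r]; j <- cand$j[r]
        if (!matched_ref[i] && !matched_pred[j]) {
          matched_ref[i] <- TRUE
          matched_pred[j] <- TRUE
        }
      }
    }
  }
  tp <- sum(matched_ref)
  fn <- nrow(tr_ref) - tp
  fp <- nrow(tr_pred) - tp
  tn <- max(length(ref$labels) - nrow(tr_ref) - fp, 0L)
  list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
       fn = as.integer(fn), halfwidth_samples = hw)
}

#' Goodness index of a classifier in ROC space
#'
#' Euclidean distance from the operating point to the perfect-classifier
#' corner: `G = sqrt((1 - TPR)^2 + (1 - TNR)^2)`. 0 is perfect, ~0.70
#' (sqrt(2)/2) is chance level, sqrt(2) the worst corner.
#'
#' @param tpr,tnr Sensitivity and specificity in `[0, 1]` (NA propagates).
#' @return The goodness index.
#' @export
goodness <- function(tpr, tnr) {
  if (any(!is.na(tpr) & (tpr < 0 | tpr > 1)) ||
      any(!is.na(tnr) & (tnr < 0 | tnr > 1)))
    stop("goodness: rates must be in [0, 1]")
  sqrt((1 - tpr)^2 + (1 - tnr)^2)
}

#' ROC category of a goodness value
#'
#' `optimum` when G <= 0.25, `good` when 0.25 < G < 0.70, `random` at
#' G = 0.70 (chance level), `bad` when G > 0.70.
#'
#' @param g Goodness value(s), >= 0.
#' @return Character vector of categories.
#' @export
categorize <- function(g) {
  vapply(g, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0) stop("categorize: g must be >= 0")
    if (x <= 0.25) "optimum"
    else if (abs(x - 0.70) <= 1e-9) "random"
    else if (x < 0.70) "good"
    else "bad"
  }, character(1))
}

#' Evaluate a predicted sequence against its reference
#'
#' @inheritParams transition_confusion
#' @return One-row data.frame with counts, TPR, TNR, G and category. Rates
#'   with zero denominators are NA (and G then NA), never silently 0.
#' @export
evaluate_sequences <- function(pred, ref, tol_ms = 60) {
  cc <- transition_confusion(pred, ref, tol_ms)
  tpr <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  tnr <- if (cc$fp + cc$tn > 0) cc$tn / (cc$fp + cc$tn) else NA_real_
  g <- if (is.na(tpr) || is.na(tnr)) NA_real_ else goodness(tpr, tnr)
  data.frame(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
             tpr = tpr, tnr = tnr, g = g, category = categorize(g),
             stringsAsFactors = FALSE)
}

#' Aggregate a study results table
#'
#' Mean and standard deviation (n - 1 denominator) of the goodness index per
#' cell of the grouping columns, mirroring a per-group/condition/classifier
#' summary of the factorial study.
#'
#' @param results Data.frame as produced by [run_study()] (needs a `g` column
#'   and the grouping columns).
#' @param group_by Character vector of grouping columns. Default
#'   `c("group", "condition", "model_id", "signal", "procedure")`.
#' @return Data.frame with the grouping columns plus `mean_G`, `sd_G`
#'   (0 when n = 1), `n`. Cells with no finite G are dropped with a warning.
#' @export
aggregate_study <- function(results,
                            group_by = c("group", "condition", "model_id",
                                         "signal", "procedure")) {
  stopifnot(nrow(results) > 0, all(group_by %in% names(results)))
  keep <- is.finite(results$g)
  if (!all(keep)) warning(sprintf("aggregate_study: dropping %d rows with undefined G",
                                  sum(!keep)))
  results <- results[keep, , drop = FALSE]
  if (!nrow(results)) stop("aggregate_study: no rows with finite G")
  agg <- do.call(rbind, lapply(
    split(results, results[group_by], drop = TRUE), function(cell) {
      out <- cell[1, group_by, drop = FALSE]
      out$mean_G <- mean(cell$g)
      out$sd_G <- if (nrow(cell) > 1) stats::sd(cell$g) else 0
      out$n <- nrow(cell)
      out
    }))
  rownames(agg) <- NULL
  agg[do.call(order, agg[group_by]), , drop = FALSE]
}

#' Grouped bar chart of aggregated goodness values
#'
#' Mean G with SD error bars per condition and classifier, faceted by group
#' and phase model (requires ggplot2).
#'
#' @param agg Output of [aggregate_study()].
#' @return A ggplot object.
#' @export
plot_study <- function(agg) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_study requires ggplot2")
  agg$classifier <- paste(agg$procedure, agg$signal, sep = "_")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$condition, y = .data$mean_G,
                                    fill = .data$classifier)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_G - .data$sd_G,
                                        ymax = .data$mean_G + .data$sd_G),
                           position = ggplot2::position_dodge(width = 0.8),
                           width = 0.25) +
    ggplot2::facet_grid(group ~ model_id) +
    ggplot2::geom_hline(yintercept = c(0.25, 0.70), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(y = "Goodness index G", x = "Walking condition") +
    ggplot2::theme_minimal()
}
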