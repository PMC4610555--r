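test_that("footswitch combos reproduce the partitioning truth table", {
  # two-phase: any switch pressed -> stance, none -> swing
  singles <- list("heel", "m5", "m1", "toe")
  for (s in singles) expect_equal(classify_combo(s, "2P"), "SP")
  expect_equal(classify_combo(c("heel", "m5", "m1", "toe"), "2P"), "SP")
  expect_equal(classify_combo(character(), "2P"), "SW")

  # four-phase
  expect_equal(classify_combo(c("heel", "m5", "m1", "toe"), "4P"), "FF")
  expect_equal(classify_combo("heel", "4P"), "HS")
  for (s in list("m5", "m1", "toe", c("m5", "toe"), c("m5", "m1", "toe")))
    expect_equal(classify_combo(s, "4P"), "HO")
  expect_equal(classify_combo(character(), "4P"), "SW")

  # six-phase
  expect_equal(classify_combo("heel", "6P"), "IC")
  expect_equal(classify_combo(c("heel", "m5"), "6P"), "LR")
  expect_equal(classify_combo(c("heel", "m5", "m1"), "6P"), "MS")
  expect_equal(classify_combo(c("m5", "m1"), "6P"), "TS")
  expect_equal(classify_combo("toe", "6P"), "PS")
  expect_equal(classify_combo(character(), "6P"), "SW")
})

test_that("combo resolution is total, deterministic, and holds the previous phase on ties", {
  # ambiguous combo ({heel, toe} matches IC and PS equally) -> hold previous
  expect_equal(classify_combo(c("heel", "toe"), "6P", previous_phase = "MS"), "MS")
  # no previous -> the model's first phase
  expect_equal(classify_combo(c("heel", "toe"), phase_model("6P")), "IC")
  # specificity tier: supersets of a unique largest rule resolve to it
  expect_equal(classify_combo(c("heel", "m5", "m1", "toe"), "6P"), "MS")
  expect_equal(classify_combo(c("m5", "m1", "toe"), "6P"), "TS")

  for (m in c("2P", "4P", "6P")) {
    model <- phase_model(m)
    for (code in 0:15) {
      active <- c("heel", "m5", "m1", "toe")[bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0]
      for (prev in model$phases) {
        lab <- classify_combo(active, model, prev)
        expect_true(lab %in% model$phases)
        expect_identical(lab, classify_combo(active, model, prev))
      }
    }
  }
})

test_that("a scripted combo timeline partitions into the six phases in order", {
  combos <- list("heel", c("heel", "m5"), c("heel", "m5", "m1"),
                 c("m5", "m1"), "toe", character())
  ch <- matrix(0, 60, 4, dimnames = list(NULL, c("heel", "m5", "m1", "toe")))
  for (i in seq_len(60)) ch[i, combos[[ceiling(i / 10)]]] <- 1
  fs <- footswitch_signal(ch[, 1], ch[, 2], ch[, 3], ch[, 4], fs_hz = 50)
  seq6 <- partition_trial(fs, "6P", target_fs_hz = 50)
  expect_equal(rle(seq6$labels)$values, c("IC", "LR", "MS", "TS", "PS", "SW"))
  expect_equal(rle(seq6$labels)$lengths, rep(10, 6))

  zero <- footswitch_signal(rep(0, 50), rep(0, 50), rep(0, 50), rep(0, 50),
                            fs_hz = 50)
  expect_true(all(partition_trial(zero, "2P", 50)$labels == "SW"))
  expect_error(partition_trial(footswitch_signal(numeric(0), numeric(0),
                                                 numeric(0), numeric(0)),
                               "2P"), "empty")
})

test_that("partitioning the generator's footswitch output recovers its script exactly", {
  for (strict in c(FALSE, TRUE)) {
    tr <- clean_trial(duration_s = 15, seed = 5,
                      template = gait_template(strict_switches = strict))
    ref <- trial_ref(tr, "6P")
    expect_identical(ref$labels, attr(tr, "script")$labels)
    # noise-free scripts never require the hold-previous fallback
    tab <- combo_table(phase_model("6P"))
    ch <- align_footswitch_to_gyro(tr$footswitch, 50,
                                   signal_times(tr$gyro_foot))$channels
    codes <- 1 + ch[, 1] + 2 * ch[, 2] + 4 * ch[, 3] + 8 * ch[, 4]
    expect_false(anyNA(tab[codes]))
  }
})

test_that("transition events sit on the first sample of each new phase", {
  const <- phase_sequence(rep("SP", 10), "2P")
  expect_equal(nrow(transitions(const)), 0)

  seqp <- phase_sequence(c("SP", "SP", "SW", "SW", "SP"), "2P")
  ev <- transitions(seqp)
  expect_equal(ev$sample_index, c(3, 5))
  expect_equal(ev$from_phase, c("SP", "SW"))
  expect_equal(ev$to_phase, c("SW", "SP"))

  tr <- clean_trial(duration_s = 60, seed = 2)
  ref2 <- trial_ref(tr, "2P")
  n_cycles <- 60 / (60 / gait_template()$cadence_spm)
  expect_equal(nrow(transitions(ref2)), 2 * n_cycles, tolerance = 0.06)
})

test_that("cycle segmentation is consistent with transition events", {
  expect_warning(out <- segment_cycles(phase_sequence(rep("SP", 20), "2P")),
                 "fewer than 2")
  expect_length(out, 0)

  labels <- rep(rep(c("SP", "SW"), 3), each = 10)
  starts <- segment_cycles(phase_sequence(labels, "2P"))
  expect_equal(starts, c(21, 41))

  tr <- clean_trial(duration_s = 30, seed = 9)
  ref <- trial_ref(tr, "6P")
  st <- segment_cycles(ref)
  expect_true(all(st %in% transitions(ref)$sample_index))
  expect_equal(length(st), length(segment_cycles(trial_ref(tr, "2P"))))
})

test_that("phase sequences round-trip through CSV", {
  tr <- clean_trial(duration_s = 12)
  ref <- trial_ref(tr, "4P")
  path <- withr::local_tempfile(fileext = ".csv")
  write_phase_csv(ref, path)
  back <- read_phase_csv(path, "4P")
  expect_identical(back$labels, ref$labels)
  expect_equal(back$fs_hz, ref$fs_hz, tolerance = 1e-9)
})
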