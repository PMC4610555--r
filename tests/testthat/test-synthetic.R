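test_that("a generated cycle is internally consistent", {
  tpl <- gait_template()
  cyc <- generate_cycle(tpl)
  expect_equal(length(cyc$foot), cyc$stride_samples)
  expect_equal(nrow(cyc$fsw), 4 * cyc$stride_samples)
  expect_setequal(unique(cyc$script), c("IC", "LR", "MS", "TS", "PS", "SW"))
  # script appears in cycle order
  expect_equal(rle(cyc$script)$values, c("IC", "LR", "MS", "TS", "PS", "SW"))

  # determinism without jitter: consecutive cycles identical
  set.seed(1)
  tr <- generate_trial(tpl, duration_s = 10, timing_jitter_sd = 0,
                       amp_jitter_sd = 0, noise_sd = 0)
  n <- cyc$stride_samples
  expect_equal(tr$gyro_foot$values[1:n], tr$gyro_foot$values[(n + 1):(2 * n)])

  # a phase squeezed below 2 samples is refused
  squeezed <- gait_template(fractions = c(IC = 0.005, LR = 0.155, MS = 0.19,
                                          TS = 0.15, PS = 0.10, SW = 0.40))
  expect_error(generate_cycle(squeezed), "shorter than 2 samples")
})

test_that("cycle counts follow cadence and duration", {
  tpl <- gait_template(cadence_spm = 40)
  set.seed(2)
  tr <- generate_trial(tpl, duration_s = 60, timing_jitter_sd = 0,
                       amp_jitter_sd = 0, noise_sd = 0)
  ref <- trial_ref(tr, "6P")
  n_cycles <- length(segment_cycles(ref)) + 1L   # starts exclude the first cycle
  expect_gte(n_cycles, 39)
  expect_lte(n_cycles, 41)
})

test_that("realized phase fractions match the template over many strides", {
  set.seed(3)
  tpl <- gait_template()
  counts <- setNames(numeric(6), names(tpl$fractions))
  n_strides <- 0
  while (n_strides < 1000) {
    stride_s <- (60 / tpl$cadence_spm) * max(1 + rnorm(1, 0, 0.03), 0.5)
    cyc <- generate_cycle(tpl, stride_s)
    counts <- counts + table(factor(cyc$script, levels = names(counts)))
    n_strides <- n_strides + 1
  }
  realized <- counts / sum(counts)
  expect_true(all(abs(realized - tpl$fractions) < 0.02))
})

test_that("a generated cohort is reproducible and carries the design structure", {
  spec <- cohort_spec(n_subjects = 3, group = "TD", duration_s = 15, seed = 5)
  coh <- generate_cohort(spec)
  expect_equal(length(coh$trials), 3 * 4 * 2)
  expect_setequal(unique(vapply(coh$trials, function(t) t$condition,
                                character(1))),
                  c("L1.0", "L1.5", "I1.0", "I1.5"))
  coh_b <- generate_cohort(spec)
  k <- names(coh$trials)[5]
  expect_identical(coh$trials[[k]]$gyro_foot$values,
                   coh_b$trials[[k]]$gyro_foot$values)
  expect_identical(coh$trials[[k]]$footswitch$channels,
                   coh_b$trials[[k]]$footswitch$channels)
})

test_that("hemiplegic cohorts have higher stride-time variability than TD", {
  stride_cv <- function(coh) {
    cvs <- vapply(coh$trials, function(tr) {
      st <- segment_cycles(trial_ref(tr, "2P"))
      d <- diff(st)
      stats::sd(d) / mean(d)
    }, numeric(1))
    mean(cvs)
  }
  td <- generate_cohort(cohort_spec(n_subjects = 4, group = "TD",
                                    conditions = "L1.0", duration_s = 30,
                                    seed = 6))
  hc <- generate_cohort(cohort_spec(n_subjects = 4, group = "HC",
                                    conditions = "L1.0", duration_s = 30,
                                    seed = 7))
  expect_gt(stride_cv(hc), stride_cv(td))
})

test_that("subject-specific training on clean cohorts reaches near-perfect goodness", {
  base <- gait_template()
  set.seed(8)
  mk <- function(rep_i) generate_trial(base, duration_s = 30,
                                       timing_jitter_sd = 0, amp_jitter_sd = 0,
                                       noise_sd = 0, repetition = rep_i)
  tr1 <- mk(1); tr2 <- mk(2)
  clf <- train_sst(classifier_spec("SST", "2P", "ft"), tr1)
  pred <- classify_scalar(clf, lowpass_filter(tr2$gyro_foot))$sequence
  expect_lte(evaluate_sequences(pred, trial_ref(tr2, "2P"))$g, 0.1)
})

test_that("rotating the angular-velocity vector emulates IMU misalignment", {
  set.seed(9)
  tr <- generate_trial(gait_template(), duration_s = 15, mode = "3axis",
                       noise_sd = 0, timing_jitter_sd = 0, amp_jitter_sd = 0)
  same <- perturb_rotation(tr, c(0, 0))
  expect_equal(same$gyro_foot$values, tr$gyro_foot$values, tolerance = 1e-12)

  # with zero off-sagittal components, a frontal-axis rotation scales by cos
  tpl0 <- gait_template(offaxis_scale = c(0, 0))
  set.seed(10)
  tr0 <- generate_trial(tpl0, duration_s = 15, mode = "3axis", noise_sd = 0,
                        timing_jitter_sd = 0, amp_jitter_sd = 0)
  rot <- perturb_rotation(tr0, c(2, 0))
  expect_equal(rot$gyro_foot$values, cos(2 * pi / 180) * tr0$gyro_foot$values,
               tolerance = 1e-9)
  # footswitch untouched
  expect_identical(rot$footswitch$channels, tr0$footswitch$channels)

  sag_only <- clean_trial(duration_s = 12)
  expect_error(perturb_rotation(sag_only, c(2, 2)), "3-axis")
})

test_that("a small mounting rotation barely changes classifier goodness", {
  set.seed(11)
  tpl <- gait_template()
  tr1 <- generate_trial(tpl, duration_s = 30, mode = "3axis", repetition = 1)
  tr2 <- generate_trial(tpl, duration_s = 30, mode = "3axis", repetition = 2)
  clf <- train_sst(classifier_spec("SST", "2P", "ft"), tr1)
  ref <- trial_ref(tr2, "2P")
  g_base <- evaluate_sequences(
    classify_scalar(clf, lowpass_filter(tr2$gyro_foot))$sequence, ref)$g
  rot <- perturb_rotation(tr2, c(2, 2))
  g_rot <- evaluate_sequences(
    classify_scalar(clf, lowpass_filter(rot$gyro_foot))$sequence, ref)$g
  expect_lte(abs(g_rot - g_base), 0.1)
})
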