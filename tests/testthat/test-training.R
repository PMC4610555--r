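test_that("the classifier factory enumerates the full factorial design", {
  specs <- enumerate_classifiers()
  expect_equal(nrow(specs), 18)
  expect_equal(anyDuplicated(specs$code), 0)
  expect_true("SPT_2P_sh_SC" %in% specs$code)
  expect_true("S2pPTshSC" %in% specs$short_code)
  expect_true("S6pSTftshDC" %in% specs$short_code)
  expect_true(all(specs$kind[specs$signal == "ftsh"] == "DC"))
  expect_true(all(specs$kind[specs$signal != "ftsh"] == "SC"))
  expect_false(any(specs$signal == "ftsh" & specs$kind == "SC"))
  expect_equal(sum(specs$procedure == "SST"), 9)

  sp <- classifier_spec("SPT", "4P", "ftsh")
  expect_equal(sp$kind, "DC")
  expect_equal(sp$code, "SPT_4P_ftsh_DC")
  expect_equal(as_classifier_spec("SST_6P_sh_SC")$model_id, "6P")
})

test_that("emission initialization normalizes occurrences before pooling", {
  # two occurrences of SP with values {1,1} and {3,3}: mean 2, ensemble sd
  gy <- gyro_signal(c(1, 1, 9, 9, 3, 3), "foot", fs_hz = 50)
  ref <- phase_sequence(c("SP", "SP", "SW", "SW", "SP", "SP"), "2P", fs_hz = 50)
  em <- init_emissions(gy, ref, L_norm = 2)
  expect_equal(unname(em$mu["SP"]), 2)
  expect_equal(unname(em$sigma["SP"]), sd(c(1, 1, 3, 3)))
  expect_equal(unname(em$durations["SP"]), 2)

  # equal weighting: occurrence duration does not bias the mean
  gy2 <- gyro_signal(c(rep(1, 8), 9, 9, 3, 3), "foot", fs_hz = 50)
  ref2 <- phase_sequence(c(rep("SP", 8), "SW", "SW", "SP", "SP"), "2P", fs_hz = 50)
  em2 <- init_emissions(gy2, ref2, L_norm = 10)
  expect_equal(unname(em2$mu["SP"]), 2)

  # zero-variance phase gets the variance floor, never sd 0
  gy3 <- gyro_signal(c(5, 5, 7, 7), "foot", fs_hz = 50)
  ref3 <- phase_sequence(c("SP", "SP", "SW", "SW"), "2P", fs_hz = 50)
  expect_gt(min(init_emissions(gy3, ref3)$sigma), 0)

  ref4 <- phase_sequence(rep("SP", 6), "2P", fs_hz = 50)
  expect_error(init_emissions(gy, ref4), "'SW' absent")
})

test_that("subject-specific training learns repetition 1 and generalizes to repetition 2", {
  tr1 <- noisy_trial(duration_s = 30, seed = 31, repetition = 1)
  tr2 <- noisy_trial(duration_s = 30, seed = 32, repetition = 2)

  clf <- train_sst(classifier_spec("SST", "2P", "ft"), tr1)
  pred <- classify_scalar(clf, lowpass_filter(tr2$gyro_foot))$sequence
  ev <- evaluate_sequences(pred, trial_ref(tr2, "2P"))
  expect_lte(ev$g, 0.25)

  # protocol guards
  expect_error(train_sst(classifier_spec("SPT", "2P", "ft"), tr1), "SST")
  expect_error(train_sst(classifier_spec("SST", "2P", "ft"), tr2),
               "repetition 1")

  dc <- train_sst(classifier_spec("SST", "6P", "ftsh"), tr1)
  expect_s3_class(dc, "distributed_classifier")
  expect_equal(dc$members$ft$signal_source, "ft")
  expect_equal(dc$members$sh$signal_source, "sh")
  expect_true(all(dc$members$ft$params$A[dc$members$ft$params$struct_zero] == 0))
})

test_that("the inter-subject template honours leave-one-out", {
  coh <- generate_cohort(cohort_spec(n_subjects = 5, conditions = "L1.0",
                                     duration_s = 20, seed = 41))
  tpl_all <- build_spt_template(coh, "L1.0")
  expect_length(tpl_all$included, 5)
  tpl_loo <- build_spt_template(coh, "L1.0", exclude_subject = "TD03")
  expect_length(tpl_loo$included, 4)
  expect_false("TD03" %in% tpl_loo$included)
  expect_length(tpl_loo$foot, tpl_loo$L_cycle)
  expect_true(all(tpl_loo$foot_sd >= 0))
  expect_true(all(c("2P", "4P", "6P") %in% names(tpl_loo$scripts)))

  coh2 <- generate_cohort(cohort_spec(n_subjects = 2, conditions = "L1.0",
                                      duration_s = 20, seed = 42))
  expect_error(build_spt_template(coh2, "L1.0", exclude_subject = "TD01"),
               "fewer than 2")
  expect_error(build_spt_template(coh, "L1.0", exclude_subject = "ZZ"),
               "not in cohort")
})

test_that("a template of identical subjects equals any one subject's cycle", {
  base <- gait_template()
  set.seed(43)
  trials <- list()
  for (s in 1:3) for (r in 1:2)
    trials[[length(trials) + 1L]] <- generate_trial(
      base, duration_s = 20, timing_jitter_sd = 0, amp_jitter_sd = 0,
      noise_sd = 0, subject_id = sprintf("TD%02d", s), condition = "L1.0",
      repetition = r)
  coh <- gait_cohort(trials)
  tpl <- build_spt_template(coh, "L1.0")
  one <- clean_trial(duration_s = 20, condition = "L1.0")
  ref <- trial_ref(one, "2P")
  starts <- segment_cycles(ref)
  cyc <- lowpass_filter(one$gyro_foot)$values[starts[1]:(starts[2] - 1)]
  cyc_n <- approx(seq_along(cyc), cyc, xout = seq(1, length(cyc),
                                                  length.out = 200))$y
  expect_equal(tpl$foot, cyc_n, tolerance = 0.02)
  expect_lt(max(tpl$foot_sd), 1)
})

test_that("standardized-parameter training uses only the template cohort", {
  coh <- generate_cohort(cohort_spec(n_subjects = 4, conditions = "L1.0",
                                     duration_s = 20, seed = 44))
  clf <- train_spt(classifier_spec("SPT", "4P", "ft"), coh, "L1.0",
                   exclude_subject = "TD02")
  expect_s3_class(clf, "scalar_classifier")
  expect_false("TD02" %in% clf$meta$included)
  expect_equal(clf$meta$excluded, "TD02")
  expect_true(all(clf$params$A[clf$params$struct_zero] == 0))
  expect_equal(clf$params$n_states, 4)

  dc <- train_spt(classifier_spec("SPT", "2P", "ftsh"), coh, "L1.0")
  expect_s3_class(dc, "distributed_classifier")
  expect_error(train_spt(classifier_spec("SST", "2P", "ft"), coh, "L1.0"),
               "SPT")
})

test_that("the study runner trains per protocol, evaluates repetition 2, and audits", {
  coh <- generate_cohort(list(
    cohort_spec(n_subjects = 3, group = "TD", conditions = "L1.0",
                duration_s = 20, seed = 45),
    cohort_spec(n_subjects = 3, group = "HC", conditions = "L1.0",
                duration_s = 20)))
  specs <- enumerate_classifiers()
  specs <- specs[specs$model_id == "2P", ]
  res <- run_study(coh, specs)
  expect_equal(nrow(res), nrow(specs) * 6 * 1)
  expect_true(all(res$g >= 0 & res$g <= sqrt(2), na.rm = TRUE))
  expect_setequal(unique(res$spec), specs$code)

  # SPT leave-one-out: TD subjects never appear in their own template
  audit <- attr(res, "spt_audit")
  expect_true(length(audit) >= 1)
  for (key in names(audit)) {
    exc <- sub("^.* ", "", key)
    if (exc != "none") expect_false(exc %in% audit[[key]])
  }
  # HC rows are evaluated against the all-TD template
  expect_true("L1.0 none" %in% names(audit))
  expect_length(audit[["L1.0 none"]], 3)

  # determinism: regenerating the same cohort gives the identical table
  coh_b <- generate_cohort(list(
    cohort_spec(n_subjects = 3, group = "TD", conditions = "L1.0",
                duration_s = 20, seed = 45),
    cohort_spec(n_subjects = 3, group = "HC", conditions = "L1.0",
                duration_s = 20)))
  res_b <- run_study(coh_b, specs)
  expect_equal(res$g, res_b$g)

  # a missing repetition is skipped with a warning
  coh3 <- coh
  coh3$trials[["TD01|L1.0|2"]] <- NULL
  expect_warning(res3 <- run_study(coh3, specs), "missing repetition")
  expect_equal(nrow(res3), nrow(specs) * 5)
})
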