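test_that("ground-truth sheet construction, determinism and validation", {
  sh <- make_ground_truth_sheet(sheet_spec(), seed = 7)
  expect_true(all(diff(sh$digit_centres) > 0))
  expect_true(all(sh$roi_mask[, round(sh$digit_centres) + 1]))
  expect_identical(sh, make_ground_truth_sheet(sheet_spec(), seed = 7))
  expect_error(make_ground_truth_sheet(
    sheet_spec(digit_centres = c(D2 = 30, D3 = 20, D4 = 65, D5 = 85))),
    "ordered")
  expect_error(make_ground_truth_sheet(sheet_spec(tuning_width = -1)),
               "positive")
  expect_error(make_ground_truth_sheet(
    sheet_spec(grid_shape = c(4, 50))), "margin")
})

test_that("session effects shift only D4 and preserve ordering", {
  sh <- make_ground_truth_sheet(small_sheet_spec(), seed = 1)
  same <- apply_session_effect(sh, session_effect("control1", 0, 0))
  expect_equal(same$digit_centres, sh$digit_centres)
  shifted <- apply_session_effect(sh, session_effect("glued", 4, 0))
  expect_equal(unname(shifted$digit_centres["D4"] - sh$digit_centres["D4"]), 4)
  expect_equal(shifted$digit_centres[c("D2", "D3", "D5")],
               sh$digit_centres[c("D2", "D3", "D5")])
  expect_equal(shifted$tuning_width, sh$tuning_width)
  expect_error(apply_session_effect(sh, session_effect("glued", 30, 0)),
               "ordering")
  expect_error(session_effect("control1", d4_shift_mm = 2),
               "control")
})

test_that("phase-encoding simulation matches the travelling-wave model", {
  sh <- make_ground_truth_sheet(small_sheet_spec(rows = 1), seed = 1)
  ts <- simulate_phase_run(sh, task_design("phase_forward"), noiseless(), 1)
  stack <- compute_lag_correlation_stack(ts)
  cm <- somatomap:::vertex_col_mm(sh)
  # a vertex at the D2 centre peaks at an early-cycle lag with r > 0.99
  v2 <- which.min(abs(cm - sh$digit_centres["D2"]))
  expect_gt(max(stack$r[v2, ]), 0.99)
  best_f <- stack$lags_s[apply(stack$r, 1, which.max)]
  # forward vs backward: best-lag ordering of digit-centre vertices reverses
  ts_b <- simulate_phase_run(sh, task_design("phase_backward"), noiseless(), 1)
  stack_b <- compute_lag_correlation_stack(ts_b)
  best_b <- stack_b$lags_s[apply(stack_b$r, 1, which.max)]
  centres_idx <- vapply(sh$digit_centres, function(mu) which.min(abs(cm - mu)),
                        integer(1))
  expect_true(all(diff(best_f[centres_idx]) > 0))
  expect_true(all(diff(best_b[centres_idx]) < 0))
  # zero amplitude leaves pure noise + drift
  sh0 <- make_ground_truth_sheet(small_sheet_spec(rows = 1), seed = 1)
  sh0$amplitude <- 0
  ts0 <- simulate_phase_run(sh0, task_design("phase_forward"),
                            noise_spec(sd = 1, drift_range = 0.5), 3)
  regs <- somatomap:::digit_regressors(task_design("phase_forward"))
  r0 <- abs(stats::cor(t(ts0$data), t(regs)))
  expect_lt(stats::quantile(r0, 0.99), 0.3)
  expect_error(simulate_phase_run(sh, task_design("block")), "phase")
  expect_error(noise_spec(sd = -1), "non-negative")
})

test_that("block-design simulation has the right duration and GLM structure", {
  d <- task_design("block")
  expect_identical(d$n_timepoints, 256L)
  sh <- make_ground_truth_sheet(small_sheet_spec(rows = 1), seed = 1)
  ts <- simulate_block_run(sh, d, noiseless(), 1)
  glm <- fit_block_glm(ts)
  amps <- somatomap:::tuning_amplitudes(sh)
  expect_equal(unname(glm$betas), unname(amps), tolerance = 1e-8)
  expect_lt(max(glm$residual_var), 1e-16)
  # equal tuning across digits at a vertex gives equal betas
  mid <- which.min(abs(somatomap:::vertex_col_mm(sh) - 55))
  sh2 <- sh
  ampfun <- somatomap:::tuning_amplitudes
  expect_equal(stats::sd(glm$betas[mid, ]) / mean(glm$betas[mid, ]),
               stats::sd(amps[mid, ]) / mean(amps[mid, ]), tolerance = 1e-6)
})

test_that("TOJ simulation follows the logistic observer", {
  obs <- toj_observer(pse_ms = 0, true_jnd_ms = 60, lapse_rate = 0)
  run <- simulate_toj_run(obs, isi_schedule = rep(400, 4000), seed = 1)
  expect_gt(mean(run$right_first), 0.98)
  run0 <- simulate_toj_run(obs, isi_schedule = rep(0, 4000), seed = 1)
  expect_lt(abs(mean(run0$right_first) - 0.5), 0.03)
  expect_error(simulate_toj_run(obs, isi_schedule = numeric(0)), "empty")
  expect_error(toj_observer(true_jnd_ms = -5), "positive")
  # default schedule: 12 ISIs x 16 repetitions
  run_def <- simulate_toj_run(obs, seed = 2)
  expect_equal(nrow(run_def), 192)
  expect_equal(as.vector(table(run_def$isi_ms)), rep(16L, 12))
})

test_that("confusion simulation respects the cue-sequence constraints", {
  for (s in 1:50) {
    cue <- somatomap:::confusion_cue_sequence(210, seed = s)
    expect_equal(length(cue), 210)
    expect_true(all(diff(cue) != 0))
  }
  # balanced ordered pairings in the Eulerian part
  cue <- somatomap:::confusion_cue_sequence(205, seed = 1)
  trans <- table(head(cue, 204), tail(cue, 204))
  expect_true(max(trans) - min(trans[trans > 0]) <= 2)
  pure <- confusion_spec(diag(4), omission_rate = 0)
  trials <- simulate_confusion_run(pure, n_blocks = 1, seed = 1)
  sc <- score_confusion(trials)
  expect_equal(sum(sc$mispress$count), 0)
  expect_equal(sc$n_omission, 0)
  expect_error(confusion_spec(matrix(1, 4, 4)), "stochastic")
})

test_that("higher D4->D5 confusion probability raises D4-D5 mis-presses", {
  hi <- confusion_spec(default_confusion_matrix(d4d5_boost = 0.15))
  lo <- confusion_spec(default_confusion_matrix())
  diffs <- vapply(1:10, function(s) {
    m_hi <- score_confusion(simulate_confusion_run(hi, 1, seed = s))
    m_lo <- score_confusion(simulate_confusion_run(lo, 1, seed = s + 100))
    m_hi$mispress$count[3] - m_lo$mispress$count[3]
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("cohort generation is counterbalanced and reproducible", {
  spec <- cohort_spec(n_subjects = 9, seed = 11,
                      sheet = small_sheet_spec(rows = 2))
  expect_equal(sum(spec$order == "A"), 4)   # 4 subjects order A, 5 order B
  expect_equal(sum(spec$order == "B"), 5)
  a <- cohort_session_data(spec, 3, "glued")
  b <- cohort_session_data(spec, 3, "glued")
  expect_identical(a, b)
  expect_gt(a$sheet$digit_centres["D4"],
            cohort_session_data(spec, 3, "control1")$sheet$digit_centres["D4"] +
              spec$d4_shift_mm - 3 * spec$centre_jitter_sd_mm)
  expect_error(cohort_spec(n_subjects = 1), "at least 2")
  small <- cohort_spec(n_subjects = 2, seed = 4,
                       sheet = small_sheet_spec(rows = 2))
  coh <- generate_cohort(small)
  expect_length(coh$subjects, 2)
  expect_named(coh$subjects[[1]]$sessions,
               c("control1", "control2", "glued"))
})
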