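test_that("each outlier criterion removes exactly the offending trials", {
  rot <- grid_rotations(1)
  tr <- make_trials("BiHand", rot, hand = rep(90, 8), judged = rep(90, 8))
  tr$judged_angle_deg[1] <- tr$true_hand_angle_deg[1] + 36  # criterion 3
  tr$ring_drift_deg[2] <- 3.0                               # criterion 1
  tr$direction_deviation_deg[3] <- 40                       # criterion 2

  res <- filter_outliers(tr)
  expect_equal(nrow(res$kept), 5)
  # reasons follow row order: rows 1..3 violate criteria 3, 1, 2
  expect_equal(res$removed$reason, c(3L, 1L, 2L))
  expect_equal(res$report$n_crit1, 1)
  expect_equal(res$report$n_crit2, 1)
  expect_equal(res$report$n_crit3, 1)
  expect_equal(res$report$n_removed + nrow(res$kept), nrow(tr))

  # boundary values are kept (criteria are strict inequalities)
  clean <- make_trials("BiHand", rot, hand = rep(90, 8), judged = rep(90, 8))
  clean$ring_drift_deg[1] <- 2.5
  clean$direction_deviation_deg[2] <- 35
  clean$judged_angle_deg[3] <- clean$true_hand_angle_deg[3] + 35
  expect_equal(nrow(filter_outliers(clean)$kept), 8)
})

test_that("first-matching-criterion tagging and order independence", {
  tr <- make_trials("BiCursor", grid_rotations(1), hand = rep(90, 8),
                    judged = rep(90, 8) + grid_rotations(1))
  tr$ring_drift_deg[1] <- 5
  tr$direction_deviation_deg[1] <- 50  # violates 1 and 2; tagged as 1
  res <- filter_outliers(tr)
  expect_equal(res$removed$reason, 1L)

  # shuffling rows does not change which trials are removed
  set.seed(1)
  perm <- sample(nrow(tr))
  res_perm <- filter_outliers(tr[perm, ])
  expect_setequal(res_perm$removed$rotation_deg, res$removed$rotation_deg)
})

test_that("filter removes injected contamination exactly", {
  params <- generative_params()
  sess <- build_session(design_spec(), seed = 21)
  tr <- generate_trials(sess, params, condition = "Dyn", seed = 21)
  tr <- inject_outliers(tr, c(drift = 0.03, direction = 0.03,
                              judgment = 0.03), seed = 22)
  res <- filter_outliers(tr)
  expect_equal(sort(res$removed$session_index),
               sort(tr$session_index[tr$outlier_injected]))
  expect_equal(res$removed$reason,
               res$removed$outlier_criterion)
})

test_that("missing columns raise an informative error", {
  tr <- make_trials("BiHand", grid_rotations(1), hand = rep(90, 8),
                    judged = rep(90, 8))
  expect_error(filter_outliers(dplyr::select(tr, -ring_drift_deg)),
               "ring_drift_deg")
})

test_that("hysteresis fit recovers slope and dual intercepts", {
  rot <- grid_rotations(2)
  hand <- seq(30, 150, length.out = 16)
  # identity data: slope 1, both intercepts 0
  tr <- make_trials("UniHand", rot, hand, judged = hand)
  fit <- fit_hysteresis(tr)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept_left, 0, tolerance = 1e-10)
  expect_equal(fit$intercept_right, 0, tolerance = 1e-10)

  # constructed +/- 2 degree side offsets: difference exactly 4
  side <- rep_len(c("left", "right"), 16)
  judged <- hand + ifelse(side == "right", 2, -2)
  tr <- make_trials("UniHand", rot, hand, judged, side = side)
  fit <- fit_hysteresis(tr)
  expect_equal(fit$intercept_difference, 4, tolerance = 1e-10)
  expect_equal(fit$intercept_right - fit$intercept_left,
               fit$intercept_difference)

  expect_error(
    fit_hysteresis(make_trials("UniHand", rot, hand, hand,
                               side = rep("left", 16))),
    "start side"
  )
})

test_that("hysteresis fit recovers a simulated offset at session scale", {
  params <- generative_params(hysteresis_offset_deg = 3,
                              outlier_rate = c(drift = 0, direction = 0,
                                               judgment = 0))
  sess <- build_session(design_spec(), seed = 23)
  tr <- generate_trials(sess, params, condition = "Dyn", seed = 23)
  fit <- fit_hysteresis(tr)
  expect_equal(fit$n_trials, 320)
  expect_gt(fit$intercept_difference, 2.0)
  expect_lt(fit$intercept_difference, 4.0)
})

test_that("hysteresis correction is exact and idempotent", {
  rot <- grid_rotations(2)
  hand <- seq(30, 150, length.out = 16)
  side <- rep_len(c("left", "right"), 16)
  judged <- hand + ifelse(side == "right", 2, -2)
  tr <- make_trials("UniHand", rot, hand, judged, side = side)
  fit <- fit_hysteresis(tr)
  corr <- correct_hysteresis(tr, fit)
  # d = 4, right-start judged 94 -> corrected 92
  expect_equal(corr$judged_corrected_deg, hand, tolerance = 1e-10)
  expect_equal(corr$true_hand_angle_deg, tr$true_hand_angle_deg)

  # zero difference leaves judgments unchanged
  tr0 <- make_trials("UniHand", rot, hand, judged = hand + 1)
  fit0 <- fit_hysteresis(tr0)
  corr0 <- correct_hysteresis(tr0, fit0)
  expect_equal(corr0$judged_corrected_deg, corr0$judged_angle_deg,
               tolerance = 1e-10)

  # simulated session with h = 4: refit on corrected data is ~zero
  params <- generative_params(hysteresis_offset_deg = 4,
                              outlier_rate = c(drift = 0, direction = 0,
                                               judgment = 0))
  sess <- build_session(design_spec(), seed = 24)
  sim <- generate_trials(sess, params, condition = "Dyn", seed = 24)
  fit <- fit_hysteresis(sim)
  corrected <- correct_hysteresis(sim, fit)
  corrected$judged_angle_deg <- corrected$judged_corrected_deg
  refit <- fit_hysteresis(corrected)
  expect_lt(abs(refit$intercept_difference), 1e-9)
})

test_that("preprocess_trials pools per participant x condition", {
  params <- generative_params()
  tr <- simulate_cohort(params, n_participants = 2, seed = 25)
  pp <- preprocess_trials(tr)
  expect_equal(nrow(pp$hysteresis), 6)  # 2 participants x 3 conditions
  expect_true("judged_corrected_deg" %in% names(pp$trials))
  expect_equal(nrow(pp$trials) + nrow(pp$removed), nrow(tr))
  # with default contamination rates the total exclusion fraction is small
  expect_lt(sum(pp$filter_report$n_removed) / nrow(tr), 0.025)
  # correction shifts judgments by at most |d|/2 per trial
  shift <- abs(pp$trials$judged_corrected_deg - pp$trials$judged_angle_deg)
  max_d <- max(abs(pp$hysteresis$intercept_difference))
  expect_true(all(shift <= max_d / 2 + 1e-12))
})
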