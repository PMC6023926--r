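test_that("derive_observable_params matches the coupling model", {
  d <- derive_observable_params(1, 1, 1)
  expect_equal(d$w_H, 0.5)
  expect_equal(d$w_C, 0.5)

  # lambda = 0.5, equal unit SDs: weights 0.25, bimodal SD sqrt(0.75)
  d <- derive_observable_params(1, 1, 0.5)
  expect_equal(d$w_H, 0.25)
  expect_equal(d$w_C, 0.25)
  expect_equal(d$sd_BiCursor, sqrt(0.75))
  expect_equal(d$sd_BiHand, sqrt(0.75))

  # classic reliability weighting at fusion: sigma_H = 2, sigma_C = 1
  d <- derive_observable_params(2, 1, 1)
  expect_equal(d$w_C, 4 / 5)
  expect_equal(d$w_H, 1 / 5)

  # weight sum equals lambda over random parameters
  set.seed(3)
  for (i in 1:50) {
    lam <- runif(1, 0.05, 1)
    d <- derive_observable_params(runif(1, 0.5, 8), runif(1, 0.5, 8), lam)
    expect_equal(d$w_H + d$w_C, lam, tolerance = 1e-12)
  }

  expect_error(derive_observable_params(1, 1, 0), "lambda")
  expect_error(derive_observable_params(1, 1, -1), "lambda")
})

test_that("noise-free generator reproduces the bias structure exactly", {
  # zero SDs with lambda = 0.6: equal-share limit gives w_C = w_H = 0.3
  params <- generative_params(sigma_H_deg = 0, sigma_C_deg = 0,
                              lambda_true = 0.6,
                              hysteresis_offset_deg = 0,
                              outlier_rate = c(drift = 0, direction = 0,
                                               judgment = 0))
  sess <- build_session(design_spec(), seed = 2)
  tr <- generate_trials(sess, params, condition = "Dyn", seed = 2)

  bh <- tr[tr$trial_type == "BiHand", ]
  expect_equal(bh$judged_angle_deg - bh$true_hand_angle_deg,
               0.3 * bh$rotation_deg, tolerance = 1e-12)
  bc <- tr[tr$trial_type == "BiCursor", ]
  expect_equal(bc$judged_angle_deg - bc$true_cursor_angle_deg,
               0.3 * -bc$rotation_deg, tolerance = 1e-12)
  uh <- tr[tr$trial_type == "UniHand", ]
  expect_equal(uh$judged_angle_deg, uh$true_hand_angle_deg)
})

test_that("trial records respect the geometric invariants", {
  params <- generative_params()
  sess <- build_session(design_spec(), seed = 4)
  tr <- generate_trials(sess, params, condition = "End", seed = 4)

  bi <- tr[tr$trial_type != "UniHand", ]
  expect_equal(bi$true_cursor_angle_deg,
               bi$true_hand_angle_deg + bi$rotation_deg)
  expect_true(all(is.na(tr$true_cursor_angle_deg[tr$trial_type ==
                                                   "UniHand"])))
  expect_true(all(tr$rotation_deg %in% design_spec()$rotations_deg))
  # hand endpoints stay within +/- 8 deg of the instructed direction
  expect_true(all(tr$direction_deviation_deg <= 8))
  # UniCursor replays the endpoint angles of its source BiCursor slot
  uc <- tr[tr$trial_type == "UniCursor", ]
  src <- tr[match(sess$source_slot[sess$trial_type == "UniCursor"],
                  tr$session_index), ]
  expect_equal(uc$true_cursor_angle_deg, src$true_cursor_angle_deg)
  expect_true(all(tr$outward_duration_s >= 0 & tr$dwell_duration_s >= 0))
})

test_that("hysteresis offset is built in by construction", {
  params <- generative_params(sigma_H_deg = 0, sigma_C_deg = 0,
                              lambda_true = 0.6,
                              hysteresis_offset_deg = 4,
                              outlier_rate = c(drift = 0, direction = 0,
                                               judgment = 0))
  sess <- build_session(design_spec(), seed = 6)
  tr <- generate_trials(sess, params, condition = "Dyn", seed = 6)
  uh <- tr[tr$trial_type == "UniHand", ]
  offset <- uh$judged_angle_deg - uh$true_hand_angle_deg
  expect_equal(unique(offset[uh$marker_start_side == "right"]), 2)
  expect_equal(unique(offset[uh$marker_start_side == "left"]), -2)
  # equal counts: sides alternate across the session
  expect_equal(sum(tr$marker_start_side == "left"),
               sum(tr$marker_start_side == "right"))
})

test_that("judgment noise has the configured scale", {
  params <- generative_params(sigma_H_deg = 6, hysteresis_offset_deg = 0,
                              outlier_rate = c(drift = 0, direction = 0,
                                               judgment = 0))
  sess <- build_session(design_spec(), seed = 8)
  tr <- generate_trials(sess, params, condition = "Dyn", seed = 8)
  uh <- tr[tr$trial_type == "UniHand", ]
  expect_equal(nrow(uh), 80)
  s <- sd(uh$judged_angle_deg - uh$true_hand_angle_deg)
  # chi-square 99% coverage band for a sample SD at n = 80, sigma = 6
  expect_gt(s, 4.5)
  expect_lt(s, 7.5)
})

test_that("generator output is reproducible under a fixed seed", {
  params <- generative_params()
  sess <- build_session(design_spec(), seed = 10)
  expect_identical(
    generate_trials(sess, params, condition = "Dyn", seed = 11),
    generate_trials(sess, params, condition = "Dyn", seed = 11)
  )
  expect_error(
    generate_trials(dplyr::mutate(sess, trial_type = "Mystery"), params),
    "Unknown trial type"
  )
})

test_that("outlier injection modifies exactly the flagged trials", {
  params <- generative_params()
  sess <- build_session(design_spec(), seed = 12)
  tr <- generate_trials(sess, params, condition = "Dyn", seed = 12)

  # no-op at zero rates
  expect_identical(
    inject_outliers(tr, c(drift = 0, direction = 0, judgment = 0)),
    tr
  )

  tr100 <- tr[1:100, ]
  out <- inject_outliers(tr100, c(drift = 0, direction = 0, judgment = 0.1),
                         seed = 13)
  n_flagged <- sum(out$outlier_criterion == 3L)
  # 99% binomial band for Binomial(100, 0.1)
  expect_gte(n_flagged, 3)
  expect_lte(n_flagged, 18)
  err <- abs(out$judged_angle_deg -
               ifelse(out$trial_type %in% c("UniHand", "BiHand"),
                      out$true_hand_angle_deg, out$true_cursor_angle_deg))
  expect_true(all(err[out$outlier_criterion == 3L] > 35))
  expect_identical(out[!out$outlier_injected, ],
                   tr100[!out$outlier_injected, ])

  out1 <- inject_outliers(tr100, c(drift = 0.1, direction = 0,
                                   judgment = 0), seed = 14)
  expect_true(all(out1$ring_drift_deg[out1$outlier_criterion == 1L] > 2.5))
  out2 <- inject_outliers(tr100, c(drift = 0, direction = 0.1,
                                   judgment = 0), seed = 15)
  expect_true(all(out2$direction_deviation_deg[out2$outlier_criterion == 2L]
                  > 35))
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(generative_params(lambda_true = 0), "lambda")
  expect_error(generative_params(lambda_true = 1.5), "lambda")
  expect_error(generative_params(sigma_H_deg = -1))
  expect_error(generative_params(outlier_rate = c(drift = 0.5,
                                                  direction = 0,
                                                  judgment = 0)),
               "0.2")
})
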