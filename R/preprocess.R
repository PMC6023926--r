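#' Physical endpoint of the judged modality
#'
#' Hand trials (`UniHand`, `BiHand`) are judged against the physical hand
#' endpoint, cursor trials against the physical cursor endpoint.
#'
#' @param trials Trial tibble.
#' @return Numeric vector of own-modality physical angles (degrees).
#' @keywords internal
own_physical_angle <- function(trials) {
  ifelse(trials$trial_type %in% c("UniHand", "BiHand"),
         trials$true_hand_angle_deg, trials$true_cursor_angle_deg)
}

#' Screen trials with the three outlier criteria
#'
#' Removes trials that violate any of, in order: (1) hand moved more than
#' 2.5 degrees along the stopper ring before returning, (2) outward
#' movement direction deviated more than 35 degrees from the instructed
#' direction, (3) absolute deviation between judged and physical
#' own-modality endpoint larger than 35 degrees (twice the maximal
#' visuomotor rotation). Each removed trial is tagged with the first
#' criterion it matches; criteria are evaluated on raw per-trial fields
#' only, so the outcome is order-independent across trials.
#'
#' @param trials Trial tibble (any mix of participants/conditions).
#' @param thresholds Numeric thresholds for the three criteria.
#' @return A list with `kept` (retained rows, unchanged), `removed`
#'   (dropped rows plus a `reason` code 1/2/3), and `report` (a tibble of
#'   per participant x condition counts and fractions per criterion).
#' @export
filter_outliers <- function(trials,
                            thresholds = c(drift = 2.5, direction = 35,
                                           judgment = 35)) {
  needed <- c("trial_type", "ring_drift_deg", "direction_deviation_deg",
              "judged_angle_deg", "true_hand_angle_deg",
              "true_cursor_angle_deg")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols) > 0) {
    stop("Missing columns required by the outlier criteria: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  err <- abs(trials$judged_angle_deg - own_physical_angle(trials))
  reason <- dplyr::case_when(
    trials$ring_drift_deg > thresholds[["drift"]] ~ 1L,
    trials$direction_deviation_deg > thresholds[["direction"]] ~ 2L,
    err > thresholds[["judgment"]] ~ 3L,
    TRUE ~ 0L
  )
  removed <- trials[reason > 0L, , drop = FALSE]
  removed$reason <- reason[reason > 0L]

  grp <- trials
  grp$reason <- reason
  report <- grp |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("participant_id",
                                                  "condition")))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_crit1 = sum(.data$reason == 1L),
      n_crit2 = sum(.data$reason == 2L),
      n_crit3 = sum(.data$reason == 3L),
      n_removed = sum(.data$reason > 0L),
      fraction_removed = .data$n_removed / .data$n_trials,
      .groups = "drop"
    )
  list(kept = trials[reason == 0L, , drop = FALSE],
       removed = removed, report = report)
}

#' Fit the dual-intercept hysteresis regression
#'
#' Position judgments can carry a left/right offset depending on where
#' the response marker started its clockwise or anti-clockwise sweep. The
#' offset is estimated, per participant and visibility condition, by
#' regressing judged on physical own-modality positions with a single
#' shared slope but separate intercepts for left- and right-start trials.
#'
#' @param trials Trials of one participant x condition (all trial types
#'   pooled), with a `marker_start_side` column of `"left"`/`"right"`.
#' @return An object of class `hysteresis_fit` with fields `slope`,
#'   `intercept_left`, `intercept_right`, `intercept_difference`
#'   (right minus left, degrees) and `n_trials`.
#' @export
fit_hysteresis <- function(trials) {
  side <- trials$marker_start_side
  if (sum(side == "left") < 2 || sum(side == "right") < 2) {
    stop("Need at least two trials per marker start side for the ",
         "hysteresis fit.", call. = FALSE)
  }
  df <- data.frame(
    judged = trials$judged_angle_deg,
    physical = own_physical_angle(trials),
    right = as.integer(side == "right")
  )
  fit <- stats::lm(judged ~ physical + right, data = df)
  b <- stats::coef(fit)
  structure(
    list(slope = unname(b[["physical"]]),
         intercept_left = unname(b[["(Intercept)"]]),
         intercept_right = unname(b[["(Intercept)"]] + b[["right"]]),
         intercept_difference = unname(b[["right"]]),
         n_trials = nrow(df)),
    class = "hysteresis_fit"
  )
}

#' @export
print.hysteresis_fit <- function(x, ...) {
  cat("<hysteresis_fit> slope ", signif(x$slope, 4),
      ", intercepts L ", signif(x$intercept_left, 4),
      " / R ", signif(x$intercept_right, 4),
      " (difference ", signif(x$intercept_difference, 4),
      " deg, n = ", x$n_trials, ")\n", sep = "")
  invisible(x)
}

#' Remove the hysteresis offset from judged positions
#'
#' Subtracts half the fitted right-minus-left intercept difference from
#' right-start judgments and adds half to left-start judgments, so a
#' refit on the corrected table yields a zero intercept difference (up to
#' round-off). Physical angles are untouched.
#'
#' @param trials Trials the fit was computed on (same participant x
#'   condition pool).
#' @param fit A [fit_hysteresis()] result.
#' @return `trials` with a `judged_corrected_deg` column.
#' @export
correct_hysteresis <- function(trials, fit) {
  stopifnot(inherits(fit, "hysteresis_fit"))
  d <- fit$intercept_difference
  adj <- ifelse(trials$marker_start_side == "right", -d / 2, d / 2)
  trials$judged_corrected_deg <- trials$judged_angle_deg + adj
  trials
}

#' Screen and hysteresis-correct a cohort of trials
#'
#' Applies [filter_outliers()] to the full table, then fits and applies
#' the hysteresis correction per participant x condition (all trial
#' types pooled). Screening comes first so gross judgment errors cannot
#' corrupt the hysteresis fit.
#'
#' @param trials Trial tibble with `participant_id` and `condition`.
#' @param thresholds Passed to [filter_outliers()].
#' @return A list with `trials` (kept rows plus `judged_corrected_deg`),
#'   `filter_report`, `removed`, and `hysteresis` (a tibble of per
#'   participant x condition fit parameters).
#' @export
preprocess_trials <- function(trials,
                              thresholds = c(drift = 2.5, direction = 35,
                                             judgment = 35)) {
  flt <- filter_outliers(trials, thresholds)
  kept <- flt$kept
  groups <- split(
    kept, interaction(kept$participant_id, kept$condition, drop = TRUE)
  )
  corrected <- vector("list", length(groups))
  fits <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    fit <- fit_hysteresis(g)
    corrected[[i]] <- correct_hysteresis(g, fit)
    fits[[i]] <- tibble::tibble(
      participant_id = g$participant_id[1],
      condition = g$condition[1],
      slope = fit$slope,
      intercept_left = fit$intercept_left,
      intercept_right = fit$intercept_right,
      intercept_difference = fit$intercept_difference,
      n_trials = fit$n_trials
    )
  }
  list(trials = dplyr::bind_rows(corrected),
       filter_report = flt$report,
       removed = flt$removed,
       hysteresis = dplyr::bind_rows(fits))
}
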