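#' Bias regression for one trial type
#'
#' Ordinary least squares of the trial-wise judgment error (judged minus
#' physical own-modality angle) on the signed discrepancy between the two
#' modalities. The regressor is chosen so the slope is directly the bias
#' weight toward the *other* modality:
#' * `BiHand`: regressor = cursor - hand, slope = `w_C_obs`;
#' * `BiCursor`: regressor = hand - cursor, slope = `w_H_obs`;
#' * `UniHand` / `UniCursor`: the rotation is a dummy regressor; only the
#'   residual variance is interpreted (it estimates the unimodal judgment
#'   variance), never the slope.
#'
#' Uses the hysteresis-corrected judgments when a `judged_corrected_deg`
#' column is present, raw judgments otherwise. The residual variance uses
#' denominator `n - 2` (slope and intercept estimated); an intercept is
#' always included since a global judgment offset may remain after the
#' start-side correction.
#'
#' @param trials Trials of a single trial type (and a single participant
#'   x condition), at least 3 rows.
#' @return A one-row tibble: `trial_type`, `condition`, `slope`,
#'   `intercept` (deg), `residual_variance` (deg^2), `residual_sd` (deg),
#'   `n_trials`.
#' @export
fit_bias_regression <- function(trials) {
  type <- unique(trials$trial_type)
  if (length(type) != 1) {
    stop("`trials` must contain a single trial type.", call. = FALSE)
  }
  n <- nrow(trials)
  if (n < 3) stop("Need at least 3 trials for the bias regression.",
                  call. = FALSE)
  judged <- if ("judged_corrected_deg" %in% names(trials)) {
    trials$judged_corrected_deg
  } else {
    trials$judged_angle_deg
  }
  error <- judged - own_physical_angle(trials)
  x <- switch(
    type,
    BiHand = trials$true_cursor_angle_deg - trials$true_hand_angle_deg,
    BiCursor = trials$true_hand_angle_deg - trials$true_cursor_angle_deg,
    UniHand = ,
    UniCursor = trials$rotation_deg,
    stop("Unknown trial type: ", type, call. = FALSE)
  )
  if (type %in% c("BiHand", "BiCursor") && stats::var(x) == 0) {
    stop("Zero variance in the hand-cursor discrepancy; ",
         "the bias weight is unidentifiable.", call. = FALSE)
  }
  fit <- stats::lm(error ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tibble::tibble(
    trial_type = type,
    condition = if ("condition" %in% names(trials)) trials$condition[1]
                else NA_character_,
    slope = unname(stats::coef(fit)[["x"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    residual_variance = rss / (n - 2),
    residual_sd = sqrt(rss / (n - 2)),
    n_trials = n
  )
}

#' Integration summary from the four trial-type regressions
#'
#' Combines the per-trial-type [fit_bias_regression()] results of one
#' participant x condition into the observed integration measures:
#' * `lambda_obs = w_H_obs + w_C_obs`, the integration strength (sum of
#'   the two bimodal slopes; deliberately *not* clipped to \[0, 1\]);
#' * `alpha_obs_deg`, the coupling angle via the two-argument arctangent
#'   of `(w_H_obs, w_C_obs)` in degrees (`atan(w_H/w_C)` when
#'   `w_C > 0`; 45 for symmetric biases, 90 for a pure hand bias);
#' * the four residual variances (unimodal hand/cursor, bimodal
#'   hand-given-cursor and cursor-given-hand).
#'
#' When `lambda_obs <= 0` the coupling angle is geometrically meaningless
#' and `lambda_flag` is set; consumers must honour it.
#'
#' @param estimates A tibble of exactly four [fit_bias_regression()]
#'   rows, one per trial type.
#' @param participant_id Identifier copied to the output.
#' @return A one-row tibble (`IntegrationSummary`).
#' @export
summarize_integration <- function(estimates, participant_id = NA_character_) {
  expected <- c("UniHand", "UniCursor", "BiHand", "BiCursor")
  if (!setequal(estimates$trial_type, expected) || nrow(estimates) != 4) {
    stop("Need exactly one regression per trial type (",
         paste(expected, collapse = ", "), ").", call. = FALSE)
  }
  row <- function(tt) estimates[estimates$trial_type == tt, ]
  w_H <- row("BiCursor")$slope
  w_C <- row("BiHand")$slope
  lambda <- w_H + w_C
  tibble::tibble(
    participant_id = participant_id,
    condition = estimates$condition[1],
    w_H_obs = w_H,
    w_C_obs = w_C,
    lambda_obs = lambda,
    alpha_obs_deg = coupling_angle(w_H, w_C),
    sigma2_H_obs = row("UniHand")$residual_variance,
    sigma2_C_obs = row("UniCursor")$residual_variance,
    sigma2_HC_obs = row("BiHand")$residual_variance,
    sigma2_CH_obs = row("BiCursor")$residual_variance,
    lambda_flag = lambda <= 0
  )
}

#' Estimate integration for every participant x condition
#'
#' Runs the four bias regressions and [summarize_integration()] on each
#' participant x condition cell of a (preprocessed) trial table.
#'
#' @param trials Trial tibble with `participant_id`, `condition`,
#'   `trial_type` columns (typically `preprocess_trials(...)$trials`).
#' @return A tidy tibble, one `IntegrationSummary` row per participant x
#'   condition.
#' @export
estimate_integration <- function(trials) {
  groups <- split(
    trials, interaction(trials$participant_id, trials$condition, drop = TRUE)
  )
  purrr::map_dfr(groups, function(g) {
    fits <- purrr::map_dfr(split(g, g$trial_type), fit_bias_regression)
    summarize_integration(fits, participant_id = g$participant_id[1])
  })
}

#' Exclude weak integrators from the coupling-angle analysis
#'
#' The coupling angle is a ratio measure and becomes noise-dominated at
#' low integration strength, so participants whose `lambda_obs` falls
#' below `threshold` in *any* condition are removed entirely. Intended
#' only for the coupling-angle analysis path; all other analyses keep
#' the full cohort.
#'
#' @param summaries Tibble from [estimate_integration()].
#' @param threshold Exclusion threshold on `lambda_obs` (default 0.2;
#'   strictly-below excludes, the boundary is retained).
#' @return The retained subset of `summaries`.
#' @export
exclude_low_integrators <- function(summaries, threshold = 0.2) {
  weak <- unique(summaries$participant_id[summaries$lambda_obs < threshold])
  summaries[!summaries$participant_id %in% weak, , drop = FALSE]
}
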