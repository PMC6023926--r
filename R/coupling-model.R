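#' Coupling-prior variance from integration strength
#'
#' The coupling-prior model expresses partial integration of two position
#' estimates through a zero-mean Gaussian prior on their difference. Its
#' variance is recovered from the observed integration strength `lambda`
#' and the two unimodal judgment variances:
#' \deqn{\sigma^2_{prior} = \frac{1-\lambda}{\lambda}
#'       (\sigma^2_C + \sigma^2_H)}
#' `lambda = 1` (full fusion) gives a zero-variance prior; as `lambda`
#' approaches 0 the prior variance diverges and the two estimates become
#' independent.
#'
#' @param lambda Integration strength, in (0, 1]. Values above 1 are
#'   rejected unless `clip_lambda = TRUE`, in which case they are clipped
#'   to 1 with a warning (the model is not defined for negative prior
#'   variances).
#' @param sigma2_C,sigma2_H Unimodal cursor- and hand-judgment variances
#'   (squared degrees), strictly positive.
#' @param clip_lambda Clip `lambda > 1` to 1 instead of raising an error.
#' @return Prior variance in squared degrees (vectorised over inputs).
#' @seealso [predict_weights()], [predict_variances()], [couple_predict()]
#' @export
prior_variance <- function(lambda, sigma2_C, sigma2_H, clip_lambda = FALSE) {
  stopifnot(is.numeric(lambda), is.numeric(sigma2_C), is.numeric(sigma2_H))
  if (any(!is.finite(lambda)) || any(lambda <= 0)) {
    stop("`lambda` must be finite and > 0; the coupling prior is undefined otherwise.",
         call. = FALSE)
  }
  if (any(lambda > 1)) {
    if (!clip_lambda) {
      stop("`lambda` > 1 implies a negative prior variance; ",
           "use `clip_lambda = TRUE` to clip to full fusion.", call. = FALSE)
    }
    warning("lambda > 1 clipped to 1 (full fusion).", call. = FALSE)
    lambda <- pmin(lambda, 1)
  }
  if (any(sigma2_C <= 0) || any(sigma2_H <= 0)) {
    stop("Unimodal variances must be strictly positive.", call. = FALSE)
  }
  (1 - lambda) / lambda * (sigma2_C + sigma2_H)
}

#' Predicted optimal bimodal weights
#'
#' Weights that an optimal observer with a Gaussian coupling prior assigns
#' to the other modality in each bimodal judgment: `w_H` is the weight of
#' hand information in the cursor judgment, `w_C` the weight of cursor
#' information in the hand judgment,
#' \deqn{w_H = \sigma^2_C / T,\quad w_C = \sigma^2_H / T,\quad
#'       T = \sigma^2_C + \sigma^2_H + \sigma^2_{prior}.}
#'
#' @inheritParams prior_variance
#' @param sigma2_prior Coupling-prior variance (squared degrees), >= 0.
#' @return A list with numeric components `w_H` and `w_C` (vectorised).
#' @export
predict_weights <- function(sigma2_C, sigma2_H, sigma2_prior) {
  check_positive_variances(sigma2_C, sigma2_H)
  if (any(sigma2_prior < 0)) {
    stop("`sigma2_prior` must be non-negative.", call. = FALSE)
  }
  total <- sigma2_C + sigma2_H + sigma2_prior
  if (any(total <= 0)) stop("Total variance must be positive.", call. = FALSE)
  list(w_H = sigma2_C / total, w_C = sigma2_H / total)
}

#' Predicted optimal bimodal judgment variances
#'
#' Marginal posterior variances of the coupled estimates, used as the
#' model's prediction for trial-to-trial variability of the bimodal
#' position judgments:
#' \deqn{\sigma^2_{C.H} = \sigma^2_C(\sigma^2_H + \sigma^2_{prior}) / T,
#'  \quad \sigma^2_{H.C} = \sigma^2_H(\sigma^2_C + \sigma^2_{prior}) / T.}
#' At `sigma2_prior = 0` both reduce to the classic fused variance
#' `sigma2_C * sigma2_H / (sigma2_C + sigma2_H)`; as `sigma2_prior` grows
#' they approach the unimodal variances (independence).
#'
#' @inheritParams predict_weights
#' @return A list with components `sigma2_CH` (predicted cursor-judgment
#'   variance in bimodal trials) and `sigma2_HC` (hand-judgment variance).
#' @export
predict_variances <- function(sigma2_C, sigma2_H, sigma2_prior) {
  check_positive_variances(sigma2_C, sigma2_H)
  if (any(sigma2_prior < 0)) {
    stop("`sigma2_prior` must be non-negative.", call. = FALSE)
  }
  total <- sigma2_C + sigma2_H + sigma2_prior
  list(
    sigma2_CH = sigma2_C * (sigma2_H + sigma2_prior) / total,
    sigma2_HC = sigma2_H * (sigma2_C + sigma2_prior) / total
  )
}

#' Predicted coupling angle from unimodal variances
#'
#' The model predicts the asymmetry of the mutual biases purely from the
#' unimodal reliabilities: `alpha_pred = atan(sigma2_C / sigma2_H)` in
#' degrees. Equal variances give 45 degrees (symmetric biases); a much
#' more reliable cursor (`sigma2_C` small) pushes the angle toward 0
#' (pure bias toward the cursor).
#'
#' @inheritParams predict_weights
#' @return Angle in degrees, in (0, 90) for positive variances.
#' @export
predict_coupling_angle <- function(sigma2_C, sigma2_H) {
  check_positive_variances(sigma2_C, sigma2_H)
  atan(sigma2_C / sigma2_H) * 180 / pi
}

#' Observed coupling angle from a pair of bias weights
#'
#' Expresses the asymmetry of the observed mutual biases on an angular
#' scale via the two-argument arctangent of `(w_H, w_C)`, in degrees.
#' Equal weights give 45; `w_C = 0` with `w_H > 0` gives 90 (pure bias
#' toward the hand). The angle is invariant to scaling both weights by a
#' common positive factor, so it separates bias asymmetry from
#' integration strength.
#'
#' @param w_H,w_C Observed bias weights (slopes of the bimodal bias
#'   regressions). May be negative; the atan2 convention keeps the result
#'   in (-180, 180].
#' @return Angle in degrees.
#' @export
coupling_angle <- function(w_H, w_C) {
  stopifnot(is.numeric(w_H), is.numeric(w_C))
  atan2(w_H, w_C) * 180 / pi
}

#' All coupling-prior predictions for one parameter set
#'
#' Convenience wrapper chaining [prior_variance()], [predict_weights()],
#' [predict_variances()] and [predict_coupling_angle()] into one tidy row.
#'
#' @inheritParams prior_variance
#' @return A one-row tibble with columns `sigma2_prior`, `w_H_pred`,
#'   `w_C_pred`, `sigma2_CH_pred`, `sigma2_HC_pred`, `alpha_pred_deg`.
#' @examples
#' couple_predict(lambda = 0.5, sigma2_H = 36, sigma2_C = 9)
#' @export
couple_predict <- function(lambda, sigma2_H, sigma2_C, clip_lambda = FALSE) {
  s2p <- prior_variance(lambda, sigma2_C, sigma2_H, clip_lambda = clip_lambda)
  w <- predict_weights(sigma2_C, sigma2_H, s2p)
  v <- predict_variances(sigma2_C, sigma2_H, s2p)
  tibble::tibble(
    sigma2_prior = s2p,
    w_H_pred = w$w_H,
    w_C_pred = w$w_C,
    sigma2_CH_pred = v$sigma2_CH,
    sigma2_HC_pred = v$sigma2_HC,
    alpha_pred_deg = predict_coupling_angle(sigma2_C, sigma2_H)
  )
}

#' Numeric MAP oracle for the coupling-prior observer
#'
#' Independent verification route for the closed-form predictions: the
#' joint log-posterior over the two latent positions (Gaussian likelihoods
#' centred on the measurements `m_H`, `m_C`, plus a Gaussian coupling
#' prior on their difference) is maximised by dense grid search followed
#' by one two-dimensional Newton step computed from finite differences of
#' the objective itself. Marginal posterior variances come from explicit
#' 2x2 precision-matrix inversion. Neither route reuses the closed-form
#' weight/variance expressions.
#'
#' @param m_H,m_C Measured hand and cursor angles (degrees).
#' @param sigma2_H,sigma2_C Likelihood variances (squared degrees), > 0.
#' @param sigma2_prior Coupling-prior variance, >= 0. Zero triggers the
#'   hard-fusion special case (both estimates equal the reliability-
#'   weighted average).
#' @param n_grid Grid points per axis for the dense search.
#' @param span_sd Half-width of the grid in units of the larger
#'   likelihood SD, beyond the measurement interval.
#' @return A list with `theta_H_hat`, `theta_C_hat` (MAP estimates) and
#'   `var_H`, `var_C` (marginal posterior variances).
#' @export
posterior_oracle <- function(m_H, m_C, sigma2_H, sigma2_C, sigma2_prior,
                             n_grid = 2001, span_sd = 6) {
  check_positive_variances(sigma2_C, sigma2_H)
  stopifnot(length(m_H) == 1, length(m_C) == 1, sigma2_prior >= 0)

  if (sigma2_prior == 0) {
    # hard fusion: single latent position, precision-weighted average
    prec <- 1 / sigma2_H + 1 / sigma2_C
    theta <- (m_H / sigma2_H + m_C / sigma2_C) / prec
    return(list(theta_H_hat = theta, theta_C_hat = theta,
                var_H = 1 / prec, var_C = 1 / prec))
  }

  neg_log_post <- function(tH, tC) {
    (tH - m_H)^2 / (2 * sigma2_H) + (tC - m_C)^2 / (2 * sigma2_C) +
      (tH - tC)^2 / (2 * sigma2_prior)
  }

  s <- sqrt(max(sigma2_H, sigma2_C))
  lo <- min(m_H, m_C) - span_sd * s
  hi <- max(m_H, m_C) + span_sd * s
  grid <- seq(lo, hi, length.out = n_grid)
  obj <- outer(grid, grid, neg_log_post)  # rows = theta_H, cols = theta_C
  idx <- arrayInd(which.min(obj), dim(obj))
  if (any(idx == 1L) || any(idx == n_grid)) {
    stop("Grid bounds do not bracket the posterior maximum.", call. = FALSE)
  }
  tH <- grid[idx[1]]
  tC <- grid[idx[2]]

  # one 2-D Newton step; finite differences are exact for this quadratic
  h <- diff(grid[1:2])
  g <- c(
    (neg_log_post(tH + h, tC) - neg_log_post(tH - h, tC)) / (2 * h),
    (neg_log_post(tH, tC + h) - neg_log_post(tH, tC - h)) / (2 * h)
  )
  f0 <- neg_log_post(tH, tC)
  H11 <- (neg_log_post(tH + h, tC) - 2 * f0 + neg_log_post(tH - h, tC)) / h^2
  H22 <- (neg_log_post(tH, tC + h) - 2 * f0 + neg_log_post(tH, tC - h)) / h^2
  H12 <- (neg_log_post(tH + h, tC + h) - neg_log_post(tH + h, tC - h) -
            neg_log_post(tH - h, tC + h) + neg_log_post(tH - h, tC - h)) /
    (4 * h^2)
  det_H <- H11 * H22 - H12^2
  step <- c(H22 * g[1] - H12 * g[2], -H12 * g[1] + H11 * g[2]) / det_H
  tH <- tH - step[1]
  tC <- tC - step[2]

  # marginal variances: invert the 2x2 posterior precision matrix
  P11 <- 1 / sigma2_H + 1 / sigma2_prior
  P22 <- 1 / sigma2_C + 1 / sigma2_prior
  P12 <- -1 / sigma2_prior
  det_P <- P11 * P22 - P12^2
  list(theta_H_hat = tH, theta_C_hat = tC,
       var_H = P22 / det_P, var_C = P11 / det_P)
}

check_positive_variances <- function(sigma2_C, sigma2_H) {
  if (any(!is.finite(sigma2_C)) || any(!is.finite(sigma2_H)) ||
      any(sigma2_C <= 0) || any(sigma2_H <= 0)) {
    stop("Variances must be finite and strictly positive.", call. = FALSE)
  }
  invisible(TRUE)
}
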