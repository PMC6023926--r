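#' Ground-truth parameters for the synthetic-trial generator
#'
#' Collects, per visibility condition, the unimodal judgment SDs, the
#' true integration strength, movement-duration means, plus the
#' session-wide hysteresis offset and outlier contamination rates. The
#' defaults describe a cohort of experienced cursor users: hand-endpoint
#' judgments about twice as variable as cursor-endpoint judgments, strong
#' integration when the cursor is visible during the movement (`Dyn`,
#' `DynEnd`) and weaker integration with endpoint-only feedback (`End`),
#' a small negative left/right response-hysteresis offset, and sub-percent
#' outlier rates per screening criterion.
#'
#' @param conditions Condition labels (order defines alignment of the
#'   per-condition vectors).
#' @param sigma_H_deg,sigma_C_deg Unimodal hand/cursor judgment SDs per
#'   condition (degrees, >= 0; zero gives the noise-free limit).
#' @param lambda_true True integration strength per condition, in (0, 1].
#' @param hysteresis_offset_deg Full right-minus-left intercept
#'   difference `h` added to judgments (`+h/2` for right marker starts,
#'   `-h/2` for left).
#' @param outward_mean_s,dwell_mean_s Mean outward-movement duration and
#'   mean time at the endpoint per condition (seconds).
#' @param outlier_rate Named rates `c(drift=, direction=, judgment=)` of
#'   injected violations of the three screening criteria, each in
#'   \[0, 0.2).
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(conditions = c("Dyn", "End", "DynEnd"),
                              sigma_H_deg = c(6, 6, 7),
                              sigma_C_deg = c(3, 3, 3),
                              lambda_true = c(0.8, 0.45, 0.8),
                              hysteresis_offset_deg = -1.75,
                              outward_mean_s = c(1.26, 1.20, 1.29),
                              dwell_mean_s = c(0.45, 0.63, 0.53),
                              outlier_rate = c(drift = 0.008,
                                               direction = 0.010,
                                               judgment = 0.003)) {
  k <- length(conditions)
  rec <- function(x) rep_len(x, k)
  sigma_H_deg <- rec(sigma_H_deg)
  sigma_C_deg <- rec(sigma_C_deg)
  lambda_true <- rec(lambda_true)
  outward_mean_s <- rec(outward_mean_s)
  dwell_mean_s <- rec(dwell_mean_s)
  stopifnot(
    all(sigma_H_deg >= 0), all(sigma_C_deg >= 0),
    all(lambda_true > 0), all(lambda_true <= 1),
    all(outward_mean_s > 0), all(dwell_mean_s > 0)
  )
  if (!all(c("drift", "direction", "judgment") %in% names(outlier_rate))) {
    stop("`outlier_rate` needs named entries drift, direction, judgment.",
         call. = FALSE)
  }
  if (any(outlier_rate < 0) || any(outlier_rate >= 0.2)) {
    stop("Outlier rates must lie in [0, 0.2).", call. = FALSE)
  }
  structure(
    list(conditions = conditions,
         sigma_H_deg = stats::setNames(sigma_H_deg, conditions),
         sigma_C_deg = stats::setNames(sigma_C_deg, conditions),
         lambda_true = stats::setNames(lambda_true, conditions),
         hysteresis_offset_deg = hysteresis_offset_deg,
         outward_mean_s = stats::setNames(outward_mean_s, conditions),
         dwell_mean_s = stats::setNames(dwell_mean_s, conditions),
         outlier_rate = outlier_rate[c("drift", "direction", "judgment")]),
    class = "generative_params"
  )
}

#' Observable quantities implied by ground-truth parameters
#'
#' Maps ground-truth unimodal SDs and integration strength to the
#' quantities the generator needs and the estimator recovers: the two
#' bimodal bias weights and the two bimodal judgment SDs, as implied by
#' the coupling-prior model. Delegates to [prior_variance()],
#' [predict_weights()] and [predict_variances()] for positive SDs; in the
#' zero-noise limit the weights follow the variance-ratio limit
#' `w_C = lambda * s2H / (s2H + s2C)` (equal split when both SDs are
#' exactly zero) and the bimodal SDs are zero.
#'
#' @param sigma_H,sigma_C Unimodal SDs in degrees (>= 0).
#' @param lambda Integration strength in (0, 1].
#' @return A list with `w_H`, `w_C`, `sd_BiCursor`, `sd_BiHand`.
#'   `w_H + w_C` equals `lambda` up to round-off.
#' @export
derive_observable_params <- function(sigma_H, sigma_C, lambda) {
  stopifnot(length(sigma_H) == 1, length(sigma_C) == 1, length(lambda) == 1,
            sigma_H >= 0, sigma_C >= 0)
  if (lambda <= 0 || lambda > 1) {
    stop("`lambda` must lie in (0, 1].", call. = FALSE)
  }
  s2H <- sigma_H^2
  s2C <- sigma_C^2
  if (s2H > 0 && s2C > 0) {
    s2p <- prior_variance(lambda, s2C, s2H)
    w <- predict_weights(s2C, s2H, s2p)
    v <- predict_variances(s2C, s2H, s2p)
    list(w_H = w$w_H, w_C = w$w_C,
         sd_BiCursor = sqrt(v$sigma2_CH), sd_BiHand = sqrt(v$sigma2_HC))
  } else {
    share_H <- if (s2H + s2C > 0) s2H / (s2H + s2C) else 0.5
    total <- (s2H + s2C) / lambda  # s2C + s2H + s2p collapses to this
    v_CH <- if (total > 0) s2C * ((1 - lambda) * s2C + s2H) / (s2H + s2C) else 0
    v_HC <- if (total > 0) s2H * ((1 - lambda) * s2H + s2C) / (s2H + s2C) else 0
    list(w_H = lambda * (1 - share_H), w_C = lambda * share_H,
         sd_BiCursor = sqrt(v_CH), sd_BiHand = sqrt(v_HC))
  }
}

#' Generate judgment trials for one session
#'
#' Instantiates the statistical model the estimation pipeline assumes.
#' For every slot of a session design the true hand endpoint is drawn
#' uniformly within +/- 8 degrees of the instructed direction (converted
#' to the stopper-ring frame, `+90`), the cursor endpoint is the hand
#' endpoint plus the visuomotor rotation, and the judged angle is
#' \deqn{judged = own + w (other - own) + hyst + \epsilon}
#' where `own`/`other` are the judged and non-judged modality endpoints,
#' `w` is the trial type's bias weight (0 for unimodal trials), `hyst` is
#' `+h/2` for right marker starts and `-h/2` for left starts (sides
#' alternate across the session), and `epsilon` is zero-mean Gaussian
#' with the trial type's SD (unimodal SDs for Uni trials, coupling-model
#' bimodal SDs for Bi trials). `UniCursor` slots replay the hand/cursor
#' endpoints of their source `BiCursor` slot with an independent judgment
#' draw. Movement durations are Gaussian around the condition means
#' (SD = 10% of the mean, floored at 0). Clean per-trial kinematic
#' scalars are drawn inside the screening thresholds.
#'
#' @param design Session tibble from [build_session()].
#' @param params A [generative_params()] object.
#' @param condition Which condition's parameters to use.
#' @param participant_id Identifier stamped on the rows.
#' @param seed Optional integer seed.
#' @return A tibble of trial records, one row per design slot, with
#'   contamination columns `outlier_injected = FALSE`,
#'   `outlier_criterion = 0` (see [inject_outliers()]).
#' @export
generate_trials <- function(design, params, condition = params$conditions[1],
                            participant_id = "P01", seed = NULL) {
  stopifnot(inherits(params, "generative_params"))
  if (!condition %in% params$conditions) {
    stop("Unknown condition: ", condition, call. = FALSE)
  }
  bad <- setdiff(unique(design$trial_type),
                 c("UniHand", "UniCursor", "BiHand", "BiCursor"))
  if (length(bad) > 0) {
    stop("Unknown trial type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)

  sigma_H <- params$sigma_H_deg[[condition]]
  sigma_C <- params$sigma_C_deg[[condition]]
  lambda <- params$lambda_true[[condition]]
  h <- params$hysteresis_offset_deg
  der <- derive_observable_params(sigma_H, sigma_C, lambda)

  n <- nrow(design)
  instr_ring <- design$instructed_direction_deg + 90
  hand <- instr_ring + stats::runif(n, -8, 8)
  cursor <- hand + design$rotation_deg

  # UniCursor replays the endpoints of its source BiCursor slot
  uc <- which(design$trial_type == "UniCursor")
  if (length(uc) > 0) {
    src <- design$source_slot[uc] + 1L  # session_index is 0-based
    hand[uc] <- hand[src]
    cursor[uc] <- cursor[src]
  }

  side <- rep_len(c("left", "right"), n)
  hyst <- ifelse(side == "right", h / 2, -h / 2)

  type <- design$trial_type
  own <- ifelse(type %in% c("UniHand", "BiHand"), hand, cursor)
  other <- ifelse(type %in% c("UniHand", "BiHand"), cursor, hand)
  w <- c(UniHand = 0, UniCursor = 0,
         BiHand = der$w_C, BiCursor = der$w_H)[type]
  sd_j <- c(UniHand = sigma_H, UniCursor = sigma_C,
            BiHand = der$sd_BiHand, BiCursor = der$sd_BiCursor)[type]
  bias <- ifelse(type %in% c("BiHand", "BiCursor"), w * (other - own), 0)
  judged <- own + bias + hyst + stats::rnorm(n, 0, sd_j)

  outward <- params$outward_mean_s[[condition]]
  dwell <- params$dwell_mean_s[[condition]]

  tibble::tibble(
    participant_id = participant_id,
    condition = condition,
    session_index = design$session_index,
    repetition_set = design$repetition_set,
    trial_type = type,
    rotation_deg = design$rotation_deg,
    instructed_direction_deg = design$instructed_direction_deg,
    true_hand_angle_deg = hand,
    true_cursor_angle_deg = ifelse(type == "UniHand", NA_real_, cursor),
    judged_angle_deg = judged,
    marker_start_side = side,
    ring_drift_deg = stats::runif(n, 0, 2.0),
    direction_deviation_deg = abs(hand - instr_ring),
    outward_duration_s = pmax(stats::rnorm(n, outward, 0.1 * outward), 0),
    dwell_duration_s = pmax(stats::rnorm(n, dwell, 0.1 * dwell), 0),
    outlier_injected = FALSE,
    outlier_criterion = 0L
  )
}

#' Inject controlled outlier contamination
#'
#' Randomly selects trials (per-criterion Bernoulli draws, disjoint
#' across criteria) and modifies each to violate exactly one screening
#' criterion: (1) ring drift pushed above 2.5 degrees, (2) outward
#' direction deviation pushed above 35 degrees, or (3) the judged angle
#' displaced so the judgment error exceeds 35 degrees. Ground-truth flags
#' are recorded so filter validation can compare removals against
#' injections exactly.
#'
#' @param trials Trial tibble from [generate_trials()].
#' @param params A [generative_params()] (uses `outlier_rate`), or a
#'   named rate vector `c(drift=, direction=, judgment=)`.
#' @param seed Optional integer seed.
#' @return `trials` with modified rows and updated `outlier_injected` /
#'   `outlier_criterion` (1, 2, 3) columns.
#' @export
inject_outliers <- function(trials, params, seed = NULL) {
  rates <- if (inherits(params, "generative_params")) {
    params$outlier_rate
  } else {
    params
  }
  stopifnot(all(c("drift", "direction", "judgment") %in% names(rates)))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  if (n == 0 || all(rates == 0)) return(trials)

  u <- stats::runif(n)
  pick1 <- u < rates[["drift"]]
  u <- stats::runif(n)
  pick2 <- !pick1 & u < rates[["direction"]]
  u <- stats::runif(n)
  pick3 <- !pick1 & !pick2 & u < rates[["judgment"]]

  if (any(pick1)) {
    trials$ring_drift_deg[pick1] <- stats::runif(sum(pick1), 2.6, 6)
    trials$outlier_criterion[pick1] <- 1L
  }
  if (any(pick2)) {
    trials$direction_deviation_deg[pick2] <- stats::runif(sum(pick2), 36, 60)
    trials$outlier_criterion[pick2] <- 2L
  }
  if (any(pick3)) {
    k <- sum(pick3)
    own <- ifelse(trials$trial_type[pick3] %in% c("UniHand", "BiHand"),
                  trials$true_hand_angle_deg[pick3],
                  trials$true_cursor_angle_deg[pick3])
    shift <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 36.5, 60)
    trials$judged_angle_deg[pick3] <- own + shift
    trials$outlier_criterion[pick3] <- 3L
  }
  trials$outlier_injected <- trials$outlier_criterion > 0L
  trials
}

#' Simulate a full multi-participant cohort
#'
#' Builds one semi-randomized session per participant and condition,
#' generates trials from the ground-truth parameters, and injects
#' outlier contamination. All randomness flows from `seed`.
#'
#' @param params A [generative_params()] object.
#' @param n_participants Number of simulated participants.
#' @param spec A [design_spec()]; its `conditions` are ignored in favour
#'   of `params$conditions`.
#' @param seed Integer seed for the whole cohort.
#' @param lambda_by_participant Optional numeric vector (length
#'   `n_participants`) overriding `lambda_true` per participant,
#'   identically in every condition. Used for recovery studies where the
#'   true integration strength varies across individuals.
#' @return A tibble of trial records for all participants x conditions.
#' @examples
#' params <- generative_params()
#' trials <- simulate_cohort(params, n_participants = 2, seed = 1)
#' dplyr::count(trials, condition, trial_type)
#' @export
simulate_cohort <- function(params, n_participants = 12, spec = design_spec(),
                            seed = NULL, lambda_by_participant = NULL) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(lambda_by_participant)) {
    stopifnot(length(lambda_by_participant) == n_participants)
  }
  ids <- sprintf("P%02d", seq_len(n_participants))
  out <- vector("list", n_participants * length(params$conditions))
  k <- 0L
  for (i in seq_len(n_participants)) {
    p_i <- params
    if (!is.null(lambda_by_participant)) {
      p_i$lambda_true[] <- lambda_by_participant[i]
    }
    for (cond in params$conditions) {
      sess <- build_session(spec, condition = cond)
      tr <- generate_trials(sess, p_i, condition = cond,
                            participant_id = ids[i])
      tr <- inject_outliers(tr, p_i)
      k <- k + 1L
      out[[k]] <- tr
    }
  }
  dplyr::bind_rows(out)
}
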