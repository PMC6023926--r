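#' Coupling-prior predictions for observed integration summaries
#'
#' Appends the model predictions (suffix `_pred`) to each
#' participant-x-condition row of an [estimate_integration()] table,
#' using the observed integration strength and the observed unimodal
#' variances as model input. Rows with `lambda_obs <= 0` get `NA`
#' predictions (the prior is undefined); `lambda_obs > 1` is clipped to
#' full fusion and flagged in `lambda_clipped`. Zero observed variances
#' (possible only for noise-free data) use the variance-ratio limit of
#' the model, with the equal-share convention when both are zero.
#'
#' @param summaries Tibble from [estimate_integration()].
#' @return `summaries` with columns `sigma2_prior`, `w_H_pred`,
#'   `w_C_pred`, `sigma2_CH_pred`, `sigma2_HC_pred`, `alpha_pred_deg`,
#'   `lambda_clipped`.
#' @export
predict_integration <- function(summaries) {
  pred <- purrr::pmap_dfr(
    list(summaries$lambda_obs, summaries$sigma2_H_obs,
         summaries$sigma2_C_obs),
    predict_one_row
  )
  dplyr::bind_cols(summaries, pred)
}

predict_one_row <- function(lambda, s2H, s2C) {
  na_row <- tibble::tibble(
    sigma2_prior = NA_real_, w_H_pred = NA_real_, w_C_pred = NA_real_,
    sigma2_CH_pred = NA_real_, sigma2_HC_pred = NA_real_,
    alpha_pred_deg = NA_real_, lambda_clipped = FALSE
  )
  if (!is.finite(lambda) || lambda <= 0) return(na_row)
  clipped <- lambda > 1
  lam <- min(lambda, 1)
  # residual variances of exactly linear (noise-free) data are pure
  # round-off; treat them as zero so the limit convention applies
  if (s2H < 1e-12) s2H <- 0
  if (s2C < 1e-12) s2C <- 0
  if (s2H > 0 && s2C > 0) {
    out <- couple_predict(lam, sigma2_H = s2H, sigma2_C = s2C)
  } else {
    # zero-variance limit of Eqs (prior -> weights -> variances)
    share_H <- if (s2H + s2C > 0) s2H / (s2H + s2C) else 0.5
    denom <- s2H + s2C
    out <- tibble::tibble(
      sigma2_prior = (1 - lam) / lam * denom,
      w_H_pred = lam * (1 - share_H),
      w_C_pred = lam * share_H,
      sigma2_CH_pred = if (denom > 0) {
        s2C * ((1 - lam) * s2C + s2H) / denom
      } else 0,
      sigma2_HC_pred = if (denom > 0) {
        s2H * ((1 - lam) * s2H + s2C) / denom
      } else 0,
      alpha_pred_deg = if (denom > 0) atan2(s2C, s2H) * 180 / pi else 45
    )
  }
  out$lambda_clipped <- clipped
  out
}

#' Run the full analysis pipeline on a simulated or supplied cohort
#'
#' End-to-end orchestration: simulate (or accept) a trial table, screen
#' outliers and correct hysteresis, estimate per-participant integration,
#' attach coupling-prior predictions, and compute the group-level
#' comparisons: integration strength per condition with uncorrected
#' pairwise paired t-tests; observed-vs-predicted bias weights per
#' bimodal trial type with a 2 (data vs model) x 3 (condition)
#' repeated-measures ANOVA and per-condition Pearson correlations;
#' observed-vs-predicted coupling angles after excluding weak
#' integrators; observed-vs-predicted bimodal judgment SDs with a
#' 2 (trial type) x 3 (condition) ANOVA on the differences; and movement
#' -duration summaries with cursor-visibility-duration vs integration-
#' strength correlations. Descriptives are mean +/- standard error of the
#' mean; variabilities are reported as SDs (degrees), not variances.
#'
#' @param config A list (or path to a JSON file) with optional entries:
#'   `n_participants` (default 12), `seed` (default 1), `params` (a list
#'   of [generative_params()] overrides), `lambda_threshold` (default
#'   0.2, for the coupling-angle exclusion), `trials` (a trial tibble to
#'   analyse instead of simulating), `out_dir` (write CSV/JSON outputs
#'   there when non-NULL).
#' @return A named list: `summaries` (per participant x condition with
#'   `_pred` columns), `integration`, `biases`, `angles`, `sds`,
#'   `durations`, `filter_report`, `hysteresis`, `metadata`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(n_participants = 6, seed = 42))
#' res$integration$per_condition
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  n_participants <- config$n_participants %||% 12
  seed <- config$seed %||% 1
  threshold <- config$lambda_threshold %||% 0.2
  params <- do.call(generative_params, config$params %||% list())

  trials <- config$trials
  if (is.null(trials)) {
    trials <- simulate_cohort(params, n_participants = n_participants,
                              seed = seed)
  }

  pp <- preprocess_trials(trials)
  summaries <- estimate_integration(pp$trials)
  summaries <- predict_integration(summaries)
  conds <- intersect(params$conditions, unique(summaries$condition))

  integration <- group_integration(summaries, conds)
  biases <- group_biases(summaries, conds)
  angles <- group_angles(summaries, conds, threshold)
  sds <- group_sds(summaries, conds)
  durations <- group_durations(pp$trials, summaries, conds)

  metadata <- list(
    package_version = as.character(utils::packageVersion("couplingprior")),
    seed = seed,
    n_participants = n_participants,
    lambda_threshold = threshold,
    notes = c("pairwise t-tests are uncorrected for multiple comparisons",
              "no sphericity correction applied to repeated-measures ANOVAs",
              "descriptives are mean +/- SEM; variability reported as SD")
  )

  out <- list(summaries = summaries, integration = integration,
              biases = biases, angles = angles, sds = sds,
              durations = durations, filter_report = pp$filter_report,
              hysteresis = pp$hysteresis, metadata = metadata)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

condition_pairs <- function(conds) {
  if (length(conds) < 2) return(NULL)
  utils::combn(conds, 2, simplify = FALSE)
}

pairwise_paired_t <- function(summaries, conds, col) {
  wide <- tidyr::pivot_wider(
    summaries[, c("participant_id", "condition", col)],
    names_from = "condition", values_from = dplyr::all_of(col)
  )
  purrr::map_dfr(condition_pairs(conds), function(pr) {
    res <- paired_t(wide[[pr[1]]], wide[[pr[2]]])
    dplyr::bind_cols(tibble::tibble(contrast = paste(pr[1], "vs", pr[2])),
                     res)
  })
}

group_integration <- function(summaries, conds) {
  per_condition <- summaries |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_lambda = mean(.data$lambda_obs),
                     sem_lambda = stats::sd(.data$lambda_obs) /
                       sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
  list(per_condition = per_condition,
       pairwise = pairwise_paired_t(summaries, conds, "lambda_obs"))
}

group_biases <- function(summaries, conds) {
  cc <- summaries[stats::complete.cases(summaries$w_H_pred), ]
  # keep only participants observed in every condition for the RM ANOVA
  full <- names(which(table(cc$participant_id) == length(conds)))
  cc <- cc[cc$participant_id %in% full, ]
  one_type <- function(obs_col, pred_col, label) {
    long <- dplyr::bind_rows(
      tibble::tibble(subject = cc$participant_id, a = "data",
                     b = cc$condition, value = cc[[obs_col]]),
      tibble::tibble(subject = cc$participant_id, a = "model",
                     b = cc$condition, value = cc[[pred_col]])
    )
    anova_tab <- rm_anova_2x3(long)
    cors <- purrr::map_dfr(conds, function(cnd) {
      sub <- cc[cc$condition == cnd, ]
      res <- pearson_cor(sub[[obs_col]], sub[[pred_col]])
      dplyr::bind_cols(tibble::tibble(condition = cnd), res)
    })
    means <- cc |>
      dplyr::group_by(.data$condition) |>
      dplyr::summarise(
        mean_obs = mean(.data[[obs_col]]),
        sem_obs = stats::sd(.data[[obs_col]]) / sqrt(dplyr::n()),
        mean_pred = mean(.data[[pred_col]]),
        sem_pred = stats::sd(.data[[pred_col]]) / sqrt(dplyr::n()),
        .groups = "drop"
      )
    list(trial_type = label, means = means, anova = anova_tab,
         correlations = cors)
  }
  list(BiHand = one_type("w_C_obs", "w_C_pred", "BiHand"),
       BiCursor = one_type("w_H_obs", "w_H_pred", "BiCursor"))
}

group_angles <- function(summaries, conds, threshold) {
  kept <- exclude_low_integrators(summaries, threshold)
  kept <- kept[stats::complete.cases(kept$alpha_pred_deg), ]
  n_kept <- length(unique(kept$participant_id))
  per_condition <- kept |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_obs = mean(.data$alpha_obs_deg),
      sem_obs = stats::sd(.data$alpha_obs_deg) / sqrt(dplyr::n()),
      mean_pred = mean(.data$alpha_pred_deg),
      sem_pred = stats::sd(.data$alpha_pred_deg) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
  tests <- purrr::map_dfr(conds, function(cnd) {
    sub <- kept[kept$condition == cnd, ]
    if (nrow(sub) < 3 || stats::sd(sub$alpha_obs_deg - sub$alpha_pred_deg)
        == 0) {
      return(tibble::tibble(condition = cnd, t_value = NA_real_,
                            df = NA_real_, p_value = NA_real_,
                            cohens_d = NA_real_, mean_diff = NA_real_,
                            n = nrow(sub)))
    }
    dplyr::bind_cols(tibble::tibble(condition = cnd),
                     paired_t(sub$alpha_obs_deg, sub$alpha_pred_deg))
  })
  list(n_retained = n_kept, per_condition = per_condition,
       obs_vs_pred = tests)
}

group_sds <- function(summaries, conds) {
  cc <- summaries[stats::complete.cases(summaries$sigma2_HC_pred), ]
  full <- names(which(table(cc$participant_id) == length(conds)))
  cc <- cc[cc$participant_id %in% full, ]
  long <- dplyr::bind_rows(
    tibble::tibble(subject = cc$participant_id, a = "BiHand",
                   b = cc$condition,
                   value = sqrt(cc$sigma2_HC_obs) - sqrt(cc$sigma2_HC_pred)),
    tibble::tibble(subject = cc$participant_id, a = "BiCursor",
                   b = cc$condition,
                   value = sqrt(cc$sigma2_CH_obs) - sqrt(cc$sigma2_CH_pred))
  )
  anova_tab <- rm_anova_2x3(long)
  means <- cc |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      sd_HC_obs = mean(sqrt(.data$sigma2_HC_obs)),
      sd_HC_pred = mean(sqrt(.data$sigma2_HC_pred)),
      sd_CH_obs = mean(sqrt(.data$sigma2_CH_obs)),
      sd_CH_pred = mean(sqrt(.data$sigma2_CH_pred)),
      sd_H_obs = mean(sqrt(.data$sigma2_H_obs)),
      sd_C_obs = mean(sqrt(.data$sigma2_C_obs)),
      .groups = "drop"
    )
  cors <- purrr::map_dfr(conds, function(cnd) {
    sub <- cc[cc$condition == cnd, ]
    dplyr::bind_rows(
      dplyr::bind_cols(
        tibble::tibble(condition = cnd, trial_type = "BiHand"),
        pearson_cor(sqrt(sub$sigma2_HC_obs), sqrt(sub$sigma2_HC_pred))
      ),
      dplyr::bind_cols(
        tibble::tibble(condition = cnd, trial_type = "BiCursor"),
        pearson_cor(sqrt(sub$sigma2_CH_obs), sqrt(sub$sigma2_CH_pred))
      )
    )
  })
  list(means = means, anova_diff = anova_tab, correlations = cors)
}

group_durations <- function(trials, summaries, conds) {
  bi <- trials[trials$trial_type %in% c("BiHand", "BiCursor"), ]
  per_subject <- bi |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(outward_s = mean(.data$outward_duration_s),
                     dwell_s = mean(.data$dwell_duration_s),
                     .groups = "drop")
  per_condition <- per_subject |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_outward = mean(.data$outward_s),
      sem_outward = stats::sd(.data$outward_s) / sqrt(dplyr::n()),
      mean_dwell = mean(.data$dwell_s),
      sem_dwell = stats::sd(.data$dwell_s) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  # duration of cursor visibility: outward phase (Dyn), endpoint dwell
  # (End), or both (DynEnd); other condition labels fall back to outward
  per_subject$cursor_visibility_s <- dplyr::case_when(
    per_subject$condition == "Dyn" ~ per_subject$outward_s,
    per_subject$condition == "End" ~ per_subject$dwell_s,
    per_subject$condition == "DynEnd" ~ per_subject$outward_s +
      per_subject$dwell_s,
    TRUE ~ per_subject$outward_s
  )
  merged <- dplyr::inner_join(
    per_subject, summaries[, c("participant_id", "condition", "lambda_obs")],
    by = c("participant_id", "condition")
  )
  visibility_vs_lambda <- purrr::map_dfr(conds, function(cnd) {
    sub <- merged[merged$condition == cnd, ]
    dplyr::bind_cols(tibble::tibble(condition = cnd),
                     pearson_cor(sub$cursor_visibility_s, sub$lambda_obs))
  })
  list(per_condition = per_condition,
       pairwise_outward = pairwise_paired_t(per_subject, conds, "outward_s"),
       pairwise_dwell = pairwise_paired_t(per_subject, conds, "dwell_s"),
       visibility_vs_lambda = visibility_vs_lambda)
}

write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(out$summaries, file.path(out_dir, "summaries.csv"))
  readr::write_csv(out$integration$per_condition,
                   file.path(out_dir, "integration_per_condition.csv"))
  readr::write_csv(out$integration$pairwise,
                   file.path(out_dir, "integration_pairwise_t.csv"))
  readr::write_csv(out$filter_report, file.path(out_dir, "filter_report.csv"))
  readr::write_csv(out$hysteresis, file.path(out_dir, "hysteresis_fits.csv"))
  jsonlite::write_json(out$metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
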