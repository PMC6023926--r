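#' Read and write trial tables and session designs as CSV
#'
#' Thin readr wrappers fixing the column types of the package's two
#' canonical tables so round-trips are lossless.
#'
#' @param trials,design Tibbles as produced by [generate_trials()] /
#'   [build_session()].
#' @param path File path.
#' @return The written tibble (write) or the parsed tibble (read).
#' @name trial_io
NULL

#' @rdname trial_io
#' @export
write_trials_csv <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(trials)
}

#' @rdname trial_io
#' @export
read_trials_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    condition = readr::col_character(),
    trial_type = readr::col_character(),
    marker_start_side = readr::col_character(),
    session_index = readr::col_integer(),
    repetition_set = readr::col_integer(),
    outlier_criterion = readr::col_integer(),
    outlier_injected = readr::col_logical(),
    .default = readr::col_double()
  ))
}

#' @rdname trial_io
#' @export
write_design_csv <- function(design, path) {
  readr::write_csv(design, path)
  invisible(design)
}

#' @rdname trial_io
#' @export
read_design_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    condition = readr::col_character(),
    trial_type = readr::col_character(),
    session_index = readr::col_integer(),
    block = readr::col_integer(),
    repetition_set = readr::col_integer(),
    source_slot = readr::col_integer(),
    .default = readr::col_double()
  ))
}

#' Serialise generator parameters to and from JSON
#'
#' @param params A [generative_params()] object.
#' @param path JSON file path.
#' @return `read_params_json` returns a [generative_params()] object.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "generative_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(params)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  generative_params(
    conditions = raw$conditions,
    sigma_H_deg = unlist(raw$sigma_H_deg),
    sigma_C_deg = unlist(raw$sigma_C_deg),
    lambda_true = unlist(raw$lambda_true),
    hysteresis_offset_deg = raw$hysteresis_offset_deg,
    outward_mean_s = unlist(raw$outward_mean_s),
    dwell_mean_s = unlist(raw$dwell_mean_s),
    outlier_rate = unlist(raw$outlier_rate)
  )
}

#' Plot integration strength per condition
#'
#' Optional ggplot2 summary figure: participant-level integration
#' strengths with condition means and SEM error bars.
#'
#' @param summaries Tibble from [estimate_integration()].
#' @return A ggplot object.
#' @export
plot_integration_strength <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting.", call. = FALSE)
  }
  means <- summaries |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(m = mean(.data$lambda_obs),
                     sem = stats::sd(.data$lambda_obs) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(means, ggplot2::aes(x = .data$condition, y = .data$m)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$sem, ymax = .data$m + .data$sem),
      width = 0.2
    ) +
    ggplot2::geom_jitter(
      data = summaries,
      ggplot2::aes(x = .data$condition, y = .data$lambda_obs),
      width = 0.08, alpha = 0.5, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "Visibility condition",
                  y = "Integration strength λ") +
    ggplot2::theme_minimal()
}
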