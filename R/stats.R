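#' Paired-samples t-test with Cohen's d
#'
#' Standard two-sided paired t-test on per-subject differences, plus the
#' paired-design effect size `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y Numeric vectors of per-subject values, paired by position,
#'   length >= 3.
#' @return A one-row tibble: `t_value`, `df` (= n - 1), `p_value`
#'   (two-sided), `cohens_d`, `mean_diff`, `n`.
#' @examples
#' paired_t(c(1, 2, 3, 4), c(0, 0, 0, 0))
#' @export
paired_t <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    stop("`x` and `y` must be paired (equal length).", call. = FALSE)
  }
  if (length(x) < 3) stop("Need at least 3 pairs.", call. = FALSE)
  d <- x - y
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("Zero variance in the paired differences; t is undefined.",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  tibble::tibble(
    t_value = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    cohens_d = mean(d) / sd_d,
    mean_diff = mean(d),
    n = length(x)
  )
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return A one-row tibble: `r`, `p_value` (two-sided, from the t
#'   transform), `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y) || length(x) < 3) {
    stop("`x` and `y` must have equal length >= 3.", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Zero variance in `x` or `y`; correlation is undefined.",
         call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Two-way fully repeated-measures ANOVA
#'
#' Within-subject ANOVA for a complete a x b design with one observation
#' per subject x cell (e.g. 2 data-vs-model levels x 3 visibility
#' conditions). Fitted with `stats::aov` using the error stratification
#' `Error(subject/(a*b))`, so each effect is tested against its own
#' effect-by-subject interaction. No sphericity correction is applied.
#'
#' Degenerate tables are flagged rather than failed: an effect with zero
#' sum of squares reports `F = 0`, `p = 1`; an effect whose error stratum
#' has zero sum of squares (perfect separation, e.g. noise-free data)
#' reports `F = Inf`, `p = 0` with `degenerate = TRUE`.
#'
#' @param data Long-format data frame of one observation per subject x
#'   cell.
#' @param value,subject,factor_a,factor_b Column names (strings).
#' @return A tibble with one row per effect (`a`, `b`, `a:b`):
#'   `F_value`, `df_num`, `df_den`, `p_value`, `degenerate`.
#' @export
rm_anova_2x3 <- function(data, value = "value", subject = "subject",
                         factor_a = "a", factor_b = "b") {
  cols <- c(value, subject, factor_a, factor_b)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("Missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- data.frame(
    value = data[[value]],
    subject = factor(data[[subject]]),
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  if (anyNA(df$value)) stop("Missing values in the response.", call. = FALSE)
  n_s <- nlevels(df$subject)
  if (n_s < 3) stop("Need at least 3 subjects.", call. = FALSE)
  counts <- table(df$subject, df$a, df$b)
  if (any(counts != 1)) {
    stop("Design must be complete: exactly one observation per subject ",
         "x cell.", call. = FALSE)
  }

  fit <- stats::aov(value ~ a * b + Error(subject / (a * b)), data = df)
  sm <- summary(fit)
  pull_stratum <- function(effect, stratum_name) {
    tab <- sm[[stratum_name]][[1]]
    rn <- trimws(rownames(tab))
    i <- which(rn == effect)
    j <- which(rn == "Residuals")
    ss_eff <- tab[i, "Sum Sq"]
    ss_err <- tab[j, "Sum Sq"]
    df_num <- tab[i, "Df"]
    df_den <- tab[j, "Df"]
    tol <- 1e-12 * max(1, abs(ss_eff) + abs(ss_err))
    if (ss_eff <= tol) {
      tibble::tibble(effect = effect, F_value = 0, df_num = df_num,
                     df_den = df_den, p_value = 1, degenerate = FALSE)
    } else if (ss_err <= tol) {
      tibble::tibble(effect = effect, F_value = Inf, df_num = df_num,
                     df_den = df_den, p_value = 0, degenerate = TRUE)
    } else {
      f <- (ss_eff / df_num) / (ss_err / df_den)
      tibble::tibble(effect = effect, F_value = f, df_num = df_num,
                     df_den = df_den,
                     p_value = stats::pf(f, df_num, df_den, lower.tail = FALSE),
                     degenerate = FALSE)
    }
  }
  dplyr::bind_rows(
    pull_stratum("a", "Error: subject:a"),
    pull_stratum("b", "Error: subject:b"),
    pull_stratum("a:b", "Error: subject:a:b")
  )
}

#' Mean and standard error of the mean
#'
#' @param x Numeric vector.
#' @return A list with `mean` and `sem` (= sd / sqrt(n)).
#' @keywords internal
mean_sem <- function(x) {
  x <- x[!is.na(x)]
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
}
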