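## Closed-form qPCR quantifications: 2^-dCT relative expression, ChIP
## percent-of-input, signal ratios with propagated SEM, decay profiles with
## half-life, and the one-tailed two-sample t-test.

#' Relative expression by the 2^-dCT method
#'
#' `2^-(ct_target - ct_reference)`; the reference target (e.g. a ribosomal
#' transcript) is supplied per measurement, never hard-coded.
#'
#' @param ct_target,ct_reference Finite Ct values (cycles); vectorized.
#' @return Relative expression ratio(s).
#' @examples
#' relative_expression_dct(25, 20)  # 2^-5
#' @export
relative_expression_dct <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    abort("Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}

#' ChIP enrichment as percent of input
#'
#' The input Ct is first adjusted for its dilution
#' (`ct_input - log2(1 / input_fraction)`), then
#' `percent = 100 * 2^(adjusted - ct_ip)`. Re-expressing the same input
#' dilution (shifting the Ct and scaling the fraction together) leaves the
#' result unchanged.
#'
#' @param ct_ip,ct_input Finite Ct values (cycles); vectorized.
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @return Percent of input.
#' @examples
#' percent_input(ct_ip = 25, ct_input = 22, input_fraction = 0.1)
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    abort("input_fraction must be in (0, 1]")
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Ratio of two percent-of-input signals with propagated SEM
#'
#' Per amplicon, the ratio of the numerator and denominator means, with the
#' SEM propagated to first order:
#' `sem = ratio * sqrt(cv_num^2 + cv_den^2)` where `cv = sem / mean`.
#'
#' @param numerator,denominator Tibbles with columns `amplicon` and `value`
#'   (replicate percent values), sharing the same amplicons.
#' @return Tibble with columns `amplicon`, `ratio`, `sem`, `n_num`, `n_den`.
#' @export
signal_ratio <- function(numerator, denominator) {
  summarize_side <- function(df, prefix) {
    df |>
      dplyr::group_by(.data$amplicon) |>
      dplyr::summarise(mean = mean(.data$value),
                       sem = sd(.data$value) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop") |>
      dplyr::rename_with(~ paste0(prefix, "_", .x), -"amplicon")
  }
  num <- summarize_side(numerator, "num")
  den <- summarize_side(denominator, "den")
  if (!setequal(num$amplicon, den$amplicon)) {
    abort("numerator and denominator must share the same amplicons")
  }
  merged <- dplyr::inner_join(num, den, by = "amplicon")
  if (any(merged$den_mean == 0)) abort("zero denominator mean")
  merged$num_sem[is.na(merged$num_sem)] <- 0
  merged$den_sem[is.na(merged$den_sem)] <- 0
  merged |>
    dplyr::mutate(
      ratio = .data$num_mean / .data$den_mean,
      sem = .data$ratio * sqrt((.data$num_sem / .data$num_mean)^2 +
                                 (.data$den_sem / .data$den_mean)^2)) |>
    dplyr::select("amplicon", "ratio", "sem", n_num = "num_n",
                  n_den = "den_n")
}

#' Transcript decay profile and half-life
#'
#' Divides every value by the value at the reference timepoint and, when at
#' least two positive relative values exist, fits `ln(relative) ~ time` by
#' least squares; the half-life is `ln(2) / |slope|` (infinite, and flagged,
#' for a non-decaying series).
#'
#' @param values Abundance values at `times` (e.g. 2^-dCT levels).
#' @param times Timepoints (minutes), same length as `values`.
#' @param t0_index Index of the reference timepoint (value must be > 0).
#' @return A `decay_fit` object: tibble of `time`, `value`, `relative` plus
#'   `half_life` and `slope` attributes; see [tidy()] / [glance()].
#' @examples
#' fit <- decay_profile(c(1, 0.5, 0.25), times = c(0, 10, 20))
#' glance(fit)
#' @export
decay_profile <- function(values, times, t0_index = 1) {
  if (length(values) != length(times)) {
    abort("values and times must have equal length")
  }
  if (!is.finite(values[t0_index]) || values[t0_index] <= 0) {
    abort("the reference timepoint value must be positive")
  }
  rel <- values / values[t0_index]
  pos <- is.finite(rel) & rel > 0
  slope <- NA_real_
  half_life <- NA_real_
  if (sum(pos) >= 2) {
    fit <- lm(log(rel[pos]) ~ times[pos])
    slope <- unname(coef(fit)[2])
    half_life <- if (abs(slope) < .Machine$double.eps^0.5) Inf
                 else log(2) / abs(slope)
  }
  structure(
    tibble::tibble(time = times, value = values, relative = rel),
    class = c("decay_fit", class(tibble::tibble())),
    slope = slope, half_life = half_life, t0_index = t0_index)
}

#' One-tailed two-sample Student's t-test
#'
#' Pooled-variance Student t (Welch available via `var_equal = FALSE`);
#' `direction = "greater"` tests the alternative that group A's mean exceeds
#' group B's, `"less"` the reverse. With zero pooled variance the P-value is
#' 0.5 for equal means by convention, and 0 or 1 (flagged by a warning) for
#' unequal means.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param direction `"greater"` (A > B) or `"less"` (A < B).
#' @param var_equal Pool the variances (classic Student test) or not
#'   (Welch).
#' @return One-row tibble: `t`, `df`, `p_value`, `direction`.
#' @export
one_tailed_t_test <- function(group_a, group_b,
                              direction = c("greater", "less"),
                              var_equal = TRUE) {
  direction <- match.arg(direction)
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) abort("each group needs at least 2 observations")
  ma <- mean(group_a); mb <- mean(group_b)
  if (var_equal) {
    sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
      (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- stats::var(group_a) / na; vb <- stats::var(group_b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  if (se == 0) {
    if (ma == mb) {
      return(tibble::tibble(t = 0, df = df, p_value = 0.5,
                            direction = direction))
    }
    warn("zero variance with unequal means: degenerate P-value")
    p <- if ((ma > mb) == (direction == "greater")) 0 else 1
    return(tibble::tibble(t = sign(ma - mb) * Inf, df = df, p_value = p,
                          direction = direction))
  }
  t <- (ma - mb) / se
  p <- if (direction == "greater") pt(t, df, lower.tail = FALSE)
       else pt(t, df, lower.tail = TRUE)
  tibble::tibble(t = t, df = df, p_value = p, direction = direction)
}
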