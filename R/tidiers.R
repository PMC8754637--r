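## broom-style tidiers for the package's result objects.

#' Tidy an overlap test result
#'
#' @param x An `overlap_result` from [overlap_permutation_test()].
#' @param ... Unused.
#' @return One-row tibble with the observed overlap, set and universe sizes
#'   and both P-values.
#' @method tidy overlap_result
#' @export
tidy.overlap_result <- function(x, ...) {
  tibble::tibble(k = x$k, K = x$K, n = x$n, N_A = x$N_A, N_B = x$N_B,
                 p_permutation = x$p_permutation,
                 p_hypergeometric = x$p_hypergeometric,
                 reps = x$reps, seed = x$seed)
}

#' @rdname tidy.overlap_result
#' @method glance overlap_result
#' @export
glance.overlap_result <- function(x, ...) {
  tibble::tibble(p_permutation = x$p_permutation,
                 p_hypergeometric = x$p_hypergeometric,
                 expected_overlap = x$K * x$n / x$N_hyper,
                 enrichment = x$k / (x$K * x$n / x$N_hyper))
}

#' Tidy a decay fit
#'
#' @param x A `decay_fit` from [decay_profile()].
#' @param ... Unused.
#' @return `tidy()`: the per-timepoint relative-remaining series;
#'   `glance()`: one row with `slope` and `half_life`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(time = x$time, value = x$value, relative = x$relative)
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(slope = attr(x, "slope"),
                 half_life = attr(x, "half_life"))
}
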