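## Occupancy-expression correlation, ratio-group classification, and
## gene-set overlap statistics (permutation and hypergeometric).

#' Mean and log-transformed FPKM per gene
#'
#' Averages replicate FPKM values per gene and applies the natural-log
#' transform `log(mean_fpkm + 1)`.
#'
#' @param fpkm_table Long tibble with columns `gene_id` and `fpkm` (one row
#'   per gene x replicate).
#' @return Tibble with columns `gene_id`, `n_reps`, `mean_fpkm`, `log_fpkm`.
#' @examples
#' mean_log_fpkm(data.frame(gene_id = c("g1", "g1"), fpkm = c(2, 4)))
#' @export
mean_log_fpkm <- function(fpkm_table) {
  if (any(fpkm_table$fpkm < 0)) abort("FPKM values must be non-negative")
  fpkm_table |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_reps = dplyr::n(),
                     mean_fpkm = mean(.data$fpkm), .groups = "drop") |>
    dplyr::mutate(log_fpkm = log(.data$mean_fpkm + 1))
}

#' Spearman rank correlation with an optional top-expressed filter
#'
#' When `top_expressed_fraction = f` is given, genes below the `1 - f`
#' quantile of the `y` variable are removed before ranking (the filter
#' applies to the expression variable only). Ties take average ranks; the
#' two-sided P-value uses the asymptotic t approximation.
#'
#' @param data Data frame with one row per gene.
#' @param x,y Columns to correlate (tidy evaluation).
#' @param top_expressed_fraction Optional fraction in (0, 1]; e.g. 0.9 keeps
#'   the top 90% of genes by `y`.
#' @return One-row tibble: `rho`, `p_value`, `n_used`, `n_removed`.
#' @examples
#' d <- data.frame(occ = 1:10, expr = (1:10)^2)
#' spearman_correlation(d, occ, expr)
#' @export
spearman_correlation <- function(data, x, y, top_expressed_fraction = NULL) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n_removed <- 0L
  if (!is.null(top_expressed_fraction)) {
    f <- top_expressed_fraction
    if (f <= 0 || f > 1) abort("top_expressed_fraction must be in (0, 1]")
    thr <- quantile(yv, probs = 1 - f, names = FALSE)
    sel <- yv >= thr
    n_removed <- sum(!sel)
    xv <- xv[sel]; yv <- yv[sel]
  }
  if (length(xv) < 3) abort("need at least 3 paired observations")
  if (length(unique(xv)) == 1 || length(unique(yv)) == 1) {
    abort("constant vector after filtering")
  }
  ct <- suppressWarnings(
    stats::cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n_used = length(xv), n_removed = n_removed)
}

#' Classify genes by the log2 ratio of two ChIP signals
#'
#' Computes `d = log2(upf1) - log2(polii)` per gene and labels genes
#' `high_ratio` (`d >= theta_high`), `low_ratio` (`d <= theta_low`) or
#' `similar`. Genes with both signals below `min_signal` are excluded as
#' `unclassified`; genes with a non-positive signal are excluded with a
#' warning count.
#'
#' @param upf1_table,polii_table Gene-signal tibbles (columns `gene_id`,
#'   `signal`) over a shared gene set.
#' @param theta_low,theta_high Log2-ratio thresholds, `theta_low <
#'   theta_high`.
#' @param min_signal Genes with both signals below this are unclassified.
#' @return Tibble with columns `gene_id`, `upf1`, `polii`, `log2_ratio`,
#'   `group` (factor: `high_ratio`, `low_ratio`, `similar`, `unclassified`).
#' @export
classify_ratio_groups <- function(upf1_table, polii_table, theta_low = -1,
                                  theta_high = 1, min_signal = 0) {
  if (theta_low >= theta_high) abort("theta_low must be < theta_high")
  merged <- dplyr::inner_join(
    dplyr::select(upf1_table, "gene_id", upf1 = "signal"),
    dplyr::select(polii_table, "gene_id", polii = "signal"),
    by = "gene_id")
  if (nrow(merged) == 0) abort("no shared genes between the two tables")

  weak <- merged$upf1 < min_signal & merged$polii < min_signal
  nonpos <- !weak & (merged$upf1 <= 0 | merged$polii <= 0)
  if (any(nonpos)) {
    warn(sprintf("classify_ratio_groups: %d gene(s) with non-positive signal excluded",
                 sum(nonpos)))
  }
  d <- rep(NA_real_, nrow(merged))
  ok <- !weak & !nonpos
  d[ok] <- log2(merged$upf1[ok]) - log2(merged$polii[ok])
  group <- rep("unclassified", nrow(merged))
  group[ok] <- dplyr::case_when(
    d[ok] >= theta_high ~ "high_ratio",
    d[ok] <= theta_low ~ "low_ratio",
    TRUE ~ "similar"
  )
  dplyr::mutate(merged, log2_ratio = d,
                group = factor(group, levels = c("high_ratio", "low_ratio",
                                                 "similar", "unclassified")))
}

#' One-sided hypergeometric overlap P-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the
#' chance of at least `k` common elements when subsets of sizes `K` and `n`
#' are drawn from an `N`-element universe. Computed in log space via
#' [stats::phyper()].
#'
#' @param k Observed overlap.
#' @param K Size of the first set.
#' @param n Size of the second set.
#' @param N Universe size.
#' @return P-value in (0, 1].
#' @examples
#' hypergeometric_overlap_test(k = 5, K = 5, n = 5, N = 10)  # 1/252
#' @export
hypergeometric_overlap_test <- function(k, K, n, N) {
  if (k > min(K, n) || K > N || n > N || k < 0) {
    abort("inconsistent counts: need k <= min(K, n) and K, n <= N")
  }
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Permutation test of gene-set overlap across two universes
#'
#' Each replicate draws `|set_a|` genes uniformly without replacement from
#' `universe_a` and `|set_b|` from `universe_b` and records the intersection
#' of the draws; the P-value is `(r + 1) / (reps + 1)` where `r` counts
#' replicates with overlap at least the observed `k = |set_a` \eqn{\cap}
#' `set_b|` (the add-one estimator, so 0 is never reported). The two
#' universes may differ (e.g. an annotation universe versus an expression
#' platform universe); draws are independent and genes are matched by id.
#' The companion hypergeometric P uses `N = |universe_a|` by default.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe_a,universe_b Character vectors containing their sets.
#' @param reps Number of permutation replicates (>= 1).
#' @param seed Integer seed for the draws.
#' @param hyper_universe Universe size for the hypergeometric companion
#'   P-value (default `length(universe_a)`).
#' @return An `overlap_result` object; see [tidy()] / [glance()] for a
#'   tibble view.
#' @export
overlap_permutation_test <- function(set_a, universe_a, set_b, universe_b,
                                     reps = 1000, seed = 1,
                                     hyper_universe = NULL) {
  if (reps < 1) abort("reps must be >= 1")
  if (!all(set_a %in% universe_a)) abort("set_a is not contained in universe_a")
  if (!all(set_b %in% universe_b)) abort("set_b is not contained in universe_b")
  k_obs <- length(intersect(set_a, set_b))
  K <- length(set_a); n_b <- length(set_b)
  N_A <- length(universe_a); N_B <- length(universe_b)

  # common id space for fast membership marking
  ids <- union(universe_a, universe_b)
  ua <- match(universe_a, ids)
  ub <- match(universe_b, ids)
  mark <- logical(length(ids))
  r <- 0L
  with_seed(seed, {
    for (i in seq_len(reps)) {
      da <- ua[sample.int(N_A, K)]
      db <- ub[sample.int(N_B, n_b)]
      mark[db] <- TRUE
      if (sum(mark[da]) >= k_obs) r <- r + 1L
      mark[db] <- FALSE
    }
  })
  p_perm <- (r + 1) / (reps + 1)
  N_hyper <- hyper_universe %||% N_A
  p_hyper <- hypergeometric_overlap_test(k_obs, K, n_b, N_hyper)
  structure(
    list(k = k_obs, K = K, n = n_b, N_A = N_A, N_B = N_B,
         N_hyper = N_hyper, p_permutation = p_perm,
         p_hypergeometric = p_hyper, reps = as.integer(reps),
         exceed_count = r, seed = as.integer(seed)),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    paste0("<overlap_result> k = %d (|A| = %d of %d, |B| = %d of %d)\n",
           "  p_permutation   = %.4g  (%d reps, seed %d)\n",
           "  p_hypergeometric = %.4g  (N = %d)\n"),
    x$k, x$K, x$N_A, x$n, x$N_B, x$p_permutation, x$reps, x$seed,
    x$p_hypergeometric, x$N_hyper))
  invisible(x)
}
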