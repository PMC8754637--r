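## Probe-level PM/MM processing: per-gene MAS5-style signals, control
## normalization, per-probe normalized values, and enriched-gene calling.

#' One-step Tukey biweight location
#'
#' Weighted location estimate around the median with MAD scale (unscaled
#' median absolute deviation plus a small epsilon, as in the Affymetrix
#' signal algorithm): weights `(1 - u^2)^2` for `|u| < 1`, zero otherwise,
#' with `u = (x - median) / (c * MAD + eps)`.
#'
#' @param x Numeric vector.
#' @param c Tuning constant (default 5).
#' @param eps Stabilizer added to the scale.
#' @return The biweight location (scalar).
#' @export
tukey_biweight <- function(x, c = 5, eps = 1e-4) {
  m <- median(x)
  s <- median(abs(x - m))
  u <- (x - m) / (c * s + eps)
  w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
  sum(w * x) / sum(w)
}

#' Summarize one gene's probe pairs into a signal value
#'
#' MAS5-style summary. Per probe pair the ideal mismatch is
#' `IM = min(mm, pm / 2)`: the mismatch estimates cross-hybridization
#' background, capped at half the perfect-match intensity so the contrast
#' never vanishes and the summary stays monotone in PM (a simplified rule
#' replacing the full Affymetrix specific-background chain); the probe value
#' is
#' `log2(pm - IM)` floored at `pm - IM >= 2^-20`; the gene signal is `2^T`
#' where `T` is the one-step Tukey biweight location of the probe values with
#' tuning constant 5.
#'
#' @param pm,mm Positive numeric vectors of equal length (>= 1 pair).
#' @return Positive scalar signal.
#' @examples
#' summarize_gene_signal(pm = c(200, 200), mm = c(100, 100))  # 100
#' @export
summarize_gene_signal <- function(pm, mm) {
  if (length(pm) == 0) abort("at least one probe pair is required")
  if (length(pm) != length(mm)) abort("pm and mm must have equal length")
  if (any(pm <= 0) || any(mm <= 0)) abort("pm and mm must be positive")
  im <- pmin(mm, pm / 2)
  pv <- log2(pmax(pm - im, 2^-20))
  2^tukey_biweight(pv, c = 5)
}

#' Per-gene signals for one array
#'
#' Applies [summarize_gene_signal()] to every gene in a probe table (probes
#' under the sentinel `"unassigned"` id are skipped).
#'
#' @param probes Probe tibble with columns `gene_id`, `pm`, `mm`.
#' @param origin Signal origin: `"ip"` or `"control"`.
#' @param assay Free-text assay label.
#' @return Gene-signal tibble with columns `gene_id`, `signal`, `origin`,
#'   `assay`.
#' @export
summarize_gene_signals <- function(probes, origin = "ip", assay = "") {
  probes |>
    dplyr::filter(.data$gene_id != "unassigned") |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(signal = summarize_gene_signal(.data$pm, .data$mm),
                     .groups = "drop") |>
    dplyr::mutate(origin = origin, assay = assay)
}

check_same_genes <- function(a, b, what = c("tableA", "tableB")) {
  only_a <- setdiff(a$gene_id, b$gene_id)
  only_b <- setdiff(b$gene_id, a$gene_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    abort(paste0(
      "gene sets differ: ",
      if (length(only_a) > 0)
        paste0("only in ", what[1], ": ",
               paste(head(only_a, 5), collapse = ", ")) else "",
      if (length(only_a) > 0 && length(only_b) > 0) "; " else "",
      if (length(only_b) > 0)
        paste0("only in ", what[2], ": ",
               paste(head(only_b, 5), collapse = ", ")) else ""))
  }
}

#' Scale two gene-signal tables to a common median
#'
#' Each table is multiplied by `target / median(signal)` where the target is
#' the arithmetic mean of the two medians, so both output medians are equal.
#'
#' @param table_a,table_b Gene-signal tibbles over the same gene set with
#'   positive medians.
#' @return List with elements `a` and `b`, the scaled tables.
#' @export
scale_to_common_median <- function(table_a, table_b) {
  check_same_genes(table_a, table_b)
  med_a <- median(table_a$signal)
  med_b <- median(table_b$signal)
  if (!is.finite(med_a) || !is.finite(med_b) || med_a <= 0 || med_b <= 0) {
    abort("both tables must have positive finite medians")
  }
  target <- (med_a + med_b) / 2
  list(a = dplyr::mutate(table_a, signal = .data$signal * target / med_a),
       b = dplyr::mutate(table_b, signal = .data$signal * target / med_b))
}

#' Average gene-signal tables
#'
#' Per-gene arithmetic mean over a list of tables covering identical gene
#' sets.
#'
#' @param tables List of gene-signal tibbles.
#' @return Gene-signal tibble (origin/assay taken from the first table).
#' @export
average_tables <- function(tables) {
  if (length(tables) == 0) abort("at least one table is required")
  for (i in seq_along(tables)[-1]) {
    check_same_genes(tables[[1]], tables[[i]],
                     what = c("table 1", paste("table", i)))
  }
  first <- tables[[1]]
  sig <- rowSums(vapply(tables, function(t) {
    t$signal[match(first$gene_id, t$gene_id)]
  }, numeric(nrow(first)))) / length(tables)
  dplyr::mutate(first, signal = sig)
}

#' Normalize an IP gene-signal table by its control
#'
#' Per-gene ratio `ip / control`. Genes whose control signal is not strictly
#' positive are excluded (their count is reported via a message), mirroring a
#' missing-data policy rather than fabricating a ratio.
#'
#' @param ip_table,control_table Gene-signal tibbles over the same gene set.
#' @return Normalized gene-signal tibble (`origin = "normalized"`) with the
#'   control assay recorded in the `control_assay` attribute.
#' @export
normalize_by_control <- function(ip_table, control_table) {
  check_same_genes(ip_table, control_table, what = c("ip", "control"))
  ctl <- control_table$signal[match(ip_table$gene_id,
                                    control_table$gene_id)]
  bad <- !(ctl > 0) | is.na(ctl)
  if (any(bad)) {
    inform(sprintf("normalize_by_control: %d gene(s) dropped (control <= 0)",
                   sum(bad)))
  }
  out <- ip_table[!bad, ]
  out$signal <- out$signal / ctl[!bad]
  out$origin <- "normalized"
  attr(out, "control_assay") <- unique(control_table$assay)
  out
}

#' Per-probe normalized values
#'
#' For every probe the PM/MM ratio is computed per array; the control
#' arrays' ratios are averaged into a control mean; each IP array's ratio is
#' divided by that control mean; and when several IP arrays are given their
#' normalized values are averaged per probe.
#'
#' @param ip_arrays Probe tibble or list of probe tibbles (the IP arrays).
#' @param control_arrays Probe tibble or list of probe tibbles (controls).
#' @return Tibble with the probe annotation columns plus `value`, the
#'   normalized PM/MM ratio.
#' @export
probe_normalized_values <- function(ip_arrays, control_arrays) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  ip_arrays <- as_list(ip_arrays)
  control_arrays <- as_list(control_arrays)
  if (length(ip_arrays) == 0 || length(control_arrays) == 0) {
    abort("at least one IP and one control array are required")
  }
  ref <- ip_arrays[[1]]
  all_arrays <- c(ip_arrays, control_arrays)
  for (t in all_arrays[-1]) {
    if (!setequal(ref$probe_id, t$probe_id)) {
      abort("all arrays must share the same probe set")
    }
  }
  ratio_of <- function(t) {
    r <- t$pm / t$mm
    r[match(ref$probe_id, t$probe_id)]
  }
  ctl_mean <- rowMeans(vapply(control_arrays, ratio_of,
                              numeric(nrow(ref))))
  norm <- vapply(ip_arrays, function(t) ratio_of(t) / ctl_mean,
                 numeric(nrow(ref)))
  out <- ref[, intersect(c("probe_id", "chrom", "position", "strand",
                           "gene_id"), names(ref))]
  out$value <- rowMeans(norm)
  out
}

# enriched-gene calling --------------------------------------------------

#' Call enriched genes from per-probe normalized values
#'
#' A simplified window caller preserving the study's downstream rules. Probe
#' scores are `log(value)` standardized genome-wide with a robust z
#' (median / MAD with the 1.4826 consistency constant; falls back to the SD
#' when the MAD is zero, and errors when both are). The window statistic at
#' each probe is the 10%-trimmed mean of scores within `window_bp / 2` on
#' either side, scaled by the square root of the number of probes retained
#' after trimming; one-sided probe P-values come from the standard normal.
#' Significant probes (`P < p_cutoff`) within `maxgap_bp` of each other merge
#' into regions (extended by the probe footprint), and a gene is enriched iff
#' the merged regions cover at least 50% of its length in bp. The
#' enrichment score is the mean normalized value of probes lying within the
#' merged region span(s) overlapping the gene.
#'
#' @param probe_values Tibble from [probe_normalized_values()].
#' @param annotation A [genome_annotation()].
#' @param p_cutoff One-sided probe P cutoff in (0, 1).
#' @param window_bp Window width in bp.
#' @param maxgap_bp Maximum gap between significant probes merged into one
#'   region.
#' @param trim Trim fraction for the window mean.
#' @param probe_len Probe footprint length (bp).
#' @return Tibble with one row per gene: `gene_id`, `chrom`, `enriched`,
#'   `fraction_significant`, `enrichment_score`, `region_start`,
#'   `region_end`, `n_probes`.
#' @export
call_enriched_genes <- function(probe_values, annotation, p_cutoff = 1e-3,
                                window_bp = 300, maxgap_bp = 300,
                                trim = 0.1, probe_len = 25) {
  if (nrow(probe_values) == 0) abort("empty probe set")
  if (p_cutoff <= 0 || p_cutoff >= 1) abort("p_cutoff must be in (0, 1)")
  pv <- probe_values[is.finite(probe_values$value) & probe_values$value > 0, ]
  if (nrow(pv) == 0) abort("no probes with positive normalized values")

  score <- log(pv$value)
  ctr <- median(score)
  scl <- mad(score)  # 1.4826 * median |dev|
  if (scl == 0) scl <- sd(score)
  if (!is.finite(scl) || scl == 0) {
    abort("degenerate probe scores: zero MAD and zero SD")
  }
  z <- (score - ctr) / scl

  half <- window_bp / 2
  pv$p <- NA_real_
  regions <- list()
  for (chrom in unique(pv$chrom)) {
    sel <- which(pv$chrom == chrom)
    ord <- sel[order(pv$position[sel])]
    pos <- pv$position[ord]
    zc <- z[ord]
    lo <- findInterval(pos - half, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + half, pos)
    stat <- vapply(seq_along(pos), function(i) {
      w <- zc[lo[i]:hi[i]]
      n <- length(w)
      k <- floor(trim * n)
      if (k > 0) w <- sort(w)[(k + 1):(n - k)]
      mean(w) * sqrt(n - 2 * k)
    }, numeric(1))
    p <- pnorm(stat, lower.tail = FALSE)
    pv$p[ord] <- p
    sig_pos <- pos[p < p_cutoff]
    if (length(sig_pos) > 0) {
      brk <- c(0L, which(diff(sig_pos) > maxgap_bp), length(sig_pos))
      regions[[chrom]] <- tibble::tibble(
        chrom = chrom,
        start = sig_pos[brk[-length(brk)] + 1L],
        end = sig_pos[brk[-1]] + probe_len
      )
    }
  }
  regions <- dplyr::bind_rows(regions)

  g <- annotation$genes
  out <- purrr::map_dfr(seq_len(nrow(g)), function(i) {
    gl <- g$end[i] - g$start[i]
    rr <- if (nrow(regions) > 0) {
      regions[regions$chrom == g$chrom[i] & regions$start < g$end[i] &
                regions$end > g$start[i], ]
    } else regions
    if (nrow(rr) == 0) {
      covered <- 0
      score_i <- NA_real_
      rs <- re <- NA_integer_
    } else {
      covered <- sum(pmin(rr$end, g$end[i]) - pmax(rr$start, g$start[i]))
      in_region <- pv$chrom == g$chrom[i] &
        purrr::reduce(purrr::map2(rr$start, rr$end, function(s, e) {
          pv$position >= s & pv$position < e
        }), `|`)
      score_i <- mean(pv$value[in_region])
      rs <- min(rr$start)
      re <- max(rr$end)
    }
    frac <- covered / gl
    tibble::tibble(
      gene_id = g$gene_id[i], chrom = g$chrom[i],
      enriched = frac >= 0.5,
      fraction_significant = pmin(frac, 1),
      enrichment_score = score_i,
      region_start = rs, region_end = re,
      n_probes = sum(pv$chrom == g$chrom[i] & pv$position >= g$start[i] &
                       pv$position < g$end[i])
    )
  })
  out
}
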