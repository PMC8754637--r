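## Metagene profiles: percent-position profiles pooled over tiling-array
## probes, and fixed-flank / scaled-body profiles over per-base coverage.
##
## Both profile builders return a `metagene_profile`: a tibble of bin means
## and contribution counts with axis metadata in attributes.

new_metagene_profile <- function(df, kind, ...) {
  structure(df, class = c("metagene_profile", class(df)), kind = kind, ...)
}

#' Percent position of probes within their genes
#'
#' The offset `u` of the probe's 5'-most base (in transcription direction)
#' from the TSS is converted to `100 * u / (L - probe_len)` so that 0% is the
#' TSS and 100% is `probe_len - 1` bp upstream of the TES (the last position
#' where the full footprint fits inside the gene). Probes with `u` outside
#' `[0, L - probe_len]` are flagged out of range.
#'
#' @param probes Probe tibble with columns `gene_id`, `position` (genomic
#'   coordinate of the lowest-coordinate footprint base).
#' @param genes Gene tibble (from a [genome_annotation()]); every gene
#'   referenced by `probes` must be longer than `probe_len`.
#' @param probe_len Probe footprint length (bp).
#' @return The probe tibble with added columns `percent` and `in_range`.
#' @export
probe_percent_position <- function(probes, genes, probe_len = 25) {
  idx <- match(probes$gene_id, genes$gene_id)
  if (anyNA(idx)) {
    abort("probes reference gene_ids missing from the annotation")
  }
  L <- genes$end[idx] - genes$start[idx]
  if (any(L <= probe_len)) {
    abort(sprintf("gene length must exceed probe_len (%d bp)", probe_len))
  }
  plus <- genes$strand[idx] == "+"
  u <- ifelse(plus,
              probes$position - genes$start[idx],
              genes$end[idx] - probes$position - probe_len)
  probes$percent <- 100 * u / (L - probe_len)
  probes$in_range <- u >= 0 & u <= (L - probe_len)
  probes
}

#' Probe metagene profile in 0.1% blocks
#'
#' Each in-range probe contributes its normalized value to the bin
#' `floor(percent / (100 / n_bins))` (bins are half-open, with 100% assigned
#' to the last bin); bin means pool probes over all genes.
#'
#' @param probe_values Tibble from [probe_normalized_values()] (columns
#'   `gene_id`, `position`, `value`).
#' @param annotation A [genome_annotation()].
#' @param probe_len Probe footprint length (bp).
#' @param n_bins Number of percent bins (default 1000, i.e. 0.1% blocks).
#' @return A `metagene_profile` tibble with columns `bin` (0-based),
#'   `position` (bin midpoint in %), `mean`, `count`.
#' @export
build_probe_metagene <- function(probe_values, annotation, probe_len = 25,
                                 n_bins = 1000) {
  pv <- probe_values[probe_values$gene_id != "unassigned", ]
  if (nrow(pv) == 0) abort("no probes assigned to genes")
  pv <- probe_percent_position(pv, annotation$genes, probe_len = probe_len)
  pv <- pv[pv$in_range, ]
  if (nrow(pv) == 0) abort("no in-range probes")
  width <- 100 / n_bins
  bin <- pmin(floor(pv$percent / width), n_bins - 1L)
  f <- factor(bin, levels = 0:(n_bins - 1))
  sums <- as.vector(tapply(pv$value, f, sum))
  cnts <- as.vector(table(f))
  df <- tibble::tibble(
    bin = 0:(n_bins - 1),
    position = (0:(n_bins - 1) + 0.5) * width,
    mean = ifelse(cnts > 0, sums / cnts, NA_real_),
    count = as.integer(cnts)
  )
  new_metagene_profile(df, kind = "percent_position", bin_width = width)
}

#' Fixed-flank / scaled-body metagene profile
#'
#' Averages a normalized coverage track over all genes on a common axis:
#' a fixed upstream flank (per-bp means at positions `-flank..-1` relative to
#' the TSS in transcription direction), the gene body linearly partitioned
#' into `body_bins` equal fractional windows (window value = coverage mean
#' weighted by base-overlap fraction; each contributing gene carries equal
#' weight in the bin mean), and a fixed downstream flank (`TES+1..TES+flank`).
#' Flank bases beyond a chromosome edge and masked (`NA`) bases are excluded
#' from the means, never zero-filled. Genes shorter than `min_length`
#' (default `body_bins / 10`) are excluded.
#'
#' @param track A normalized [coverage_track()].
#' @param annotation A [genome_annotation()].
#' @param flank Flank width in bp.
#' @param body_bins Number of scaled body windows.
#' @param min_length Minimum gene length in bp.
#' @return A `metagene_profile` tibble with columns `bin` (1-based across
#'   the concatenated axis), `segment` (`upstream` / `body` / `downstream`),
#'   `position` (bp relative to TSS/TES for flanks, percent for the body),
#'   `mean`, `count`.
#' @export
build_flank_body_metagene <- function(track, annotation, flank = 1000,
                                      body_bins = 1000, min_length = NULL) {
  stopifnot(inherits(track, "coverage_track"))
  min_length <- min_length %||% (body_bins / 10)
  g <- annotation$genes
  g <- g[(g$end - g$start) >= min_length, ]
  if (nrow(g) == 0) abort("no genes pass the minimum-length filter")

  up_sum <- up_cnt <- numeric(flank)
  dn_sum <- dn_cnt <- numeric(flank)
  body_sum <- body_cnt <- numeric(body_bins)

  for (i in seq_len(nrow(g))) {
    v <- track$values[[g$chrom[i]]]
    clen <- length(v)
    s <- g$start[i]; e <- g$end[i]
    plus <- g$strand[i] == "+"

    # flank offsets 1..flank: offset k is k bp upstream of the TSS
    # (downstream of the TES) in transcription direction
    up_pos <- if (plus) s - (1:flank) else e - 1L + (1:flank)
    dn_pos <- if (plus) e - 1L + (1:flank) else s - (1:flank)
    for (side in c("up", "dn")) {
      pos <- if (side == "up") up_pos else dn_pos
      valid <- pos >= 0 & pos < clen
      vals <- rep(NA_real_, flank)
      vals[valid] <- v[pos[valid] + 1L]
      ok <- !is.na(vals)
      if (side == "up") {
        up_sum[ok] <- up_sum[ok] + vals[ok]
        up_cnt[ok] <- up_cnt[ok] + 1
      } else {
        dn_sum[ok] <- dn_sum[ok] + vals[ok]
        dn_cnt[ok] <- dn_cnt[ok] + 1
      }
    }

    # body: fractional windows via interpolated cumulative sums, NA-aware
    vb <- v[(s + 1L):e]
    wb <- as.numeric(!is.na(vb))
    vb0 <- ifelse(is.na(vb), 0, vb)
    CS <- c(0, cumsum(vb0))
    CW <- c(0, cumsum(wb))
    L <- e - s
    edges <- (0:body_bins) * (L / body_bins)
    interp <- function(C, x) {
      f <- floor(x)
      frac <- x - f
      base <- C[f + 1L]
      add <- ifelse(f < L, frac * (C[f + 2L] - C[f + 1L]), 0)
      base + add
    }
    sv <- interp(CS, edges)
    wv <- interp(CW, edges)
    num <- diff(sv)
    den <- diff(wv)
    val <- ifelse(den > 1e-12, num / den, NA_real_)
    if (!plus) val <- rev(val)
    ok <- !is.na(val)
    body_sum[ok] <- body_sum[ok] + val[ok]
    body_cnt[ok] <- body_cnt[ok] + 1
  }

  up_sum <- rev(up_sum)
  up_cnt <- rev(up_cnt)
  df <- dplyr::bind_rows(
    tibble::tibble(segment = "upstream", position = -(flank:1),
                   mean = ifelse(up_cnt > 0, up_sum / up_cnt, NA_real_),
                   count = as.integer(up_cnt)),
    tibble::tibble(segment = "body",
                   position = (seq_len(body_bins) - 0.5) * (100 / body_bins),
                   mean = ifelse(body_cnt > 0, body_sum / body_cnt, NA_real_),
                   count = as.integer(body_cnt)),
    tibble::tibble(segment = "downstream", position = as.numeric(1:flank),
                   mean = ifelse(dn_cnt > 0, dn_sum / dn_cnt, NA_real_),
                   count = as.integer(dn_cnt))
  )
  df <- dplyr::mutate(df, bin = dplyr::row_number(), .before = 1)
  new_metagene_profile(df, kind = "flank_body_flank", flank = flank,
                       body_bins = body_bins)
}

#' Write a metagene profile as TSV
#'
#' @param profile A `metagene_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metagene <- function(profile, path) {
  readr::write_tsv(tibble::as_tibble(profile), path, progress = FALSE)
  invisible(path)
}
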