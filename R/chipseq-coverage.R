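## Per-base ChIP-seq coverage: pileup, depth normalization, input
## normalization and replicate averaging.

#' Per-base coverage from read intervals
#'
#' The value at each base is the number of read intervals containing it, so
#' the sum over all bases equals the total read-bases.
#'
#' @param reads BED-style tibble with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A raw [coverage_track()].
#' @export
coverage_from_reads <- function(reads, chrom_lengths) {
  bad_chrom <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(bad_chrom) > 0) {
    abort(paste0("reads on unknown chromosome(s): ",
                 paste(bad_chrom, collapse = ", ")))
  }
  out_of_bounds <- reads$start < 0 | reads$end > chrom_lengths[reads$chrom] |
    reads$start >= reads$end
  if (any(out_of_bounds)) {
    abort(sprintf("%d read interval(s) outside chromosome bounds",
                  sum(out_of_bounds)))
  }
  values <- lapply(names(chrom_lengths), function(chrom) {
    r <- reads[reads$chrom == chrom, ]
    if (nrow(r) == 0) return(numeric(chrom_lengths[[chrom]]))
    cov <- IRanges::coverage(IRanges::IRanges(start = r$start + 1L,
                                              end = r$end),
                             width = chrom_lengths[[chrom]])
    as.numeric(cov)
  })
  coverage_track(setNames(values, names(chrom_lengths)), label = "reads",
                 normalized = FALSE)
}

#' Depth-normalize a coverage track
#'
#' Divides every base by the total number of aligned reads in the library.
#'
#' @param track A [coverage_track()].
#' @param total_aligned_reads Positive read count.
#' @return A normalized [coverage_track()].
#' @export
depth_normalize <- function(track, total_aligned_reads) {
  stopifnot(inherits(track, "coverage_track"))
  if (total_aligned_reads <= 0) abort("total_aligned_reads must be > 0")
  coverage_track(lapply(track$values, `/`, total_aligned_reads),
                 label = paste0(track$label, "/depth"), normalized = TRUE)
}

#' Input-normalize an IP coverage track
#'
#' Base-wise ratio `ip / input`. Bases where the input is zero are masked
#' (`NA`, the default) or regularized with a pseudocount
#' `(ip + epsilon) / (input + epsilon)`.
#'
#' @param ip_track,input_track Depth-normalized [coverage_track()]s over the
#'   same chromosomes.
#' @param policy `"mask"` or `"pseudocount"`.
#' @param epsilon Pseudocount (used only under `policy = "pseudocount"`).
#' @return A normalized [coverage_track()]; masked bases are `NA`.
#' @export
input_normalize <- function(ip_track, input_track,
                            policy = c("mask", "pseudocount"),
                            epsilon = 1e-9) {
  policy <- match.arg(policy)
  stopifnot(inherits(ip_track, "coverage_track"),
            inherits(input_track, "coverage_track"))
  if (!setequal(names(ip_track$values), names(input_track$values))) {
    abort("ip and input tracks cover different chromosome sets")
  }
  if (!ip_track$normalized || !input_track$normalized) {
    warn("input_normalize expects depth-normalized tracks")
  }
  values <- lapply(names(ip_track$values), function(chrom) {
    ip <- ip_track$values[[chrom]]
    inp <- input_track$values[[chrom]]
    if (length(ip) != length(inp)) {
      abort(paste0("track lengths differ on ", chrom))
    }
    if (policy == "mask") {
      out <- ip / inp
      out[inp == 0] <- NA_real_
      out
    } else {
      (ip + epsilon) / (inp + epsilon)
    }
  })
  coverage_track(setNames(values, names(ip_track$values)),
                 label = paste0(ip_track$label, "/", input_track$label),
                 normalized = TRUE)
}

#' Average coverage tracks base-wise
#'
#' Arithmetic mean per base. A base is missing in the mean iff it is missing
#' in any input track, so replicate averaging never fabricates coverage at a
#' masked base.
#'
#' @param tracks Non-empty list of [coverage_track()]s over the same
#'   chromosomes.
#' @return A [coverage_track()].
#' @export
average_tracks <- function(tracks) {
  if (length(tracks) == 0) abort("at least one track is required")
  ref <- tracks[[1]]
  for (t in tracks[-1]) {
    if (!setequal(names(t$values), names(ref$values))) {
      abort("tracks cover different chromosome sets")
    }
  }
  values <- lapply(names(ref$values), function(chrom) {
    mats <- vapply(tracks, function(t) t$values[[chrom]],
                   numeric(length(ref$values[[chrom]])))
    rowSums(mats) / length(tracks)  # NA propagates through the sum
  })
  coverage_track(setNames(values, names(ref$values)),
                 label = paste0("mean(", length(tracks), ")"),
                 normalized = ref$normalized)
}
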