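# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive quantities by the most literal route
# (enumeration, per-base loops) so they share no code with the package.

# Hypergeometric upper tail by direct enumeration of choose-products.
hyper_enum <- function(k, K, n, N) {
  j <- k:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Spearman rho by the classic 1 - 6*sum(d^2)/(n(n^2-1)) formula (no ties).
spearman_formula <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Naive probe metagene: one probe at a time, straight loops.
brute_probe_metagene <- function(probe_values, annotation, probe_len = 25,
                                 n_bins = 1000) {
  g <- annotation$genes
  sums <- numeric(n_bins)
  cnts <- integer(n_bins)
  for (i in seq_len(nrow(probe_values))) {
    gid <- probe_values$gene_id[i]
    if (gid == "unassigned") next
    row <- g[g$gene_id == gid, ]
    L <- row$end - row$start
    u <- if (row$strand == "+") probe_values$position[i] - row$start
         else row$end - probe_values$position[i] - probe_len
    if (u < 0 || u > L - probe_len) next
    pct <- 100 * u / (L - probe_len)
    bin <- min(floor(pct / (100 / n_bins)), n_bins - 1)
    sums[bin + 1] <- sums[bin + 1] + probe_values$value[i]
    cnts[bin + 1] <- cnts[bin + 1] + 1L
  }
  list(mean = ifelse(cnts > 0, sums / cnts, NA_real_), count = cnts)
}

# Naive flank/body metagene: per gene, per base, fractional body windows
# accumulated base by base.
brute_flank_body <- function(track, annotation, flank = 1000,
                             body_bins = 1000, min_length = body_bins / 10) {
  g <- annotation$genes
  g <- g[(g$end - g$start) >= min_length, ]
  up_s <- up_c <- numeric(flank)
  dn_s <- dn_c <- numeric(flank)
  b_s <- b_c <- numeric(body_bins)
  for (i in seq_len(nrow(g))) {
    v <- track$values[[g$chrom[i]]]
    clen <- length(v)
    s <- g$start[i]; e <- g$end[i]; L <- e - s
    plus <- g$strand[i] == "+"
    for (k in 1:flank) {
      upos <- if (plus) s - k else e - 1 + k
      dpos <- if (plus) e - 1 + k else s - k
      if (upos >= 0 && upos < clen && !is.na(v[upos + 1])) {
        up_s[flank - k + 1] <- up_s[flank - k + 1] + v[upos + 1]
        up_c[flank - k + 1] <- up_c[flank - k + 1] + 1
      }
      if (dpos >= 0 && dpos < clen && !is.na(v[dpos + 1])) {
        dn_s[k] <- dn_s[k] + v[dpos + 1]
        dn_c[k] <- dn_c[k] + 1
      }
    }
    for (j in 1:body_bins) {
      a <- s + (j - 1) * L / body_bins
      b <- s + j * L / body_bins
      num <- 0; den <- 0
      for (base in floor(a):(ceiling(b) - 1)) {
        w <- min(b, base + 1) - max(a, base)
        if (w > 0 && !is.na(v[base + 1])) {
          num <- num + w * v[base + 1]
          den <- den + w
        }
      }
      jj <- if (plus) j else body_bins - j + 1
      if (den > 1e-12) {
        b_s[jj] <- b_s[jj] + num / den
        b_c[jj] <- b_c[jj] + 1
      }
    }
  }
  list(
    up = ifelse(up_c > 0, up_s / up_c, NA_real_),
    body = ifelse(b_c > 0, b_s / b_c, NA_real_),
    down = ifelse(dn_c > 0, dn_s / dn_c, NA_real_)
  )
}

# Minimal annotation: genes placed explicitly.
tiny_annotation <- function(starts, ends, strands, chrom_len = NULL,
                            chrom = "chr1") {
  genome_annotation(
    tibble::tibble(
      gene_id = sprintf("g%02d", seq_along(starts)),
      chrom = chrom, start = starts, end = ends, strand = strands
    ),
    chrom_lengths = if (is.null(chrom_len)) NULL
                    else setNames(as.integer(chrom_len), chrom)
  )
}

# Direct probe-value fixture for the enriched-gene caller: background probes
# every `spacing` bp with lognormal noise, selected genes elevated `fold`-x
# over a fraction of their length (anchored at the gene start).
make_probe_values <- function(annotation, enriched_genes = character(0),
                              fold = 10, frac_of_gene = 1, spacing = 20,
                              noise_sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    g <- annotation$genes
    out <- lapply(names(annotation$chrom_lengths), function(chrom) {
      len <- annotation$chrom_lengths[[chrom]]
      pos <- seq.int(0L, len - 25L, by = spacing)
      value <- exp(rnorm(length(pos), 0, noise_sd))
      gene_id <- rep("unassigned", length(pos))
      rows <- which(g$chrom == chrom)
      for (i in rows) {
        inside <- pos >= g$start[i] & pos < g$end[i]
        gene_id[inside] <- g$gene_id[i]
        if (g$gene_id[i] %in% enriched_genes) {
          lift <- pos >= g$start[i] &
            pos < g$start[i] + frac_of_gene * (g$end[i] - g$start[i])
          value[lift] <- value[lift] * fold
        }
      }
      tibble::tibble(chrom = chrom, position = pos, gene_id = gene_id,
                     value = value)
    })
    dplyr::bind_rows(out) |>
      dplyr::mutate(probe_id = sprintf("p%05d", dplyr::row_number()),
                    .before = 1)
  })
}
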