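## Synthetic-data generators with planted, recorded ground truth.
##
## All generators are pure functions of (seed, parameters): one root seed
## derives per-component child seeds by fixed offsets (see sim_seeds()), and
## RNG state is restored on exit, so identical inputs give identical outputs
## byte-for-byte regardless of the caller's RNG state.

SIM_SEED_OFFSETS <- c(annotation = 1L, occupancy = 2L, probe_array = 3L,
                      probe_control = 4L, chipseq = 5L, expression = 6L,
                      de_labels = 7L, permutation = 8L)

#' Child seeds derived from one root seed
#'
#' Each simulator component consumes its own child seed so that re-running a
#' single component does not disturb the others. Offsets are fixed; seeds are
#' kept below 2^31.
#'
#' @param seed Root integer seed.
#' @return Named integer vector of per-component seeds.
#' @export
sim_seeds <- function(seed) {
  seed <- as.integer(seed)
  setNames(as.integer((as.numeric(seed) * 131L + SIM_SEED_OFFSETS) %%
                        2147483647), names(SIM_SEED_OFFSETS))
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# annotation -------------------------------------------------------------

#' Simulate a compact genome annotation
#'
#' Places non-overlapping genes with log-normally distributed lengths and
#' exponential-tailed intergenic gaps (never below `gap_min`) along
#' `n_chroms` chromosomes, with strands drawn Bernoulli(0.5). Chromosome
#' lengths are sized to the placement unless `chrom_length` pins them, in
#' which case an overflow is an error.
#'
#' @param seed Integer seed (deterministic output).
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes.
#' @param length_meanlog,length_sdlog Log-normal parameters of gene length
#'   (defaults give a median of 1500 bp).
#' @param length_range Gene lengths are clamped into this range (bp).
#' @param gap_min Minimum intergenic gap (bp).
#' @param gap_mean Mean intergenic gap (bp).
#' @param chrom_length Optional fixed chromosome length; error if the genes
#'   do not fit.
#' @return A [genome_annotation()].
#' @examples
#' ann <- simulate_annotation(seed = 1, n_genes = 20)
#' ann$genes
#' @export
simulate_annotation <- function(seed, n_genes = 200, n_chroms = 2,
                                length_meanlog = log(1500),
                                length_sdlog = 0.45,
                                length_range = c(300, 8000),
                                gap_min = 200, gap_mean = 500,
                                chrom_length = NULL) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (n_chroms < 1) abort("n_chroms must be >= 1")
  with_seed(seed, {
    lens <- round(pmin(pmax(rlnorm(n_genes, length_meanlog, length_sdlog),
                            length_range[1]), length_range[2]))
    gaps <- round(gap_min + rexp(n_genes + n_chroms,
                                 1 / max(gap_mean - gap_min, 1)))
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)

    chrom_of <- sort(rep_len(seq_len(n_chroms), n_genes))
    genes <- vector("list", n_chroms)
    chrom_lengths <- integer(n_chroms)
    gi <- 1L
    for (ci in seq_len(n_chroms)) {
      idx <- which(chrom_of == ci)
      pos <- 0L
      starts <- ends <- integer(length(idx))
      for (j in seq_along(idx)) {
        pos <- pos + as.integer(gaps[gi])
        starts[j] <- pos
        pos <- pos + as.integer(lens[idx[j]])
        ends[j] <- pos
        gi <- gi + 1L
      }
      chrom_lengths[ci] <- pos + as.integer(gaps[gi])
      gi <- gi + 1L
      genes[[ci]] <- tibble::tibble(
        gene_id = sprintf("g%04d", idx),
        chrom = sprintf("chr%d", ci),
        start = starts, end = ends,
        strand = strands[idx],
        biotype = "protein_coding"
      )
      if (!is.null(chrom_length) && chrom_lengths[ci] > chrom_length) {
        abort(sprintf(
          "requested genes cannot fit: chr%d needs %d bp but chrom_length is %d",
          ci, chrom_lengths[ci], as.integer(chrom_length)))
      }
    }
    if (!is.null(chrom_length)) chrom_lengths[] <- as.integer(chrom_length)
    genome_annotation(dplyr::bind_rows(genes),
                      setNames(chrom_lengths,
                               sprintf("chr%d", seq_len(n_chroms))))
  })
}

# occupancy ground truth -------------------------------------------------

#' Simulate per-gene occupancy ground truth
#'
#' Draws a latent transcription rate tau per gene (log-normal), sets Pol II
#' occupancy equal to tau, and plants a "bound" subset whose second-factor
#' (e.g. Upf1) occupancy follows `tau * exp(sigma_eps * eps)`; unbound genes
#' receive occupancy strictly below `background`. The bound subset is drawn
#' with probability proportional to tau — chromatin association of an
#' RNA-binding factor tracks active transcription, so binding is planted
#' preferentially at transcribed genes rather than uniformly. Unless `sigma_eps` is given,
#' the noise scale is solved by bisection so that the realized Spearman
#' correlation between the two occupancies over all genes matches
#' `rho_target`; the realized value and solved sigma are recorded as
#' attributes (`realized_rho`, `sigma_eps`). Genes are labelled
#' `high_ratio` / `low_ratio` / `similar` from `log2(upf1 / polii)` against
#' `ratio_thresholds`. Noisy per-gene measured signals (`upf1_signal`,
#' `polii_signal`) emulate assay-level measurement error on top of the latent
#' occupancies.
#'
#' @param seed Integer seed.
#' @param annotation A [genome_annotation()].
#' @param frac_bound Fraction of genes in the bound subset (exact count,
#'   `round(frac_bound * n)`).
#' @param rho_target Target Spearman correlation in (0, 1); ignored when
#'   `sigma_eps` is supplied.
#' @param ratio_thresholds Length-2 numeric `c(theta_low, theta_high)` on the
#'   log2 ratio scale.
#' @param tau_sdlog Log-sd of the latent rate.
#' @param background Background occupancy level bounding unbound genes.
#' @param sigma_eps Optional fixed noise scale (skips the solve).
#' @param signal_noise_sd Log-sd of the measurement noise on the emitted
#'   signal columns.
#' @param fpkm_scale Proportionality constant between tau and true FPKM.
#' @return Tibble (one row per gene) with columns `gene_id`, `tau`,
#'   `polii_occupancy`, `upf1_occupancy`, `bound`, `group_label`,
#'   `fpkm_true`, `upf1_signal`, `polii_signal`; attributes `sigma_eps`,
#'   `realized_rho`, `background`, `ratio_thresholds`.
#' @export
simulate_occupancy <- function(seed, annotation, frac_bound = 0.5,
                               rho_target = 0.56,
                               ratio_thresholds = c(-1, 1),
                               tau_sdlog = 1, background = 0.05,
                               sigma_eps = NULL, signal_noise_sd = 0.1,
                               fpkm_scale = 10) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (frac_bound < 0 || frac_bound > 1) abort("frac_bound must be in [0, 1]")
  if (is.null(sigma_eps) && (rho_target <= 0 || rho_target >= 1)) {
    abort("rho_target must be in (0, 1)")
  }
  if (length(ratio_thresholds) != 2 ||
      ratio_thresholds[1] >= ratio_thresholds[2]) {
    abort("ratio_thresholds must be c(theta_low, theta_high) with low < high")
  }
  n <- nrow(annotation$genes)
  with_seed(seed, {
    tau <- rlnorm(n, 0, tau_sdlog)
    bound <- rep(FALSE, n)
    n_bound <- round(frac_bound * n)
    if (n_bound > 0) bound[sample.int(n, n_bound, prob = tau)] <- TRUE
    eps <- rnorm(n)
    bg_vals <- background * exp(-abs(rnorm(n)))  # strictly below background
    meas1 <- rnorm(n, 0, signal_noise_sd)
    meas2 <- rnorm(n, 0, signal_noise_sd)

    upf1_at <- function(sig) {
      ifelse(bound, tau * exp(sig * eps), bg_vals)
    }
    rho_at <- function(sig) {
      suppressWarnings(cor(upf1_at(sig), tau, method = "spearman"))
    }

    if (is.null(sigma_eps)) {
      if (n_bound == 0) {
        sigma_eps <- 0
      } else {
        rho0 <- rho_at(0)
        if (is.na(rho0) || rho0 <= rho_target) {
          if (!is.na(rho0) && rho0 < rho_target - 0.05) {
            warn(sprintf(
              "rho_target %.2f not attainable at frac_bound %.2f (max %.3f); using sigma_eps = 0",
              rho_target, frac_bound, rho0))
          }
          sigma_eps <- 0
        } else {
          lo <- 0; hi <- 8
          for (it in 1:50) {
            mid <- (lo + hi) / 2
            if (rho_at(mid) > rho_target) lo <- mid else hi <- mid
          }
          sigma_eps <- (lo + hi) / 2
        }
      }
    }
    upf1 <- upf1_at(sigma_eps)
    polii <- tau
    d <- log2(upf1 / polii)
    group <- dplyr::case_when(
      d >= ratio_thresholds[2] ~ "high_ratio",
      d <= ratio_thresholds[1] ~ "low_ratio",
      TRUE ~ "similar"
    )
    out <- tibble::tibble(
      gene_id = annotation$genes$gene_id,
      tau = tau,
      polii_occupancy = polii,
      upf1_occupancy = upf1,
      bound = bound,
      group_label = group,
      fpkm_true = fpkm_scale * tau,
      upf1_signal = upf1 * exp(meas1),
      polii_signal = polii * exp(meas2)
    )
    attr(out, "sigma_eps") <- sigma_eps
    attr(out, "realized_rho") <- rho_at(sigma_eps)
    attr(out, "background") <- background
    attr(out, "ratio_thresholds") <- ratio_thresholds
    out
  })
}

# shared helpers ---------------------------------------------------------

## Per-chromosome occupancy vector: the gene's occupancy over its span, 0
## elsewhere, optionally smoothed with a centered moving average of width
## smooth_bp (truncated at chromosome edges), which spreads enrichment across
## gene boundaries the way ~500 bp chromatin fragments do.
occupancy_vector <- function(annotation, occ_by_gene, smooth_bp = 0) {
  g <- annotation$genes
  occ <- occ_by_gene[match(g$gene_id, names(occ_by_gene))]
  out <- lapply(names(annotation$chrom_lengths), function(chrom) {
    v <- numeric(annotation$chrom_lengths[[chrom]])
    rows <- which(g$chrom == chrom)
    for (i in rows) v[(g$start[i] + 1L):g$end[i]] <- occ[i]
    if (smooth_bp > 1) v <- moving_average(v, smooth_bp)
    v
  })
  setNames(out, names(annotation$chrom_lengths))
}

## Centered moving average with edge truncation (window shrinks at the ends).
moving_average <- function(v, width) {
  n <- length(v)
  h <- floor(width / 2)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# probe arrays -----------------------------------------------------------

#' Simulate a PM/MM tiling array and its paired control
#'
#' Probes are laid every `spacing` bp across the whole genome (genes and
#' intergenic gaps). Local occupancy is the gene occupancy smoothed by a
#' `smooth_bp` moving average across gene boundaries, emulating the spread of
#' chromatin fragments beyond the probe footprint. Intensities follow a
#' multiplicative model: `PM = background * exp(eta) * (1 + gain * occ)`,
#' `MM = background * kappa * exp(eta')`, with `kappa < 1` the
#' cross-hybridization factor and log-normal noise of sd `noise_sd`. The
#' control array uses local occupancy 0 everywhere.
#'
#' @param seed Integer seed.
#' @param annotation A [genome_annotation()].
#' @param truth Ground-truth tibble from [simulate_occupancy()].
#' @param occupancy Which occupancy column drives the IP array: `"upf1"` or
#'   `"polii"`.
#' @param spacing Probe spacing in bp (>= 1).
#' @param probe_len Probe footprint length in bp.
#' @param background Background intensity `B`.
#' @param kappa Mismatch cross-hybridization factor (< 1).
#' @param gain Occupancy-to-intensity gain `g`.
#' @param noise_sd Log-normal noise sd on PM and MM.
#' @param smooth_bp Fragment-smoothing window (bp).
#' @return List with elements `ip` and `control`, each a probe tibble with
#'   columns `probe_id`, `chrom`, `position`, `strand`, `pm`, `mm`,
#'   `gene_id`.
#' @export
simulate_probe_array <- function(seed, annotation, truth,
                                 occupancy = c("upf1", "polii"),
                                 spacing = 20, probe_len = 25,
                                 background = 100, kappa = 0.5, gain = 5,
                                 noise_sd = 0.3, smooth_bp = 500) {
  occupancy <- match.arg(occupancy)
  if (spacing < 1) abort("spacing must be >= 1")
  if (kappa <= 0 || kappa >= 1) abort("kappa must be in (0, 1)")
  occ_col <- paste0(occupancy, "_occupancy")
  occ_by_gene <- setNames(truth[[occ_col]], truth$gene_id)
  ov <- occupancy_vector(annotation, occ_by_gene, smooth_bp = smooth_bp)

  g <- annotation$genes
  grid <- purrr::map_dfr(names(annotation$chrom_lengths), function(chrom) {
    len <- annotation$chrom_lengths[[chrom]]
    if (len <= probe_len) return(tibble::tibble())
    pos <- seq.int(0L, len - probe_len, by = spacing)
    rows <- g[g$chrom == chrom, ]
    if (nrow(rows) == 0) {
      gene_id <- rep("unassigned", length(pos))
    } else {
      hit <- findInterval(pos, rows$start)
      gene_id <- ifelse(hit > 0 & pos < rows$end[pmax(hit, 1L)],
                        rows$gene_id[pmax(hit, 1L)], "unassigned")
    }
    occ_local <- ov[[chrom]][pos + 1L]
    tibble::tibble(chrom = chrom, position = pos, gene_id = gene_id,
                   occ_local = occ_local)
  })
  n <- nrow(grid)
  with_seed(seed, {
    eta_ip <- rnorm(n, 0, noise_sd); etap_ip <- rnorm(n, 0, noise_sd)
    eta_ct <- rnorm(n, 0, noise_sd); etap_ct <- rnorm(n, 0, noise_sd)
    base <- tibble::tibble(
      probe_id = sprintf("p%06d", seq_len(n)),
      chrom = grid$chrom, position = grid$position, strand = "+",
      gene_id = grid$gene_id
    )
    ip <- dplyr::mutate(base,
      pm = background * exp(eta_ip) * (1 + gain * grid$occ_local),
      mm = background * kappa * exp(etap_ip),
      .before = "gene_id")
    control <- dplyr::mutate(base,
      pm = background * exp(eta_ct),
      mm = background * kappa * exp(etap_ct),
      .before = "gene_id")
    list(ip = ip, control = control)
  })
}

# ChIP-seq reads ---------------------------------------------------------

#' Simulate single-end ChIP-seq reads for IP and input
#'
#' Fragment midpoints are drawn proportional to `occupancy(position) +
#' floor_weight` for the IP library and uniformly for the input library.
#' Fragment lengths are Normal(`fragment_mean`, `fragment_sd`) truncated at
#' `read_len`; each fragment emits one `read_len` interval from its 5' end on
#' a random strand. Fragments falling off a chromosome are resampled up to
#' `retry_cap` times.
#'
#' @param seed Integer seed.
#' @param annotation A [genome_annotation()].
#' @param truth Ground-truth tibble from [simulate_occupancy()].
#' @param occupancy Occupancy column driving the IP: `"polii"` or `"upf1"`.
#' @param n_reads Reads per library (>= 1).
#' @param fragment_mean,fragment_sd Fragment length distribution (bp).
#' @param read_len Read length (bp).
#' @param floor_weight Uniform floor added to the IP sampling weight.
#' @param retry_cap Resampling attempts before erroring.
#' @return List with elements `ip` and `input`, each a BED-style read tibble.
#' @export
simulate_chipseq <- function(seed, annotation, truth,
                             occupancy = c("polii", "upf1"),
                             n_reads = 50000, fragment_mean = 500,
                             fragment_sd = 100, read_len = 50,
                             floor_weight = 0.1, retry_cap = 100) {
  occupancy <- match.arg(occupancy)
  if (n_reads < 1) abort("n_reads must be >= 1")
  if (any(annotation$chrom_lengths < fragment_mean)) {
    abort("chromosome shorter than the mean fragment size")
  }
  occ_col <- paste0(occupancy, "_occupancy")
  occ_by_gene <- setNames(truth[[occ_col]], truth$gene_id)
  ov <- occupancy_vector(annotation, occ_by_gene, smooth_bp = 0)
  chroms <- names(annotation$chrom_lengths)
  offsets <- c(0, cumsum(as.numeric(annotation$chrom_lengths)))
  genome_size <- offsets[length(offsets)]

  draw_library <- function(weights) {
    cdf <- cumsum(weights) / sum(weights)
    draw_mid <- function(k) findInterval(runif(k), cdf) + 1  # linear index
    sample_reads <- function(k) {
      lin <- draw_mid(k)
      ci <- findInterval(lin - 0.5, offsets)
      mid <- lin - offsets[ci] - 1  # 0-based within chromosome
      len <- pmax(round(rnorm(k, fragment_mean, fragment_sd)), read_len)
      fstart <- mid - floor(len / 2)
      fend <- fstart + len
      strand <- sample(c("+", "-"), k, replace = TRUE)
      tibble::tibble(ci = ci, fstart = fstart, fend = fend, strand = strand)
    }
    fr <- sample_reads(n_reads)
    clen <- as.numeric(annotation$chrom_lengths)
    bad <- fr$fstart < 0 | fr$fend > clen[fr$ci]
    tries <- 0
    while (any(bad)) {
      tries <- tries + 1
      if (tries > retry_cap) {
        abort("could not place fragments within chromosome bounds (retry cap)")
      }
      repl <- sample_reads(sum(bad))
      fr[bad, ] <- repl
      bad <- fr$fstart < 0 | fr$fend > clen[fr$ci]
    }
    start <- ifelse(fr$strand == "+", fr$fstart, fr$fend - read_len)
    tibble::tibble(
      chrom = chroms[fr$ci],
      start = as.integer(start),
      end = as.integer(start + read_len),
      name = sprintf("r%07d", seq_len(n_reads)),
      score = 0,
      strand = fr$strand
    )
  }

  with_seed(seed, {
    w_ip <- unlist(ov, use.names = FALSE) + floor_weight
    ip <- draw_library(w_ip)
    input <- draw_library(rep(1, genome_size))
    list(ip = ip, input = input)
  })
}

# expression and DE labels -----------------------------------------------

#' Simulate replicate FPKM values
#'
#' Each replicate FPKM is the gene's true FPKM (proportional to the latent
#' transcription rate) times log-normal noise of sd `dispersion`.
#'
#' @param seed Integer seed.
#' @param truth Ground-truth tibble from [simulate_occupancy()].
#' @param n_replicates Number of replicates (>= 1).
#' @param dispersion Log-sd of the replicate noise.
#' @return Long tibble with columns `gene_id`, `replicate`, `fpkm`.
#' @export
simulate_expression <- function(seed, truth, n_replicates = 2,
                                dispersion = 0.2) {
  if (n_replicates < 1) abort("n_replicates must be >= 1")
  n <- nrow(truth)
  with_seed(seed, {
    tidyr::crossing(gene_id = truth$gene_id,
                    replicate = seq_len(n_replicates)) |>
      dplyr::arrange(match(.data$gene_id, truth$gene_id), .data$replicate) |>
      dplyr::mutate(
        fpkm = rep(truth$fpkm_true, each = n_replicates) *
          exp(rnorm(n * n_replicates, 0, dispersion))
      )
  })
}

#' Simulate differential-expression labels with a planted overlap
#'
#' Labels exactly `n_de` genes as differentially expressed, exactly
#' `planted_overlap` of which are drawn from the bound subset of `truth`;
#' each labelled gene is `up` with probability `frac_up`, otherwise `down`.
#'
#' @param seed Integer seed.
#' @param truth Ground-truth tibble from [simulate_occupancy()].
#' @param n_de Number of DE genes.
#' @param frac_up Probability a DE gene is up-regulated.
#' @param planted_overlap Number of DE genes drawn from bound genes; must be
#'   feasible given the bound/unbound counts.
#' @return Tibble with columns `gene_id`, `direction` (`"up"`/`"down"`);
#'   attributes `n_de`, `planted_overlap`.
#' @export
simulate_de_labels <- function(seed, truth, n_de, frac_up = 0.7,
                               planted_overlap) {
  bound_ids <- truth$gene_id[truth$bound]
  unbound_ids <- truth$gene_id[!truth$bound]
  if (planted_overlap > min(n_de, length(bound_ids))) {
    abort("planted_overlap exceeds min(n_de, number of bound genes)")
  }
  if (n_de - planted_overlap > length(unbound_ids)) {
    abort("n_de - planted_overlap exceeds the number of unbound genes")
  }
  with_seed(seed, {
    de <- c(sample(bound_ids, planted_overlap),
            sample(unbound_ids, n_de - planted_overlap))
    direction <- ifelse(runif(n_de) < frac_up, "up", "down")
    out <- tibble::tibble(gene_id = de, direction = direction)
    attr(out, "n_de") <- as.integer(n_de)
    attr(out, "planted_overlap") <- as.integer(planted_overlap)
    out
  })
}
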