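test_that("annotations are deterministic, non-overlapping and gapped", {
  a1 <- simulate_annotation(1, n_genes = 50)
  a2 <- simulate_annotation(1, n_genes = 50)
  expect_identical(a1$genes, a2$genes)
  expect_identical(a1$chrom_lengths, a2$chrom_lengths)

  for (chrom in unique(a1$genes$chrom)) {
    g <- a1$genes[a1$genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) {
      gaps <- g$start[-1] - g$end[-nrow(g)]
      expect_true(all(gaps >= 200))
    }
    expect_true(all(g$end <= a1$chrom_lengths[[chrom]]))
  }
  expect_true(all(g_len <- a1$genes$end - a1$genes$start >= 300))
  expect_error(simulate_annotation(1, n_genes = 0), "n_genes")
  expect_error(simulate_annotation(1, n_genes = 50, chrom_length = 1000),
               "cannot fit")
})

test_that("occupancy generator plants the documented rank structure", {
  ann <- simulate_annotation(2, n_genes = 400)

  # monotone transform: fully bound, noiseless => perfect rank agreement
  t1 <- simulate_occupancy(3, ann, frac_bound = 1, sigma_eps = 0)
  expect_equal(cor(t1$upf1_occupancy, t1$polii_occupancy,
                   method = "spearman"), 1)

  # nothing bound => everything sits at background, labelled low_ratio
  t0 <- simulate_occupancy(3, ann, frac_bound = 0, sigma_eps = 0)
  expect_true(all(t0$group_label == "low_ratio"))
  expect_true(all(t0$upf1_occupancy < attr(t0, "background")))

  # unbound genes always stay below the recorded background level
  th <- simulate_occupancy(4, ann, frac_bound = 0.5, rho_target = 0.5)
  expect_true(all(th$upf1_occupancy[!th$bound] < attr(th, "background")))

  # group labels reproduce the log2-ratio thresholds used at generation
  d <- log2(th$upf1_occupancy / th$polii_occupancy)
  thr <- attr(th, "ratio_thresholds")
  expect_equal(th$group_label,
               ifelse(d >= thr[2], "high_ratio",
                      ifelse(d <= thr[1], "low_ratio", "similar")))

  expect_error(simulate_occupancy(1, ann, rho_target = 1.5), "rho_target")
})

test_that("the sigma solver lands near the requested Spearman target", {
  ann <- simulate_annotation(5, n_genes = 2000)
  tr <- simulate_occupancy(6, ann, rho_target = 0.56)
  expect_lt(abs(attr(tr, "realized_rho") - 0.56), 0.02)
  expect_gt(attr(tr, "sigma_eps"), 0)
  # determinism
  tr2 <- simulate_occupancy(6, ann, rho_target = 0.56)
  expect_identical(tr, tr2)
})

test_that("probe arrays follow the multiplicative intensity model", {
  ann <- simulate_annotation(7, n_genes = 30)
  tr <- simulate_occupancy(8, ann, frac_bound = 0.5, sigma_eps = 0.3)

  # noiseless, occupancy zeroed: PM/MM is exactly 1/kappa everywhere
  tr0 <- tr
  tr0$upf1_occupancy[] <- 0
  arr0 <- simulate_probe_array(9, ann, tr0, noise_sd = 0, kappa = 0.4)
  expect_equal(arr0$ip$pm / arr0$ip$mm, rep(1 / 0.4, nrow(arr0$ip)))
  expect_equal(arr0$control$pm / arr0$control$mm,
               rep(1 / 0.4, nrow(arr0$control)))

  # bound genes hybridize hotter than unbound ones at equal background
  arr <- simulate_probe_array(9, ann, tr)
  by_gene <- arr$ip |>
    dplyr::filter(gene_id != "unassigned") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(pm = mean(pm))
  bound <- tr$bound[match(by_gene$gene_id, tr$gene_id)]
  expect_gt(mean(by_gene$pm[bound]), mean(by_gene$pm[!bound]))

  # byte-identical TSV on re-run with the same seed
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_probe_table(simulate_probe_array(9, ann, tr)$ip, f1)
  write_probe_table(simulate_probe_array(9, ann, tr)$ip, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated reads enrich occupied genes and obey bounds", {
  ann <- simulate_annotation(10, n_genes = 30)
  tr <- simulate_occupancy(11, ann, frac_bound = 0.5, sigma_eps = 0)
  # make one gene dominate
  hot <- which.max(tr$upf1_occupancy * tr$bound)
  tr$polii_occupancy[] <- 0.01
  tr$polii_occupancy[hot] <- 50
  reads <- simulate_chipseq(12, ann, tr, n_reads = 5000)
  expect_identical(reads, simulate_chipseq(12, ann, tr, n_reads = 5000))
  expect_true(all(reads$ip$end - reads$ip$start == 50))
  expect_true(all(reads$ip$start >= 0))
  expect_true(all(reads$ip$end <=
                    ann$chrom_lengths[reads$ip$chrom]))

  cov <- coverage_from_reads(reads$ip, ann$chrom_lengths)
  g <- ann$genes[hot, ]
  gene_mean <- mean(cov$values[[g$chrom]][(g$start + 1):g$end])
  genome_mean <- sum(unlist(lapply(cov$values, sum))) /
    sum(as.numeric(ann$chrom_lengths))
  expect_gt(gene_mean, genome_mean)
})

test_that("input-library noise shrinks with sequencing depth", {
  ann <- simulate_annotation(13, n_genes = 50)
  tr <- simulate_occupancy(14, ann, frac_bound = 0.5, sigma_eps = 0)
  per_gene_cv <- function(n_reads) {
    reads <- simulate_chipseq(15, ann, tr, n_reads = n_reads)
    cov <- coverage_from_reads(reads$input, ann$chrom_lengths)
    m <- vapply(seq_len(nrow(ann$genes)), function(i) {
      g <- ann$genes[i, ]
      mean(cov$values[[g$chrom]][(g$start + 1):g$end])
    }, numeric(1))
    sd(m) / mean(m)
  }
  expect_gt(per_gene_cv(1e4), per_gene_cv(1e5))
})

test_that("expression replicates wrap the true FPKM", {
  ann <- simulate_annotation(16, n_genes = 100)
  tr <- simulate_occupancy(17, ann)
  noiseless <- simulate_expression(18, tr, n_replicates = 3, dispersion = 0)
  wide <- tidyr::pivot_wider(noiseless, names_from = replicate,
                             values_from = fpkm)
  expect_equal(wide$`1`, tr$fpkm_true[match(wide$gene_id, tr$gene_id)])
  expect_equal(wide$`1`, wide$`2`)

  noisy <- simulate_expression(18, tr, n_replicates = 2, dispersion = 0.2)
  expect_identical(noisy, simulate_expression(18, tr, 2, dispersion = 0.2))
  m <- mean_log_fpkm(noiseless)
  expect_equal(cor(m$mean_fpkm[match(tr$gene_id, m$gene_id)], tr$tau,
                   method = "spearman"), 1)
})

test_that("DE labels plant the requested overlap with bound genes", {
  ann <- simulate_annotation(19, n_genes = 200)
  tr <- simulate_occupancy(20, ann, frac_bound = 0.4, sigma_eps = 0.3)

  de0 <- simulate_de_labels(21, tr, n_de = 30, planted_overlap = 0)
  expect_length(intersect(de0$gene_id, tr$gene_id[tr$bound]), 0)

  de <- simulate_de_labels(21, tr, n_de = 30, planted_overlap = 12)
  expect_equal(nrow(de), 30)
  expect_length(intersect(de$gene_id, tr$gene_id[tr$bound]), 12)

  up <- simulate_de_labels(22, tr, n_de = 10, frac_up = 1,
                           planted_overlap = 5)
  expect_true(all(up$direction == "up"))

  expect_error(simulate_de_labels(23, tr, n_de = 5, planted_overlap = 10),
               "planted_overlap")
})

test_that("child seeds are fixed offsets of the root seed", {
  s <- sim_seeds(42)
  expect_named(s, c("annotation", "occupancy", "probe_array",
                    "probe_control", "chipseq", "expression", "de_labels",
                    "permutation"))
  expect_true(all(s > 0 & s < 2^31))
  expect_identical(sim_seeds(42), s)
  expect_false(any(sim_seeds(43) == s))
})
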