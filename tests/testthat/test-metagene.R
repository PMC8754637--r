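test_that("probe percent positions anchor at TSS and the 24-bp TES rule", {
  genes <- tibble::tibble(gene_id = c("gp", "gm"), chrom = "chr1",
                          start = c(1000L, 1000L), end = c(2025L, 2025L),
                          strand = c("+", "-"))
  probes <- tibble::tibble(gene_id = c("gp", "gp", "gm"),
                           position = c(1000L, 2000L, 2000L))
  out <- probe_percent_position(probes, genes)
  # + strand: probe at the TSS is 0%; at L - 25 it is exactly 100%
  expect_equal(out$percent[1], 0)
  expect_equal(out$percent[2], 100)
  # - strand: footprint [2000, 2025) has its 5'-most transcribed base at
  # 2024, the TSS of the minus-strand gene
  expect_equal(out$percent[3], 0)
  expect_true(all(out$in_range))

  off <- probe_percent_position(
    tibble::tibble(gene_id = "gp", position = 990L), genes)
  expect_false(off$in_range)

  short <- tibble::tibble(gene_id = "s", chrom = "chr1", start = 0L,
                          end = 20L, strand = "+")
  expect_error(probe_percent_position(
    tibble::tibble(gene_id = "s", position = 0L), short), "probe_len")
})

test_that("probe metagene bins pool values per 0.1% block", {
  ann <- tiny_annotation(starts = 1000L, ends = 3025L, strands = "+",
                         chrom_len = 5000)
  # flat input gives a flat profile in every populated bin
  pv <- tibble::tibble(gene_id = "g01",
                       position = seq(1000L, 3000L, by = 20L), value = 1)
  prof <- build_probe_metagene(pv, ann)
  expect_equal(nrow(prof), 1000)
  expect_true(all(abs(prof$mean[prof$count > 0] - 1) < 1e-9))
  expect_equal(sum(prof$count), nrow(pv))

  # one probe at 50% lands in bin 500 with its own value
  single <- tibble::tibble(gene_id = "g01", position = 2000L, value = 2)
  p1 <- build_probe_metagene(single, ann)
  expect_equal(p1$mean[p1$bin == 500], 2)
  expect_equal(p1$count[p1$bin == 500], 1)
  expect_equal(sum(p1$count), 1)

  expect_error(build_probe_metagene(
    tibble::tibble(gene_id = "unassigned", position = 1L, value = 1), ann),
    "no probes")
})

test_that("probe metagene is invariant under strand reflection", {
  ann <- simulate_annotation(50, n_genes = 15)
  tr <- simulate_occupancy(51, ann, frac_bound = 0.5, sigma_eps = 0.3)
  arr <- simulate_probe_array(52, ann, tr)
  pv <- probe_normalized_values(arr$ip, arr$control)

  # mirror the genome: flip gene strands and reflect probe positions
  clen <- ann$chrom_lengths
  mirror_genes <- ann$genes
  mirror_genes$strand <- ifelse(ann$genes$strand == "+", "-", "+")
  mirror_genes$start <- unname(clen[ann$genes$chrom] - ann$genes$end)
  mirror_genes$end <- unname(clen[ann$genes$chrom] - ann$genes$start)
  mirror_ann <- genome_annotation(mirror_genes, clen)
  mirror_pv <- pv
  mirror_pv$position <- clen[pv$chrom] - pv$position - 25L

  p1 <- build_probe_metagene(pv, ann)
  p2 <- build_probe_metagene(mirror_pv, mirror_ann)
  expect_equal(p2$mean, p1$mean)
  expect_equal(p2$count, p1$count)
})

test_that("probe metagene matches the naive per-probe loop", {
  ann <- simulate_annotation(53, n_genes = 12)
  tr <- simulate_occupancy(54, ann, frac_bound = 0.5, sigma_eps = 0.3)
  arr <- simulate_probe_array(55, ann, tr)
  pv <- probe_normalized_values(arr$ip, arr$control)
  prof <- build_probe_metagene(pv, ann)
  brute <- brute_probe_metagene(pv, ann)
  expect_equal(prof$mean, brute$mean, tolerance = 1e-12)
  expect_equal(prof$count, brute$count)
})

test_that("flank/body metagene is flat on flat input", {
  ann <- tiny_annotation(starts = c(2000L, 9000L), ends = c(4000L, 12000L),
                         strands = c("+", "-"), chrom_len = 20000)
  tr <- coverage_track(list(chr1 = rep(3, 20000)), normalized = TRUE)
  prof <- build_flank_body_metagene(tr, ann, flank = 500, body_bins = 100)
  expect_equal(nrow(prof), 500 + 100 + 500)
  expect_true(all(abs(prof$mean - 3) < 1e-9))
  expect_true(all(prof$count == 2))
})

test_that("flank/body metagene separates gene body from flanks", {
  ann <- tiny_annotation(starts = 5000L, ends = 7000L, strands = "+",
                         chrom_len = 20000)
  v <- rep(1, 20000)
  v[5001:7000] <- 2  # 1-based storage of [5000, 7000)
  tr <- coverage_track(list(chr1 = v), normalized = TRUE)
  prof <- build_flank_body_metagene(tr, ann, flank = 200, body_bins = 50)
  expect_true(all(prof$mean[prof$segment == "upstream"] == 1))
  expect_true(all(prof$mean[prof$segment == "downstream"] == 1))
  expect_true(all(prof$mean[prof$segment == "body"] == 2))
})

test_that("minus-strand profiles mirror plus-strand ones", {
  clen <- 30000L
  ann_minus <- tiny_annotation(starts = c(4000L, 15000L),
                               ends = c(6000L, 18000L),
                               strands = c("-", "-"), chrom_len = clen)
  # mirrored construction: reverse the coordinate axis and use + strand
  ann_plus <- tiny_annotation(starts = clen - c(6000L, 18000L),
                              ends = clen - c(4000L, 15000L),
                              strands = c("+", "+"), chrom_len = clen)
  withr::with_seed(6, v <- exp(rnorm(clen, 0, 0.4)))
  tr_minus <- coverage_track(list(chr1 = v), normalized = TRUE)
  tr_plus <- coverage_track(list(chr1 = rev(v)), normalized = TRUE)
  pm <- build_flank_body_metagene(tr_minus, ann_minus, flank = 300,
                                  body_bins = 40)
  pp <- build_flank_body_metagene(tr_plus, ann_plus, flank = 300,
                                  body_bins = 40)
  expect_equal(pm$mean, pp$mean, tolerance = 1e-12)
  expect_equal(pm$count, pp$count)
})

test_that("flank clipping and masked bases are excluded, not zero-filled", {
  ann <- tiny_annotation(starts = 100L, ends = 700L, strands = "+",
                         chrom_len = 1000)
  v <- rep(2, 1000)
  v[50:60] <- NA  # masked stretch inside the upstream flank
  tr <- coverage_track(list(chr1 = v), normalized = TRUE)
  prof <- build_flank_body_metagene(tr, ann, flank = 300, body_bins = 30)
  up <- prof[prof$segment == "upstream", ]
  # positions beyond the chromosome start contribute nothing
  expect_true(all(up$count[up$position < -100] == 0))
  expect_true(all(is.na(up$mean[up$count == 0])))
  # masked bases drop out but defined ones still average to 2
  expect_true(all(up$mean[up$count > 0] == 2))
})

test_that("flank/body metagene matches the naive per-base loop", {
  ann <- simulate_annotation(56, n_genes = 8)
  tr_truth <- simulate_occupancy(57, ann, frac_bound = 0.5, sigma_eps = 0.3)
  reads <- simulate_chipseq(58, ann, tr_truth, n_reads = 5000)
  cov <- depth_normalize(coverage_from_reads(reads$ip, ann$chrom_lengths),
                         5000)
  # plant a masked base to exercise NA handling in both implementations
  cov$values[[1]][1000:1050] <- NA
  prof <- build_flank_body_metagene(cov, ann, flank = 400, body_bins = 80)
  brute <- brute_flank_body(cov, ann, flank = 400, body_bins = 80)
  expect_equal(prof$mean[prof$segment == "upstream"], brute$up,
               tolerance = 1e-12)
  expect_equal(prof$mean[prof$segment == "body"], brute$body,
               tolerance = 1e-12)
  expect_equal(prof$mean[prof$segment == "downstream"], brute$down,
               tolerance = 1e-12)
})
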