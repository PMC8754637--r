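test_that("gene signal summary reproduces its closed forms", {
  # identical probe pairs: biweight of a constant is the constant
  expect_equal(summarize_gene_signal(pm = rep(200, 4), mm = rep(100, 4)),
               100)
  # mm >= pm forces the halved-PM ideal mismatch
  expect_equal(summarize_gene_signal(pm = 200, mm = 300), 100)
  expect_error(summarize_gene_signal(numeric(0), numeric(0)), "one probe")
  expect_error(summarize_gene_signal(c(100, -1), c(50, 50)), "positive")
})

test_that("the biweight summary resists a single outlier probe", {
  pm <- c(200, 210, 190, 205, 20000)
  mm <- rep(100, 5)
  sig <- summarize_gene_signal(pm, mm)
  consensus <- summarize_gene_signal(pm[1:4], mm[1:4])
  naive <- 2^mean(log2(pm - mm))  # plain-mean oracle
  expect_lt(abs(sig - consensus), abs(naive - consensus))
})

test_that("raising PM never decreases the signal", {
  withr::with_seed(1, {
    for (i in 1:20) {
      pm <- exp(rnorm(8, 5, 0.5))
      mm <- pm * runif(8, 0.3, 1.4)
      s1 <- summarize_gene_signal(pm, mm)
      s2 <- summarize_gene_signal(pm * runif(8, 1, 2), mm)
      expect_gte(s2, s1)
    }
  })
})

sig_table <- function(ids, values) {
  tibble::tibble(gene_id = ids, signal = values, origin = "ip", assay = "x")
}

test_that("median scaling equalizes medians via the mean target", {
  a <- sig_table(c("g1", "g2", "g3"), c(5, 10, 20))
  b <- sig_table(c("g1", "g2", "g3"), c(10, 20, 40))
  out <- scale_to_common_median(a, b)
  expect_equal(median(out$a$signal), 15)
  expect_equal(median(out$b$signal), 15)
  expect_equal(out$a$signal, c(5, 10, 20) * 1.5)
  expect_equal(out$b$signal, c(10, 20, 40) * 0.75)

  same <- scale_to_common_median(a, a)
  expect_equal(same$a$signal, a$signal)

  withr::with_seed(2, {
    for (i in 1:10) {
      x <- sig_table(letters[1:7], exp(rnorm(7)))
      y <- sig_table(letters[1:7], exp(rnorm(7)))
      sc <- scale_to_common_median(x, y)
      expect_equal(median(sc$a$signal), median(sc$b$signal))
    }
  })
})

test_that("table averaging is the per-gene mean and checks gene sets", {
  a <- sig_table(c("g1", "g2"), c(1, 10))
  b <- sig_table(c("g2", "g1"), c(30, 3))  # different order, same set
  expect_equal(average_tables(list(a, b))$signal, c(2, 20))
  expect_equal(average_tables(list(a))$signal, a$signal)
  expect_equal(average_tables(list(a, a, a))$signal, a$signal)
  c_tab <- sig_table(c("g1", "gX"), c(1, 2))
  expect_error(average_tables(list(a, c_tab)), "gX")
})

test_that("control normalization divides per gene and is scale invariant", {
  ip <- sig_table(c("g1", "g2"), c(4, 9))
  ctl <- sig_table(c("g1", "g2"), c(2, 3))
  out <- normalize_by_control(ip, ctl)
  expect_equal(out$signal, c(2, 3))
  expect_equal(out$origin, c("normalized", "normalized"))

  # joint rescaling of IP and control leaves the ratio unchanged
  ip7 <- dplyr::mutate(ip, signal = signal * 7)
  ctl7 <- dplyr::mutate(ctl, signal = signal * 7)
  expect_equal(normalize_by_control(ip7, ctl7)$signal, out$signal)

  same <- normalize_by_control(ip, ip)
  expect_equal(same$signal, c(1, 1))

  ctl0 <- sig_table(c("g1", "g2"), c(2, 0))
  expect_message(dropped <- normalize_by_control(ip, ctl0), "1 gene")
  expect_equal(dropped$gene_id, "g1")
})

probe_tab <- function(pm, mm) {
  tibble::tibble(probe_id = sprintf("p%d", seq_along(pm)), chrom = "chr1",
                 position = seq_along(pm) * 20L, strand = "+", pm = pm,
                 mm = mm, gene_id = "g1")
}

test_that("per-probe normalization divides by the control mean ratio", {
  ip <- probe_tab(pm = c(200, 300), mm = c(100, 100))
  ctl1 <- probe_tab(pm = c(100, 150), mm = c(100, 150))  # ratios 1
  ctl2 <- probe_tab(pm = c(80, 120), mm = c(80, 120))    # ratios 1
  out <- probe_normalized_values(ip, list(ctl1, ctl2))
  expect_equal(out$value, c(2, 3))

  # IP ratios equal to the control mean give exactly 1
  flat <- probe_normalized_values(ctl1, list(ctl1, ctl2))
  expect_equal(flat$value, c(1, 1))

  # two identical IP arrays average to either one
  two <- probe_normalized_values(list(ip, ip), list(ctl1, ctl2))
  expect_equal(two$value, out$value)

  short <- ctl1[1, ]
  expect_error(probe_normalized_values(ip, short), "same probe set")
})

test_that("enriched calls respect the fraction-of-gene rule", {
  ann <- tiny_annotation(starts = c(1000L, 4000L, 7000L),
                         ends = c(2500L, 5500L, 8500L),
                         strands = c("+", "-", "+"), chrom_len = 10000)
  # g01 enriched end-to-end, g02 over 40% of its length only, g03 background
  pv <- make_probe_values(ann, enriched_genes = "g01", fold = 10, seed = 3)
  pv2 <- make_probe_values(ann, enriched_genes = "g02", fold = 10,
                           frac_of_gene = 0.4, seed = 3)
  pv$value[pv2$gene_id == "g02"] <- pv2$value[pv2$gene_id == "g02"]

  calls <- call_enriched_genes(pv, ann)
  expect_true(calls$enriched[calls$gene_id == "g01"])
  expect_equal(calls$fraction_significant[calls$gene_id == "g01"], 1,
               tolerance = 0.05)
  expect_false(calls$enriched[calls$gene_id == "g02"])
  expect_gt(calls$fraction_significant[calls$gene_id == "g02"], 0)
  expect_false(calls$enriched[calls$gene_id == "g03"])
  expect_gt(calls$enrichment_score[calls$gene_id == "g01"], 5)

  # enriched <=> fraction_significant >= 0.5 on every row
  expect_equal(calls$enriched, calls$fraction_significant >= 0.5)
})

test_that("a null array produces (almost) no enriched genes", {
  ann <- simulate_annotation(30, n_genes = 50)
  pv <- make_probe_values(ann, enriched_genes = character(0), seed = 4)
  calls <- call_enriched_genes(pv, ann, p_cutoff = 1e-3)
  expect_lte(sum(calls$enriched), ceiling(1e-3 * nrow(calls)))
})

test_that("stringent cutoffs call a subset of lenient cutoffs", {
  ann <- simulate_annotation(31, n_genes = 60)
  tr <- simulate_occupancy(32, ann, frac_bound = 0.3, sigma_eps = 0.5)
  arr <- simulate_probe_array(33, ann, tr)
  ctl2 <- simulate_probe_array(34, ann, tr)
  pv <- probe_normalized_values(arr$ip, list(arr$control, ctl2$control))
  lenient <- call_enriched_genes(pv, ann, p_cutoff = 1e-3)
  strict <- call_enriched_genes(pv, ann, p_cutoff = 1e-4)
  called_strict <- strict$gene_id[strict$enriched]
  called_lenient <- lenient$gene_id[lenient$enriched]
  expect_true(all(called_strict %in% called_lenient))
})

test_that("degenerate probe scores fail loudly", {
  pv <- tibble::tibble(probe_id = c("p1", "p2"), chrom = "chr1",
                       position = c(0L, 20L), gene_id = "g1",
                       value = c(1, 1))
  expect_error(call_enriched_genes(pv,
                                   tiny_annotation(0L, 100L, "+", 200)),
               "degenerate")
  expect_error(call_enriched_genes(pv[0, ],
                                   tiny_annotation(0L, 100L, "+", 200)),
               "empty probe set")
})
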