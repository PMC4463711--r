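test_that("background correction subtracts per spot and floors at a constant", {
  s <- qc_filter(make_scan(cy5 = c(1000, 50), cy3 = c(500, 500)))
  s$b_cy5 <- c(100, 100); s$b_cy3 <- c(0, 0)
  out <- background_correct(s)
  expect_equal(out$f_cy5, c(900, 1))   # 50 - 100 clamps to the floor
  expect_equal(out$f_cy3, c(500, 500))
  out2 <- background_correct(s, floor = 0.5)
  expect_equal(out2$f_cy5[2], 0.5)
  expect_error(array_scan(data.frame(probe_id = "P1", gene_symbol = "G",
                                     f_cy5 = -1, b_cy5 = 0, f_cy3 = 1,
                                     b_cy3 = 0, qc_flag = 0), "p"),
               "non-negative")
})

test_that("balanced channels normalize with constant one and exact ratios", {
  ratios <- c(2, 0.5, 0.75, 0.75)        # sums balanced by construction
  s <- make_scan(cy5 = 200 * ratios, cy3 = rep(200, 4), bg5 = 50, bg3 = 30)
  rm <- compute_ratio_matrix(global_normalize(background_correct(qc_filter(s))),
                             panel = sprintf("G%02d", 1:4))
  expect_equal(unname(rm$values[1, ]), ratios)  # identity path, exact
})

test_that("a uniform twofold dye bias is removed by sum normalization", {
  s <- make_scan(cy5 = 2 * c(100, 300, 600), cy3 = c(100, 300, 600))
  n <- global_normalize(background_correct(qc_filter(s)))
  expect_equal(attr(n, "norm_constant"), 0.5)
  expect_lt(abs(sum(n$f_cy5) - sum(n$f_cy3)) / sum(n$f_cy3), 1e-9)
  rm <- compute_ratio_matrix(n, panel = sprintf("G%02d", 1:3))
  expect_equal(unname(rm$values[1, ]), c(1, 1, 1))
})

test_that("median normalization centers the null-gene ratio", {
  # null cohort with a strong dye bias: after normalization the median
  # ratio of (all-null) genes must sit within 5% of 1
  cfg <- sim_config(n_pairs = 6, n_genes = 60, seed = 2,
                    planted_effects = data.frame(gene = integer(0),
                                                 true_fc = numeric(0)),
                    scan = list(dye_bias = 1.7, flag_frac = 0))
  co <- simulate_cohort(cfg)
  rm_sum <- preprocess_scans(simulate_scans(co), co$ratios$genes,
                             method = "sum")
  rm_med <- preprocess_scans(simulate_scans(co), co$ratios$genes,
                             method = "median")
  expect_lt(abs(median(rm_sum$values) - 1), 0.05)
  expect_lt(abs(median(rm_med$values) - 1), 0.05)
})

test_that("qc filtering is pure bookkeeping", {
  flags <- rep(0, 169); flags[c(3, 77, 140)] <- -50
  s <- make_scan(cy5 = rep(100, 169), cy3 = rep(100, 169), flags = flags,
                 symbols = sprintf("G%03d", 1:169))
  out <- suppressWarnings(qc_filter(s))
  expect_equal(nrow(out), 166)
  expect_equal(attr(out, "n_removed"), 3)
  # no bad flags: output identical spot table
  s2 <- make_scan(cy5 = 1:5, cy3 = 1:5)
  expect_equal(as.data.frame(qc_filter(s2))[names(s2)], as.data.frame(s2),
               ignore_attr = TRUE)
})

test_that("a fully flagged gene becomes a missing cell, not a crash", {
  flags1 <- c(-50, 0, 0)                  # gene 1 lost in pair 1 only
  s1 <- make_scan(cy5 = c(100, 200, 300), cy3 = c(100, 100, 100),
                  flags = flags1, pair_id = "p1")
  s2 <- make_scan(cy5 = c(100, 200, 300), cy3 = c(100, 100, 100),
                  pair_id = "p2")
  pre <- function(s) global_normalize(background_correct(
    suppressWarnings(qc_filter(s))), method = "median")
  expect_warning(rm <- compute_ratio_matrix(list(pre(s1), pre(s2)),
                                            panel = sprintf("G%02d", 1:3),
                                            max_missing = 0.6),
                 "missing")
  expect_true(is.na(rm$values["p1", "G01"]))
  expect_false(anyNA(rm$values["p2", ]))
  # stricter missing policy drops the gene entirely, with a warning
  warns <- capture_warnings(
    rm2 <- compute_ratio_matrix(list(pre(s1), pre(s2)),
                                panel = sprintf("G%02d", 1:3),
                                max_missing = 0.2))
  expect_match(warns, "dropping", all = FALSE)
  expect_false("G01" %in% colnames(rm2$values))
})

test_that("duplicate spots are averaged on the corrected scale", {
  # duplicate spots for GA plus three balanced genes so the median spot
  # ratio (and hence the normalization constant) is exactly 1
  s <- make_scan(cy5 = c(300, 500, 100, 50, 80), cy3 = c(200, 200, 100, 50, 80),
                 symbols = c("GA", "GA", "GB", "GC", "GD"))
  rm <- compute_ratio_matrix(global_normalize(background_correct(qc_filter(s)),
                                              method = "median"),
                             panel = c("GA", "GB", "GC", "GD"))
  # channel means for GA: Cy5 (300, 500) -> 400, Cy3 -> 200; ratio 2
  expect_equal(unname(rm$values[1, "GA"]), 2)
})

test_that("ratios are invariant under common rescaling of both channels", {
  s <- make_scan(cy5 = c(120, 340, 80), cy3 = c(100, 210, 95),
                 bg5 = 10, bg3 = 10)
  scale_scan <- function(s, k) {
    s$f_cy5 <- s$f_cy5 * k; s$b_cy5 <- s$b_cy5 * k
    s$f_cy3 <- s$f_cy3 * k; s$b_cy3 <- s$b_cy3 * k
    s
  }
  pre <- function(s) compute_ratio_matrix(
    global_normalize(background_correct(qc_filter(s))),
    panel = sprintf("G%02d", 1:3))
  expect_equal(pre(s)$values, pre(scale_scan(s, 7))$values, tolerance = 1e-12)
})

test_that("pipeline stages refuse to run out of order", {
  s <- make_scan(cy5 = c(100, 200), cy3 = c(100, 100))
  expect_error(background_correct(s), "qc_filter")
  expect_error(global_normalize(qc_filter(s)), "background_correct")
  expect_error(compute_ratio_matrix(background_correct(qc_filter(s)),
                                    panel = c("G01", "G02")),
               "global_normalize")
})

test_that("preprocessing recovers the generator's ratio matrix", {
  cfg <- sim_config(n_pairs = 8, n_genes = 40, seed = 6,
                    planted_effects = data.frame(gene = 1:2,
                                                 true_fc = c(3, 0.4)),
                    scan = list(dye_bias = 1.4, flag_frac = 0))
  co <- simulate_cohort(cfg)
  rm <- preprocess_scans(simulate_scans(co), co$ratios$genes,
                         method = "median")
  rel <- rm$values / co$ratios$values
  # recovery is exact up to one constant per array: within each pair the
  # ratio of recovered to true values must not vary across genes at all
  within_pair_spread <- apply(rel, 1, function(v) diff(range(v)) / mean(v))
  expect_true(all(within_pair_spread < 1e-9))
  # and the per-array constant itself stays within a few percent of 1
  expect_true(all(abs(rowMeans(rel) - 1) < 0.15))
  expect_lt(median(abs(rowMeans(rel) - 1)), 0.06)
})

test_that("GenePix-style scan files round-trip", {
  cfg <- sim_config(n_pairs = 2, n_genes = 12, seed = 4,
                    planted_effects = data.frame(gene = 1, true_fc = 2))
  sc <- simulate_scans(cfg)[[1]]
  path <- tempfile(fileext = ".tsv")
  write_scan(sc, path)
  back <- read_scan(path, pair_id = attr(sc, "pair_id"))
  expect_equal(back$f_cy5, sc$f_cy5)
  expect_equal(back$qc_flag, sc$qc_flag)
  expect_equal(back$gene_symbol, sc$gene_symbol)
  expect_equal(attr(back, "pair_id"), attr(sc, "pair_id"))
})
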