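test_that("config validation names the offending field", {
  expect_error(sim_config(n_pairs = 1), "n_pairs")
  expect_error(sim_config(log_ratio_sd = 0), "log_ratio_sd")
  expect_error(sim_config(degree_split = 1.5), "degree_split")
  expect_error(sim_config(n_genes = 10,
                          planted_effects = data.frame(gene = 11, true_fc = 2)),
               "planted_effects")
  expect_error(sim_config(n_genes = 10,
                          planted_effects = data.frame(gene = 1, true_fc = -2)),
               "planted_effects")
  expect_error(sim_config(scan = list(bogus = 1)), "scan")
})

test_that("null model with tiny noise gives ratios of one", {
  cfg <- sim_config(n_pairs = 5, n_genes = 8,
                    planted_effects = data.frame(gene = integer(0),
                                                 true_fc = numeric(0)),
                    log_ratio_sd = 1e-7, seed = 1)
  co <- simulate_cohort(cfg)
  expect_true(all(abs(co$ratios$values - 1) < 1e-5))
  expect_true(all(co$truth$true_fc == 1))
})

test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- sim_config(n_pairs = 12, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$ratios$values, b$ratios$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(simulate_scans(a)[[3]], simulate_scans(b)[[3]])
  # and serialization is byte-identical too
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "ratios.csv")),
                   readLines(file.path(d2, "ratios.csv")))
})

test_that("a gene planted at the published BIRC3 effect size is recovered", {
  cfg <- sim_config(n_pairs = 100, n_genes = 10, seed = 7,
                    planted_effects = data.frame(gene = 1, true_fc = 4.26),
                    degree_genes = integer(0))
  co <- simulate_cohort(cfg)
  r <- co$ratios$values[, 1]
  sem <- sd(r) / sqrt(length(r))
  expect_lt(abs(mean(r) - 4.26), 2 * sem)
})

test_that("planted fold changes sit within two SEM at near-nominal coverage", {
  reps <- 200
  hits <- 0L; tries <- 0L
  for (i in seq_len(reps)) {
    cfg <- sim_config(n_pairs = 100, n_genes = 5, seed = 1000 + i,
                      planted_effects = data.frame(gene = c(1, 2),
                                                   true_fc = c(4.26, 0.33)),
                      degree_genes = integer(0))
    co <- simulate_cohort(cfg)
    for (g in 1:2) {
      r <- co$ratios$values[, g]
      sem <- sd(r) / 10
      tries <- tries + 1L
      if (abs(mean(r) - cfg$planted_effects$true_fc[g]) <= 2 * sem)
        hits <- hits + 1L
    }
  }
  # two-SEM coverage is nominally ~95%; allow 3 binomial SDs below
  expect_gte(hits / tries, 0.95 - 3 * sqrt(0.95 * 0.05 / tries))
})

test_that("cohort metadata has degrees for cases only and plausible ages", {
  co <- simulate_cohort(sim_config(n_pairs = 30, seed = 3))
  md <- co$metadata
  expect_true(all(!is.na(md$degree[md$role == "case"])))
  expect_true(all(is.na(md$degree[md$role == "control"])))
  expect_true(all(md$age[md$role == "case"] >= 43 &
                    md$age[md$role == "case"] <= 79))
  expect_true(all(md$age[md$role == "control"] >= 40 &
                    md$age[md$role == "control"] <= 77))
  expect_setequal(unique(co$degrees), c("I", "II"))
  expect_equal(sum(co$degrees == "II"), 15)
})

test_that("degree substructure leaves the marginal fold change unchanged", {
  # strong degree separation; the planted gene's mean ratio must stay at FC
  cfg <- sim_config(n_pairs = 400, n_genes = 4, seed = 9,
                    planted_effects = data.frame(gene = 1, true_fc = 3),
                    degree_genes = 1L, degree_effect = 1)
  co <- simulate_cohort(cfg)
  r <- co$ratios$values[, 1]
  expect_lt(abs(mean(r) - 3), 3 * sd(r) / sqrt(length(r)))
  # and the two degree groups really differ by the configured log2 shift
  diff_deg <- mean(log2(r[co$degrees == "II"])) -
    mean(log2(r[co$degrees == "I"]))
  expect_lt(abs(diff_deg - 1), 0.3)
})

test_that("flagged spots are exactly the ones excluded downstream", {
  cfg <- sim_config(n_pairs = 4, n_genes = 50, seed = 5,
                    planted_effects = data.frame(gene = integer(0),
                                                 true_fc = numeric(0)),
                    scan = list(flag_frac = 0.1))
  scans <- simulate_scans(cfg)
  for (s in scans) {
    bad <- s$probe_id[s$qc_flag < 0]
    kept <- suppressWarnings(qc_filter(s))
    expect_setequal(setdiff(s$probe_id, kept$probe_id), bad)
    expect_equal(attr(kept, "n_removed"), length(bad))
  }
})

test_that("synthetic Ct tables encode the planted ddCt truth", {
  # zero truth, vanishing noise -> fold change 1
  ct0 <- simulate_ct_table("A", ddct_truth = 0, ct_sd = 1e-9, seed = 1)
  expect_equal(as.numeric(ddct_fold_change(ct0, "A")), 1, tolerance = 1e-6)
  # ddCt = -2 -> fold change 4
  ct2 <- simulate_ct_table("A", ddct_truth = -2, ct_sd = 1e-9, seed = 1)
  expect_equal(as.numeric(ddct_fold_change(ct2, "A")), 4, tolerance = 1e-6)
  expect_error(simulate_ct_table(character(0), 0), "non-empty")
})

test_that("noisy Ct estimate converges at the analytic rate", {
  # ddCt noise: dCt per sample has var 2*sd^2 (target + housekeeper), groups
  # of 10 give se(ddCt) = sqrt(2 * 2 * sd^2 / 10)
  se <- sqrt(2 * 2 * 0.2^2 / 10)
  fc <- suppressWarnings(
    ddct_fold_change(simulate_ct_table("A", ddct_truth = 1, ct_sd = 0.2,
                                       n_case = 10, n_control = 10, seed = 11),
                     "A"))
  expect_lt(abs(attr(fc, "ddct") - 1), 3 * se)
  expect_lt(abs(as.numeric(fc) - 0.5), 0.5 * (2^(3 * se) - 1) + 1e-9)
})
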