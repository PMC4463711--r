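make_separable_cohort <- function(n_pairs, n_genes, n_informative, seed,
                                  fc = 6, sd = 0.1) {
  fcs <- rep(c(fc, 1 / fc), length.out = n_informative)
  simulate_cohort(sim_config(
    n_pairs = n_pairs, n_genes = n_genes,
    planted_effects = data.frame(gene = seq_len(n_informative), true_fc = fcs),
    log_ratio_sd = sd, degree_genes = integer(0), seed = seed))
}

test_that("the sweep builds exactly folds times n_max models", {
  co <- make_separable_cohort(10, 12, 4, seed = 2)
  cv <- loocv_size_sweep(co$samples, co$metadata$role, n_max = 8,
                         de_first = FALSE)
  expect_equal(cv$models_built, 20 * 8)
  expect_equal(cv$n_folds, 20)
  expect_true(all(cv$accuracy_by_n >= 0 & cv$accuracy_by_n <= 1))
  expect_length(cv$per_fold_selections, 20)
})

test_that("a strongly separable cohort reaches perfect held-out accuracy", {
  co <- make_separable_cohort(15, 30, 25, seed = 3)
  cv <- loocv_size_sweep(co$samples, co$metadata$role, n_max = 20,
                         de_first = FALSE)
  expect_equal(unname(cv$accuracy_by_n[20]), 1)
  expect_gte(unname(cv$accuracy_by_n[5]), 0.95)
})

test_that("permuted labels drive held-out accuracy to chance", {
  co <- make_separable_cohort(30, 20, 6, seed = 101)
  set.seed(101)
  y_perm <- sample(co$metadata$role)
  cv <- loocv_size_sweep(co$samples, y_perm, n_max = 5, de_first = FALSE)
  band <- 3 * sqrt(0.25 / 60)
  expect_lt(abs(mean(cv$accuracy_by_n) - 0.5), band)
  expect_true(all(abs(cv$accuracy_by_n - 0.5) < band + 0.1))
})

test_that("per-fold selection guards against selection leakage", {
  # pure-noise genes: a wrapper that reselects features inside each fold
  # stays at chance, while ranking once on the full data (including the
  # held-out sample) inflates the apparent accuracy
  set.seed(103)
  n <- 40; G <- 400
  X <- matrix(rnorm(n * G), n, G, dimnames = list(NULL, sprintf("N%03d", 1:G)))
  y <- rep(c("case", "control"), each = n / 2)
  proper <- loocv_size_sweep(X, y, n_max = 10, de_first = FALSE)
  # leaky protocol, emulated outside the package surface
  disc_full <- discretize_expression(X)
  rank_full <- select_mrmr(disc_full, y, n = 10)
  leaky_genes <- rank_full$ordered_genes
  correct <- 0
  for (i in seq_len(n)) {
    m <- train_svm(X[-i, leaky_genes, drop = FALSE], y[-i], cost_c = 0.5)
    if (predict(m, X[i, leaky_genes, drop = FALSE]) == y[i])
      correct <- correct + 1
  }
  leaky_acc <- correct / n
  proper_acc <- unname(proper$accuracy_by_n[10])
  expect_lt(abs(proper_acc - 0.5), 3 * sqrt(0.25 / n))  # chance, as it must be
  expect_gt(leaky_acc, proper_acc + 0.1)                # the leak inflates
})

test_that("nested screening rebuilds the feature pool inside each fold", {
  co <- make_separable_cohort(12, 15, 5, seed = 5, fc = 4, sd = 0.3)
  cv <- loocv_size_sweep(co$samples, co$metadata$role, n_max = 4,
                         de_first = TRUE, pairs = co$metadata$pair_id)
  expect_equal(cv$models_built, 24 * 4)
  expect_gte(unname(cv$accuracy_by_n[4]), 0.9)
  expect_error(loocv_size_sweep(co$samples, co$metadata$role, n_max = 4),
               "pairs")
})

test_that("a pool smaller than n_max truncates the curve with a warning", {
  co <- make_separable_cohort(10, 10, 3, seed = 6)
  expect_warning(cv <- loocv_size_sweep(co$samples, co$metadata$role,
                                        n_max = 5, pool = 1:3),
                 "truncated")
  expect_equal(cv$models_built, 20 * 3)
  expect_true(all(is.na(cv$accuracy_by_n[4:5])))
})

test_that("the final signature recovers planted genes and is deterministic", {
  co <- make_separable_cohort(25, 50, 20, seed = 7, fc = 4, sd = 0.3)
  planted <- co$truth$symbol[co$truth$de_truth != "ns"]
  sig <- kbd_signature(co$samples, co$metadata$role, n = 20,
                       de_first = FALSE, cost_c = 0.5)
  expect_gte(length(intersect(sig$genes, planted)), 18)
  sig2 <- kbd_signature(co$samples, co$metadata$role, n = 20,
                        de_first = FALSE, cost_c = 0.5)
  expect_identical(sig$genes, sig2$genes)
  expect_identical(sig$svm$weights, sig2$svm$weights)
  # n equal to the pool size returns the whole pool
  sig_all <- kbd_signature(co$samples, co$metadata$role, n = 50,
                           de_first = FALSE, cost_c = 0.5)
  expect_setequal(sig_all$genes, colnames(co$samples))
})

test_that("test-set evaluation reports the confusion metrics faithfully", {
  co <- make_separable_cohort(20, 20, 8, seed = 8)
  tr <- co$metadata$pair_id %in% sprintf("pair%03d", 1:15)
  sig <- kbd_signature(co$samples[tr, ], co$metadata$role[tr], n = 6,
                       de_first = FALSE, cost_c = 0.5)
  ct <- evaluate_signature(sig, co$samples[!tr, ], co$metadata$role[!tr])
  expect_equal(ct$tp + ct$fn, 5)         # five held-out cases
  expect_equal(ct$tn + ct$fp, 5)
  expect_equal(ct$accuracy, 1)           # far-separated classes
  # selection frequencies are reported per fold when a curve is available
  cv <- loocv_size_sweep(co$samples[tr, ], co$metadata$role[tr], n_max = 6,
                         de_first = FALSE)
  sigf <- kbd_signature(co$samples[tr, ], co$metadata$role[tr], n = 6,
                        de_first = FALSE, cost_c = 0.5, curve = cv)
  expect_true(all(sigf$selection_freq <= 1))
  expect_gte(max(sigf$selection_freq), 0.9)
})
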