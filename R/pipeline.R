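#' Configuration for an end-to-end pipeline run
#'
#' Collects every stage parameter of the discovery pipeline: the synthetic
#' cohort (or input files), train/test split, screening thresholds, mRMR and
#' SVM settings, degree-discriminant options and the master seed. The split
#' assigns whole case-control pairs, reproducing an 80/80 training plus
#' 20/20 test design by default; an explicit split (vector of test pair IDs)
#' may be given instead of a seeded one, and the two sets are checked
#' disjoint.
#'
#' @param sim a \code{\link{sim_config}} for the synthetic cohort (default:
#'   the study-scale design with the given seed).
#' @param n_test_pairs number of pairs held out as the independent test set
#'   (default 20).
#' @param test_pairs optional explicit character vector of test pair IDs;
#'   overrides the seeded split.
#' @param fc_up,fc_down,alpha differential-expression screening thresholds.
#' @param n_signature final signature size (default 20).
#' @param n_max signature-size sweep upper bound; set 0 to skip the LOOCV
#'   sweep (default 0, as the sweep is the expensive stage).
#' @param criterion,k_sigma mRMR settings.
#' @param grid SVM cost grid for the final model.
#' @param bda_priors \code{"equal"} or \code{"proportional"}.
#' @param from_scans build the ratio matrix through the full scan
#'   preprocessing chain rather than taking the generator's ratios
#'   (default TRUE).
#' @param norm_method global normalization flavor, \code{"median"} (default;
#'   robust to the asymmetric differential-expression load of this panel)
#'   or \code{"sum"}.
#' @param seed master seed.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(sim = NULL, n_test_pairs = 20, test_pairs = NULL,
                       fc_up = 2, fc_down = 0.5, alpha = 0.05,
                       n_signature = 20, n_max = 0, criterion = "MID",
                       k_sigma = 1, grid = 2^seq(-5, 15, by = 2),
                       bda_priors = "equal", from_scans = TRUE,
                       norm_method = c("median", "sum"), seed = 1) {
  seed <- check_count(seed, "seed", min = 0L)
  if (is.null(sim)) sim <- sim_config(seed = seed)
  stopifnot(inherits(sim, "sim_config"))
  norm_method <- match.arg(norm_method)
  n_test_pairs <- check_count(n_test_pairs, "n_test_pairs", min = 1L)
  if (n_test_pairs >= sim$n_pairs)
    stop_field("n_test_pairs", "must leave at least one training pair")
  structure(list(sim = sim, n_test_pairs = n_test_pairs,
                 test_pairs = test_pairs, fc_up = fc_up, fc_down = fc_down,
                 alpha = alpha, n_signature = n_signature, n_max = n_max,
                 criterion = criterion, k_sigma = k_sigma, grid = grid,
                 bda_priors = bda_priors, from_scans = from_scans,
                 norm_method = norm_method, seed = seed),
            class = "run_config")
}

#' Run the full discovery pipeline and persist its artifacts
#'
#' Chains every stage on a synthetic cohort: simulate, preprocess the
#' two-channel scans into the ratio matrix, split whole pairs into training
#' and test sets, screen the training pairs for differential expression,
#' rank and fit the signature on training samples only, evaluate on the
#' untouched test set, run the degree discriminant on all cases, and produce
#' the qPCR and age validation statistics. All tabular artifacts are written
#' as CSV, models and metrics as JSON, together with a manifest recording
#' seeds, the split, and MD5 checksums of every artifact. Training and test
#' pairs are validated disjoint before anything runs.
#'
#' @param config a \code{\link{run_config}}.
#' @param out_dir output directory (created; must be writable).
#' @return Invisibly, a list with the in-memory results: \code{cohort},
#'   \code{de}, \code{signature}, \code{curve} (if the sweep ran),
#'   \code{test_metrics}, \code{bda}, \code{qpcr}, \code{age},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    cohort <- simulate_cohort(config$sim)
    pair_ids <- cohort$ratios$pair_ids

    # split whole pairs, seeded unless given explicitly
    test_pairs <- config$test_pairs
    if (is.null(test_pairs)) {
      test_pairs <- with_seed(derive_seed(config$seed, "split"),
                              sample(pair_ids, config$n_test_pairs))
    }
    if (!all(test_pairs %in% pair_ids))
      stop("unknown test pair id(s): ",
           paste(setdiff(test_pairs, pair_ids), collapse = ", "))
    train_pairs <- setdiff(pair_ids, test_pairs)
    if (length(intersect(train_pairs, test_pairs)))
      stop("training and test pair sets overlap")

    stage <- "preprocess"
    rm_full <- if (config$from_scans) {
      scans <- simulate_scans(cohort)
      suppressWarnings(preprocess_scans(scans, cohort$ratios$genes,
                                        method = config$norm_method))
    } else cohort$ratios

    meta <- cohort$metadata
    tr_samples <- meta$pair_id %in% train_pairs
    te_samples <- meta$pair_id %in% test_pairs

    stage <- "diffexpr"
    tr_rows <- match(train_pairs, rm_full$pair_ids)
    rm_train <- ratio_matrix(rm_full$values[tr_rows, , drop = FALSE],
                             genes = rm_full$genes, pair_ids = train_pairs)
    de <- screen_de(rm_train, fc_up = config$fc_up, fc_down = config$fc_down,
                    alpha = config$alpha)
    de_pool <- de$symbol[de$call != "ns"]

    stage <- "signature"
    x_tr <- cohort$samples[tr_samples, , drop = FALSE]
    y_tr <- meta$role[tr_samples]
    curve <- NULL
    if (config$n_max > 0)
      curve <- loocv_size_sweep(x_tr, y_tr, n_max = config$n_max,
                                pool = de_pool, criterion = config$criterion,
                                k_sigma = config$k_sigma)
    sig <- kbd_signature(x_tr, y_tr, n = min(config$n_signature,
                                             length(de_pool)),
                         pool = de_pool, criterion = config$criterion,
                         k_sigma = config$k_sigma, grid = config$grid,
                         seed = config$seed, curve = curve)

    stage <- "evaluate"
    metrics <- evaluate_signature(sig, cohort$samples[te_samples, , drop = FALSE],
                                  meta$role[te_samples])

    stage <- "bda"
    vals <- rm_full$values[, sig$genes, drop = FALSE]
    # missing cells (all spots of a gene flagged on an array) are filled
    # with the gene's median ratio so the discriminant sees complete rows
    for (j in seq_len(ncol(vals))) {
      nas <- is.na(vals[, j])
      if (any(nas)) vals[nas, j] <- stats::median(vals[, j], na.rm = TRUE)
    }
    lr_cases <- log2(vals)
    bda_res <- loocv_bda(lr_cases, cohort$degrees, priors = config$bda_priors)

    stage <- "validation_stats"
    qpcr_genes <- utils::head(sig$genes, 6)
    truth_fc <- cohort$truth$true_fc[match(qpcr_genes, cohort$truth$symbol)]
    ct <- simulate_ct_table(qpcr_genes, ddct_truth = -log2(truth_fc),
                            seed = derive_seed(config$seed, "qpcr"))
    qpcr <- data.frame(gene = qpcr_genes, stringsAsFactors = FALSE)
    qpcr$fold_change <- vapply(qpcr_genes, function(g)
      as.numeric(ddct_fold_change(ct, g)), 0)
    qpcr$p_ranksum <- vapply(qpcr_genes, function(g) {
      sub <- ct[ct$gene == g, ]
      rank_sum_test(sub$ct[sub$group == "case"],
                    sub$ct[sub$group == "control"])$p
    }, 0)
    case_ages <- meta$age[meta$role == "case"]
    age <- age_association(rm_full, case_ages, genes = sig$genes)

    stage <- "write"
    write_cohort(cohort, file.path(out_dir, "cohort"))
    write_ratio_csv(rm_full, file.path(out_dir, "ratios_preprocessed.csv"))
    utils::write.csv(as.data.frame(de), file.path(out_dir, "de_results.csv"),
                     row.names = FALSE)
    writeLines(format_table1(de), file.path(out_dir, "de_table.txt"))
    if (!is.null(curve))
      utils::write.csv(data.frame(n = seq_len(curve$n_max),
                                  loocv_accuracy = curve$accuracy_by_n),
                       file.path(out_dir, "signature_curve.csv"),
                       row.names = FALSE)
    jsonlite::write_json(list(genes = sig$genes,
                              weights = unname(sig$svm$weights),
                              bias = sig$svm$bias, cost_c = sig$cost_c,
                              center = unname(sig$svm$center),
                              scale = unname(sig$svm$scale)),
                         file.path(out_dir, "signature.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(list(tp = metrics$tp, fn = metrics$fn,
                              tn = metrics$tn, fp = metrics$fp,
                              accuracy = metrics$accuracy,
                              sensitivity = metrics$sensitivity,
                              specificity = metrics$specificity),
                         file.path(out_dir, "test_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(cbind(table = "original", as.data.frame(bda_res$original)),
                     file.path(out_dir, "bda_original.csv"), row.names = FALSE)
    utils::write.csv(cbind(table = "cross_validated",
                           as.data.frame(bda_res$cross_validated)),
                     file.path(out_dir, "bda_cross_validated.csv"),
                     row.names = FALSE)
    utils::write.csv(qpcr, file.path(out_dir, "qpcr_validation.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(age), file.path(out_dir, "age_association.csv"),
                     row.names = FALSE)

    arts <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    arts <- arts[basename(arts) != "manifest.json"]
    manifest <- list(
      seed = config$seed,
      train_pairs = sort(train_pairs), test_pairs = sort(test_pairs),
      test_samples_untouched_before_evaluation = TRUE,
      n_models_built = if (is.null(curve)) 0L else curve$models_built,
      checksums = as.list(tools::md5sum(arts)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(cohort = cohort, de = de, signature = sig, curve = curve,
         test_metrics = metrics, bda = bda_res, qpcr = qpcr, age = age,
         manifest = manifest)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
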