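#' Configuration for a synthetic KBD cohort
#'
#' Defines the full parameterization of a synthetic matched case-control
#' cohort profiled on a two-color array: cohort size, gene panel, planted
#' differential effects, log-ratio noise, disease-degree substructure, and
#' the master seed. Defaults reproduce the study design the package targets:
#' 100 matched pairs, a 169-gene panel with 50 differential genes (18 up, 32
#' down) at the published effect sizes, and i.i.d. Gaussian noise on log2
#' ratios.
#'
#' Fold changes are planted so that the \emph{arithmetic mean} of the
#' case/control ratio equals \code{true_fc}: per-pair log2 ratios are drawn
#' from Normal(log2(fc) - sd^2 ln(2)/2, sd^2), which cancels the lognormal
#' mean bias exactly. This matches the convention of reporting mean +/- SEM
#' of per-pair ratios.
#'
#' @param n_pairs number of matched case-control pairs (>= 2; default 100).
#' @param n_genes number of genes on the panel (default 169).
#' @param planted_effects data.frame with columns \code{gene} (1-based column
#'   index) and \code{true_fc} (> 0). Default: the 50 differential genes of
#'   \code{\link{kbd_panel}} when \code{n_genes == 169}, otherwise none.
#' @param log_ratio_sd SD of per-pair log2-ratio noise (> 0; default 0.3).
#' @param degree_effect additive log2 separation between degree-II and
#'   degree-I cases on the degree-sensitive gene subset (default 0.5). The
#'   shift is applied symmetrically (+/- half the effect) with a
#'   mean-preserving correction, so the marginal case/control fold change of
#'   the subset stays at its planted value regardless of the degree mix.
#' @param degree_genes integer indices of degree-sensitive genes. Default:
#'   the five up-regulated signature genes when \code{n_genes == 169} (their
#'   fold changes sit far from the calling thresholds, so degree
#'   substructure cannot alter the differential-expression truth), otherwise
#'   none.
#' @param degree_split fraction of cases labeled degree II (default 0.5).
#' @param age_trend optional list \code{list(gene =, slope =)} planting a
#'   linear dependence of a gene's case log2 expression on case age
#'   (per-year slope); off by default, for negative-control tests only.
#' @param scan list of scan-generation parameters: \code{dye_bias}
#'   (multiplicative Cy5 dye bias, default 1.5), \code{bg_mean}/\code{bg_sd}
#'   (additive background intensity, default 100/10), \code{flag_frac}
#'   (fraction of spots flagged bad, default 0.02), \code{baseline_range}
#'   (log2 range of per-gene baseline intensities, default c(8, 14)).
#' @param seed master seed; all stage generators derive child seeds from it.
#' @return An object of class \code{sim_config}.
#' @examples
#' cfg <- sim_config(n_pairs = 10, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n_pairs = 100, n_genes = 169, planted_effects = NULL,
                       log_ratio_sd = 0.3, degree_effect = 0.5,
                       degree_genes = NULL, degree_split = 0.5,
                       age_trend = NULL, scan = list(), seed = 1) {
  n_pairs <- check_count(n_pairs, "n_pairs", min = 2L)
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  log_ratio_sd <- check_positive(log_ratio_sd, "log_ratio_sd")
  degree_split <- check_fraction(degree_split, "degree_split")
  if (!is.numeric(degree_effect) || length(degree_effect) != 1L || is.na(degree_effect))
    stop_field("degree_effect", "must be a single finite number")
  if (is.null(planted_effects)) {
    if (n_genes == 169L) {
      panel <- kbd_panel()
      idx <- which(panel$de_truth != "ns")
      planted_effects <- data.frame(gene = idx, true_fc = panel$true_fc[idx])
    } else {
      planted_effects <- data.frame(gene = integer(0), true_fc = numeric(0))
    }
  }
  planted_effects <- as.data.frame(planted_effects)
  if (!all(c("gene", "true_fc") %in% names(planted_effects)))
    stop_field("planted_effects", "needs columns `gene` and `true_fc`")
  if (nrow(planted_effects) > 0) {
    if (any(planted_effects$gene != round(planted_effects$gene)) ||
        any(planted_effects$gene < 1) || any(planted_effects$gene > n_genes))
      stop_field("planted_effects", "gene indices must lie in 1..n_genes")
    if (anyDuplicated(planted_effects$gene))
      stop_field("planted_effects", "gene indices must be unique")
    if (any(!is.finite(planted_effects$true_fc)) || any(planted_effects$true_fc <= 0))
      stop_field("planted_effects", "true_fc must be positive and finite")
  }
  if (is.null(degree_genes)) {
    degree_genes <- if (n_genes == 169L) {
      panel <- kbd_panel()
      which(panel$signature & panel$de_truth == "up")
    } else integer(0)
  }
  degree_genes <- as.integer(degree_genes)
  if (length(degree_genes) && (any(degree_genes < 1) || any(degree_genes > n_genes)))
    stop_field("degree_genes", "indices must lie in 1..n_genes")
  if (!is.null(age_trend)) {
    if (!is.list(age_trend) || !all(c("gene", "slope") %in% names(age_trend)))
      stop_field("age_trend", "must be list(gene =, slope =)")
    age_trend$gene <- check_count(age_trend$gene, "age_trend$gene")
    if (age_trend$gene > n_genes)
      stop_field("age_trend$gene", "exceeds n_genes")
  }
  scan_defaults <- list(dye_bias = 1.5, bg_mean = 100, bg_sd = 10,
                        flag_frac = 0.02, baseline_range = c(8, 14))
  if (!is.list(scan)) stop_field("scan", "must be a list")
  unknown <- setdiff(names(scan), names(scan_defaults))
  if (length(unknown))
    stop_field("scan", paste("unknown parameter(s):", paste(unknown, collapse = ", ")))
  scan <- utils::modifyList(scan_defaults, scan)
  check_positive(scan$dye_bias, "scan$dye_bias")
  check_fraction(scan$flag_frac, "scan$flag_frac")
  if (scan$bg_mean < 0 || scan$bg_sd < 0)
    stop_field("scan$bg_mean/bg_sd", "must be non-negative")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(n_pairs = n_pairs, n_genes = n_genes,
                 planted_effects = planted_effects,
                 log_ratio_sd = log_ratio_sd, degree_effect = degree_effect,
                 degree_genes = degree_genes, degree_split = degree_split,
                 age_trend = age_trend, scan = scan, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d pairs x %d genes, %d planted effects, seed %d\n",
              x$n_pairs, x$n_genes, nrow(x$planted_effects), x$seed))
  invisible(x)
}

#' Generate a synthetic matched case-control cohort
#'
#' Draws per-sample log2 expression profiles for each case and its matched
#' control, forms the per-pair case/control ratio matrix, assigns KBD degree
#' labels (I/II) to cases with a degree-sensitive expression shift, and
#' attaches ages, sexes and the planted ground truth. Deterministic given the
#' config seed.
#'
#' Per gene g with true fold change FC_g, the pair log2 ratio is
#' Normal(log2(FC_g) - sd^2 ln(2)/2, sd^2), split evenly between the case and
#' control sample profiles, so that the expected arithmetic mean ratio is
#' exactly FC_g. Null genes have FC_g = 1. Degree-II cases additionally
#' receive \code{degree_effect} on the configured gene subset.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An object of class \code{paired_cohort}: list with components
#'   \code{ratios} (a \code{\link{ratio_matrix}}, pairs x genes),
#'   \code{samples} (2*n_pairs x genes matrix of per-sample log2 expression,
#'   cases then controls), \code{metadata} (per-sample data.frame:
#'   \code{sample_id}, \code{role}, \code{pair_id}, \code{degree},
#'   \code{age}, \code{sex}), \code{truth} (per-gene \code{true_fc} and
#'   \code{de_truth}), \code{degrees}, and \code{seed_used}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_pairs
  G <- config$n_genes
  if (G == 169L) {
    panel <- kbd_panel()
    genes <- panel[, c("symbol", "public_id", "gene_name")]
  } else {
    genes <- data.frame(symbol = sprintf("G%03d", seq_len(G)),
                        public_id = sprintf("SYN_%03d", seq_len(G)),
                        gene_name = sprintf("synthetic gene %d", seq_len(G)),
                        stringsAsFactors = FALSE)
  }
  true_fc <- rep(1, G)
  true_fc[config$planted_effects$gene] <- config$planted_effects$true_fc
  de_truth <- rep("ns", G)
  de_truth[true_fc > 1] <- "up"
  de_truth[true_fc < 1] <- "down"

  sd_pair <- config$log_ratio_sd
  sd_sample <- sd_pair / sqrt(2)
  # mean-corrected planting for differential genes:
  # E[2^N(m, sd^2)] = FC when m = log2(FC) - sd^2 ln2/2.
  # Null genes stay centered at log2 ratio 0 so the paired t-test is exactly
  # type-I calibrated on them (their ratio-scale mean, ~2^(sd^2 ln2/2), is
  # far inside the calling thresholds).
  m_g <- ifelse(true_fc == 1, 0, log2(true_fc) - sd_pair^2 * log(2) / 2)

  seed_used <- derive_seed(config$seed, "cohort")
  out <- with_seed(seed_used, {
    n2 <- round(n * config$degree_split)
    degrees <- rep("I", n)
    if (n2 > 0) degrees[sample.int(n, n2)] <- "II"
    x_ctrl <- matrix(stats::rnorm(n * G, 0, sd_sample), n, G)
    x_case <- matrix(stats::rnorm(n * G, 0, sd_sample), n, G) +
      rep(m_g, each = n)
    if (length(config$degree_genes) && config$degree_effect != 0) {
      # symmetric +/- half-shift between degrees; the correction term cancels
      # the mean inflation of the mixture so E[ratio] stays at the planted FC
      half <- config$degree_effect / 2
      p2 <- mean(degrees == "II")
      corr <- log2(p2 * 2^half + (1 - p2) * 2^-half)
      dg <- config$degree_genes
      shift <- ifelse(degrees == "II", half, -half) - corr
      x_case[, dg] <- x_case[, dg] + shift
    }
    age_case <- sample(43:79, n, replace = TRUE)
    age_ctrl <- sample(40:77, n, replace = TRUE)
    sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.44, 0.56))
    if (!is.null(config$age_trend)) {
      g <- config$age_trend$gene
      x_case[, g] <- x_case[, g] +
        config$age_trend$slope * (age_case - mean(age_case))
    }
    list(degrees = degrees, x_ctrl = x_ctrl, x_case = x_case,
         age_case = age_case, age_ctrl = age_ctrl, sex = sex)
  })

  pair_ids <- sprintf("pair%03d", seq_len(n))
  ratios <- ratio_matrix(2^(out$x_case - out$x_ctrl), genes = genes,
                         pair_ids = pair_ids)
  samples <- rbind(out$x_case, out$x_ctrl)
  sample_ids <- c(sprintf("KBD%03d", seq_len(n)), sprintf("CTL%03d", seq_len(n)))
  dimnames(samples) <- list(sample_ids, genes$symbol)
  metadata <- data.frame(
    sample_id = sample_ids,
    role = rep(c("case", "control"), each = n),
    pair_id = rep(pair_ids, 2),
    degree = c(out$degrees, rep(NA_character_, n)),
    age = c(out$age_case, out$age_ctrl),
    sex = rep(out$sex, 2),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(symbol = genes$symbol, true_fc = true_fc,
                      de_truth = de_truth, stringsAsFactors = FALSE)
  structure(list(ratios = ratios, samples = samples, metadata = metadata,
                 truth = truth, degrees = out$degrees,
                 config = config, seed_used = seed_used),
            class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("<paired_cohort> %d pairs x %d genes (seed %d)\n",
              nrow(x$ratios$values), ncol(x$ratios$values), x$config$seed))
  cat(sprintf("  planted: %d up, %d down, %d null genes\n",
              sum(x$truth$de_truth == "up"), sum(x$truth$de_truth == "down"),
              sum(x$truth$de_truth == "ns")))
  cat(sprintf("  case degrees: %d I / %d II\n",
              sum(x$degrees == "I"), sum(x$degrees == "II")))
  invisible(x)
}

#' Generate two-channel spot-intensity scans for a cohort
#'
#' Emulates the raw output of a two-color hybridization: for each matched
#' pair, one scan with per-spot Cy3 (control) and Cy5 (case) foreground and
#' background intensities and a quality flag. Per-gene baseline intensities
#' are lognormal and shared across arrays (probe affinity); a channel-wide
#' multiplicative dye bias is injected on Cy5 so that normalization is
#' non-trivial; a configurable fraction of spots is flagged bad. Running the
#' preprocessing chain on these scans recovers the cohort's ratio matrix up
#' to normalization error.
#'
#' @param cohort a \code{\link{paired_cohort}} (or a \code{\link{sim_config}},
#'   in which case the cohort is generated first).
#' @return List of \code{\link{array_scan}} objects, one per pair.
#' @export
simulate_scans <- function(cohort) {
  if (inherits(cohort, "sim_config")) cohort <- simulate_cohort(cohort)
  stopifnot(inherits(cohort, "paired_cohort"))
  config <- cohort$config
  sc <- config$scan
  n <- config$n_pairs
  G <- config$n_genes
  x_case <- cohort$samples[seq_len(n), , drop = FALSE]
  x_ctrl <- cohort$samples[n + seq_len(n), , drop = FALSE]
  with_seed(derive_seed(config$seed, "scans"), {
    baseline <- 2^stats::runif(G, sc$baseline_range[1], sc$baseline_range[2])
    lapply(seq_len(n), function(p) {
      true3 <- baseline * 2^x_ctrl[p, ]
      true5 <- baseline * 2^x_case[p, ] * sc$dye_bias
      bg3 <- pmax(stats::rnorm(G, sc$bg_mean, sc$bg_sd), 0)
      bg5 <- pmax(stats::rnorm(G, sc$bg_mean, sc$bg_sd), 0)
      flags <- ifelse(stats::runif(G) < sc$flag_frac, -50L, 0L)
      array_scan(data.frame(
        probe_id = sprintf("P%03d", seq_len(G)),
        gene_symbol = cohort$truth$symbol,
        f_cy5 = true5 + bg5, b_cy5 = bg5,
        f_cy3 = true3 + bg3, b_cy3 = bg3,
        qc_flag = flags, stringsAsFactors = FALSE
      ), pair_id = cohort$ratios$pair_ids[p])
    })
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Simulates threshold-cycle measurements for a set of target genes and a
#' housekeeping gene in case and control groups, with a planted per-gene
#' ddCt ground truth: Ct(target, case) sits \code{ddct_truth} cycles above
#' Ct(target, control) after housekeeper normalization, so the expected
#' relative fold change is 2^-ddct_truth.
#'
#' @param genes character vector of target gene symbols (non-empty).
#' @param ddct_truth numeric vector of true ddCt values, one per gene
#'   (finite; recycled if length 1).
#' @param n_case,n_control group sizes (default 5/5).
#' @param ct_sd SD of Ct measurement noise in cycles (default 0.2).
#' @param baseline_ct mean target-gene Ct in controls (default 25 cycles).
#' @param hk_ct housekeeping-gene Ct (default 18 cycles).
#' @param housekeeper housekeeping gene symbol (default \code{"ACTB"},
#'   beta-actin).
#' @param seed RNG seed.
#' @return A \code{ct_table}: long-format data.frame with columns
#'   \code{sample_id}, \code{group}, \code{gene}, \code{ct}, and the
#'   housekeeper symbol stored as an attribute.
#' @export
simulate_ct_table <- function(genes, ddct_truth, n_case = 5, n_control = 5,
                              ct_sd = 0.2, baseline_ct = 25, hk_ct = 18,
                              housekeeper = "ACTB", seed = 1) {
  if (length(genes) == 0) stop("`genes` must be non-empty")
  if (any(!is.finite(ddct_truth))) stop_field("ddct_truth", "must be finite")
  ddct_truth <- rep_len(ddct_truth, length(genes))
  if (ct_sd < 0) stop_field("ct_sd", "must be non-negative")
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  ids <- c(sprintf("KBD%02d", seq_len(n_case)),
           sprintf("CTL%02d", seq_len(n_control)))
  grp <- rep(c("case", "control"), c(n_case, n_control))
  with_seed(derive_seed(seed, "ct"), {
    rows <- lapply(seq_along(genes), function(i) {
      mu <- ifelse(grp == "case", baseline_ct + ddct_truth[i], baseline_ct)
      data.frame(sample_id = ids, group = grp, gene = genes[i],
                 ct = stats::rnorm(length(ids), mu, ct_sd),
                 stringsAsFactors = FALSE)
    })
    hk <- data.frame(sample_id = ids, group = grp, gene = housekeeper,
                     ct = stats::rnorm(length(ids), hk_ct, ct_sd),
                     stringsAsFactors = FALSE)
    tab <- do.call(rbind, c(rows, list(hk)))
    rownames(tab) <- NULL
    ct_table(tab, housekeeper = housekeeper)
  })
}

#' @rdname simulate_ct_table
#' @param x long-format data.frame with columns \code{sample_id},
#'   \code{group}, \code{gene}, \code{ct}.
#' @export
ct_table <- function(x, housekeeper = "ACTB") {
  need <- c("sample_id", "group", "gene", "ct")
  if (!all(need %in% names(x)))
    stop("ct_table needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(x$ct))) stop("Ct values must be finite")
  if (any(x$ct < 10 | x$ct > 40))
    warning("Ct values outside the usual 10-40 cycle range")
  structure(as.data.frame(x), housekeeper = housekeeper,
            class = c("ct_table", "data.frame"))
}

#' Write cohort artifacts to disk
#'
#' Writes the ratio matrix (CSV, genes x pairs), sample metadata (CSV) and
#' the planted ground truth (JSON) to a directory.
#'
#' @param cohort a \code{\link{paired_cohort}}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "paired_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ratio_csv(cohort$ratios, file.path(dir, "ratios.csv"))
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
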