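# independent brute-force oracles and small fixture builders used across
# the suite; deliberately written with plain loops, not via package internals

# plug-in mutual information by explicit summation over observed cells
mi_brute <- function(x, y) {
  n <- length(x)
  total <- 0
  for (ux in unique(x)) for (uy in unique(y)) {
    pxy <- sum(x == ux & y == uy) / n
    if (pxy > 0) {
      px <- sum(x == ux) / n
      py <- sum(y == uy) / n
      total <- total + pxy * log2(pxy / (px * py))
    }
  }
  total
}

# mRMR step criterion for one candidate given the already-selected set
mrmr_crit_brute <- function(states, labels, selected, cand, criterion) {
  rel <- mi_brute(states[, cand], labels)
  if (length(selected) == 0) return(rel)
  red <- mean(vapply(selected, function(s)
    mi_brute(states[, cand], states[, s]), 0))
  if (criterion == "MID") rel - red else rel / max(red, 1e-12)
}

# primal soft-margin objective of a linear SVM on standardized features
hinge_objective <- function(w, b, Z, y_pm, C) {
  margins <- y_pm * (Z %*% w + b)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - margins))
}

# hand-built array scan: one spot per gene, given true channel intensities
make_scan <- function(cy5, cy3, bg5 = 0, bg3 = 0, flags = 0,
                      symbols = sprintf("G%02d", seq_along(cy5)),
                      pair_id = "p1") {
  array_scan(data.frame(
    probe_id = sprintf("P%02d", seq_along(cy5)),
    gene_symbol = symbols,
    f_cy5 = cy5 + bg5, b_cy5 = rep_len(bg5, length(cy5)),
    f_cy3 = cy3 + bg3, b_cy3 = rep_len(bg3, length(cy3)),
    qc_flag = rep_len(flags, length(cy5)),
    stringsAsFactors = FALSE
  ), pair_id = pair_id)
}

# long-format Ct table from per-group dCt values against a fixed housekeeper
make_ct <- function(dct_case, dct_control, hk_ct = 20, gene = "GENE",
                    housekeeper = "ACTB") {
  ids <- c(sprintf("K%02d", seq_along(dct_case)),
           sprintf("C%02d", seq_along(dct_control)))
  grp <- rep(c("case", "control"), c(length(dct_case), length(dct_control)))
  ct_table(rbind(
    data.frame(sample_id = ids, group = grp, gene = gene,
               ct = hk_ct + c(dct_case, dct_control)),
    data.frame(sample_id = ids, group = grp, gene = housekeeper, ct = hk_ct)
  ), housekeeper = housekeeper)
}
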