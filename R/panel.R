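#' Reference 169-gene KBD target panel with planted effect sizes
#'
#' Builds the default gene panel used by the synthetic-cohort generator: a
#' 169-gene custom panel of which 50 genes are differentially expressed in
#' KBD blood (18 up-, 32 down-regulated). The 20 signature genes carry the
#' published mean fold changes; the remaining 30 differential genes (real but
#' unnamed in the published table) are given synthetic symbols
#' (\code{KBDU}/\code{KBDD}) with fold changes spaced deterministically over
#' the same ranges, and the 119 non-differential genes (\code{NULL###}) have
#' true fold change 1.
#'
#' @return A data.frame with one row per gene and columns \code{symbol},
#'   \code{public_id}, \code{gene_name}, \code{true_fc} (true mean
#'   case/control ratio), \code{de_truth} (\code{"up"}, \code{"down"} or
#'   \code{"ns"}) and \code{signature} (logical; the 20-gene signature panel).
#' @examples
#' panel <- kbd_panel()
#' table(panel$de_truth)
#' @export
kbd_panel <- function() {
  sig <- data.frame(
    gene_name = c(
      "ATP-binding cassette, sub-family C, member 13, pseudogene",
      "ABI family, member 3 (NESH) binding protein",
      "Branched chain amino-acid transaminase 1, cytosolic",
      "Calcium channel, voltage-dependent, gamma subunit 6",
      "Chondroitin sulfate N-acetylgalactosaminyltransferase 1",
      "Cathepsin C",
      "Cytochrome b5 reductase 3",
      "Dystrophin, muscular dystrophy",
      "Enhancer of rudimentary homolog (Drosophila)",
      "F11 receptor",
      "FK506 binding protein 9, 63 kDa",
      "Frizzled family receptor 1",
      "Growth differentiation factor 5",
      "Hemoglobin, alpha 2",
      "Zinc family member 5",
      "Baculoviral IAP repeat containing 3",
      "FGFR1 oncogene partner 2",
      "Sialic acid binding lg-like lectin 8",
      "Single-stranded DNA binding protein 1, mitochondrial",
      "Tetratricopeptide repeat domain 25"
    ),
    symbol = c(
      "ABCC13", "ABI3BP", "BCAT1", "CACNG6", "CSGALNACT1", "CTSC",
      "CYB5R3", "DMD", "ERH", "F11R", "FKBP9", "FZD1", "GDF5", "HBA2",
      "ZIC5", "BIRC3", "FGFR1OP2", "SIGLEC8", "SSBP1", "TTC25"
    ),
    public_id = c(
      "NR_003087", "NM_015429", "NM_001178091", "NM_145814", "NM_001130518",
      "NM_001114173", "NM_000398", "NM_007868", "NM_004450", "NM_016946",
      "NM_007270", "NM_003505", "NM_000557", "NM_000517", "NM_033132",
      "NM_001165", "NM_001171887", "NM_014442", "NM_001256510", "NM_031421"
    ),
    true_fc = c(
      0.42, 0.33, 0.43, 0.39, 0.21, 0.39, 0.48, 0.37, 0.38, 0.46,
      0.49, 0.47, 0.44, 0.49, 0.38, 4.26, 2.39, 2.50, 3.12, 3.19
    ),
    stringsAsFactors = FALSE
  )
  sig$de_truth <- ifelse(sig$true_fc > 1, "up", "down")
  sig$signature <- TRUE

  # unnamed differential genes: deterministic fold changes over the same ranges
  n_up_extra <- 13L
  n_down_extra <- 17L
  up_extra <- data.frame(
    gene_name = paste0("synthetic up-regulated gene ", seq_len(n_up_extra)),
    symbol = sprintf("KBDU%02d", seq_len(n_up_extra)),
    public_id = sprintf("SYN_U%03d", seq_len(n_up_extra)),
    true_fc = round(seq(2.2, 4.0, length.out = n_up_extra), 2),
    de_truth = "up", signature = FALSE, stringsAsFactors = FALSE
  )
  down_extra <- data.frame(
    gene_name = paste0("synthetic down-regulated gene ", seq_len(n_down_extra)),
    symbol = sprintf("KBDD%02d", seq_len(n_down_extra)),
    public_id = sprintf("SYN_D%03d", seq_len(n_down_extra)),
    true_fc = round(seq(0.25, 0.48, length.out = n_down_extra), 2),
    de_truth = "down", signature = FALSE, stringsAsFactors = FALSE
  )
  n_null <- 169L - nrow(sig) - n_up_extra - n_down_extra
  nulls <- data.frame(
    gene_name = paste0("synthetic non-differential gene ", seq_len(n_null)),
    symbol = sprintf("NULL%03d", seq_len(n_null)),
    public_id = sprintf("SYN_N%03d", seq_len(n_null)),
    true_fc = 1, de_truth = "ns", signature = FALSE, stringsAsFactors = FALSE
  )
  panel <- rbind(sig, up_extra, down_extra, nulls)
  rownames(panel) <- NULL
  panel
}
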