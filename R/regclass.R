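# Transcriptional regulation is read from the cytoplasmic fractions alone
# (the total-mRNA arm of the experiment) and cross-tabulated against the
# translational classes to separate genes whose polysome engagement changes
# because of transcript abundance from genes under true translational
# control.

#' Classify transcriptional regulation from cytoplasmic counts
#'
#' Per-gene `log2FC = log2(mean_cyto_T / mean_cyto_NT)` on normalized
#' counts; two-sided permutation p-value over condition labels within the
#' cytoplasmic fraction; BH-FDR; classes by the same fold / alpha
#' thresholds as the translational classification.
#'
#' @param counts CountDataset
#' @param genes gene ids to classify
#' @param cfg [ti_config()]
#' @param size_factors optional precomputed factors
#' @return data.frame with `gene_id`, `log2_fc`, `p_value`, `fdr`,
#'   `txn_class`
#' @export
classify_transcriptional <- function(counts, genes, cfg = ti_config(),
                                     size_factors = NULL) {
  t_idx <- group_columns(counts, "cytoplasmic", "T")
  nt_idx <- group_columns(counts, "cytoplasmic", "NT")
  if (length(t_idx) < 2 || length(nt_idx) < 2)
    stop("need >= 2 cytoplasmic replicates per condition")
  nm <- normalized_counts(counts, size_factors)[genes, , drop = FALSE]
  mt <- rowMeans(nm[, t_idx, drop = FALSE])
  mnt <- rowMeans(nm[, nt_idx, drop = FALSE])
  lfc <- ifelse(mt > 0 & mnt > 0, log2(mt / mnt), NA_real_)
  res <- perm_test_core(nm, list(list(t_idx = t_idx, nt_idx = nt_idx,
                                      sign = +1)),
                        cfg$n_permutations, cfg$seed)
  fdr <- adjust_fdr(res$p)
  data.frame(gene_id = genes, log2_fc = lfc, p_value = res$p, fdr = fdr,
             txn_class = classify_regulation(lfc, fdr, cfg),
             stringsAsFactors = FALSE)
}

#' Cross-tabulate translational against transcriptional classes
#'
#' Builds the 3x3 contingency of te_class (rows: up/down/stable) by
#' txn_class (columns), with row percentages (percent of the te_class row
#' total) reported to 1 decimal.
#'
#' @param te_classes named character vector (names = gene ids) or data.frame
#'   with `gene_id` and `te_class`
#' @param txn_classes same, with `txn_class`
#' @param universe gene ids to tabulate; every member must be classified by
#'   both inputs
#' @return list of class `RegClassTable` with `counts` (3x3 integer) and
#'   `row_percentages` (3x3, NA for empty rows)
#' @export
cross_classify <- function(te_classes, txn_classes, universe) {
  as_named <- function(x, col) {
    if (is.data.frame(x)) stats::setNames(x[[col]], x$gene_id) else x
  }
  te <- as_named(te_classes, "te_class")
  tx <- as_named(txn_classes, "txn_class")
  miss <- universe[!(universe %in% names(te)) | !(universe %in% names(tx))]
  if (length(miss) > 0)
    stop("gene in universe missing a class: ", miss[1])
  lv <- c("up", "down", "stable")
  counts <- table(factor(te[universe], lv), factor(tx[universe], lv))
  counts <- matrix(as.integer(counts), 3, 3, dimnames = dimnames(counts))
  names(dimnames(counts)) <- c("te_class", "txn_class")
  rt <- rowSums(counts)
  pct <- counts * NA_real_
  nz <- rt > 0
  pct[nz, ] <- round(100 * counts[nz, , drop = FALSE] / rt[nz], 1)
  structure(list(counts = counts, row_percentages = pct), class = "RegClassTable")
}

#' @export
print.RegClassTable <- function(x, ...) {
  cat("Cross-classification (rows te_class, cols txn_class)\ncounts:\n")
  print(x$counts)
  cat("row percentages:\n")
  print(x$row_percentages)
  invisible(x)
}

#' Class percentages of a total
#'
#' Each count times 100 over the total, reported to 2 decimals; NA markers
#' when the total is 0.
#'
#' @param counts_by_class numeric vector of counts (names kept)
#' @param total denominator, normally `sum(counts_by_class)`
#' @return numeric vector of percentages
#' @export
class_percentages <- function(counts_by_class, total = sum(counts_by_class)) {
  if (total == 0)
    return(stats::setNames(rep(NA_real_, length(counts_by_class)),
                           names(counts_by_class)))
  round(100 * counts_by_class / total, 2)
}
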