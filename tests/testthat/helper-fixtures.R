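# Builders for small in-code fixtures shared across test files.

# Sample sheet for `reps` replicates in each of the four groups, ordered
# cyto-NT, cyto-T, poly-NT, poly-T.
make_sheet <- function(reps = 3) {
  design <- expand.grid(replicate = seq_len(reps),
                        condition = c("NT", "T"),
                        fraction = c("cytoplasmic", "polysomal"),
                        stringsAsFactors = FALSE)
  design$sample_id <- sprintf("%s_%s_r%d",
                              ifelse(design$fraction == "polysomal", "poly", "cyto"),
                              design$condition, design$replicate)
  design[, c("sample_id", "fraction", "condition", "replicate")]
}

# CountDataset whose four group means are given per gene; each sample in a
# group carries the group mean exactly (integer means only).
make_group_counts <- function(cyto_nt, cyto_t, poly_nt, poly_t, reps = 3) {
  sheet <- make_sheet(reps)
  n <- length(cyto_nt)
  counts <- matrix(0, n, nrow(sheet),
                   dimnames = list(sprintf("g%d", seq_len(n)), sheet$sample_id))
  vals <- list(cytoplasmic = list(NT = cyto_nt, T = cyto_t),
               polysomal = list(NT = poly_nt, T = poly_t))
  for (j in seq_len(nrow(sheet)))
    counts[, j] <- vals[[sheet$fraction[j]]][[sheet$condition[j]]]
  count_dataset(counts, sheet)
}

# Brute-force oracle for the TI interaction permutation test: enumerates all
# label assignments (applied jointly to both fractions), statistic computed
# with plain rowMeans on normalized counts.
oracle_ti_perm <- function(ds, genes) {
  nm <- normalized_counts(ds)[genes, , drop = FALSE]
  gc <- function(fr, cond) {
    idx <- which(ds$samples$fraction == fr & ds$samples$condition == cond)
    idx[order(ds$samples$replicate[idx])]
  }
  ord_p <- c(gc("polysomal", "T"), gc("polysomal", "NT"))
  ord_c <- c(gc("cytoplasmic", "T"), gc("cytoplasmic", "NT"))
  nT <- length(gc("polysomal", "T"))
  n <- length(ord_p)
  A <- utils::combn(n, nT)
  stat <- sapply(seq_len(ncol(A)), function(k) {
    tpos <- A[, k]
    log2(rowMeans(nm[, ord_p[tpos], drop = FALSE])) -
      log2(rowMeans(nm[, ord_p[-tpos], drop = FALSE])) -
      log2(rowMeans(nm[, ord_c[tpos], drop = FALSE])) +
      log2(rowMeans(nm[, ord_c[-tpos], drop = FALSE]))
  })
  stat <- matrix(stat, nrow = length(genes))
  obs <- abs(stat[, 1])
  rowSums(abs(stat) >= obs - 1e-9) / ncol(A)
}

# Independent Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}
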