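# Translational Index (TI) pipeline. For each gene the TI is X1/X2 where
# X1 is the polysomal-to-cytoplasmic ratio of normalized mean counts in
# treated cells and X2 the same ratio in non-treated cells; log2 TI > 0
# means treatment enhanced the gene's translational efficiency.
# Significance comes from a permutation test of this fraction x condition
# interaction; multiplicity is controlled by Benjamini-Hochberg FDR.

#' TI analysis configuration
#'
#' @param fold_cutoff minimum linear TI fold change to call a gene
#'   translationally regulated (applied as |log2 TI| >= log2(fold_cutoff))
#' @param alpha FDR threshold for calling regulation
#' @param expression_min_mean minimum normalized mean count required in all
#'   four (fraction, condition) groups for a gene to count as expressed
#' @param n_permutations Monte-Carlo permutation budget; the test enumerates
#'   exhaustively whenever the number of distinct label assignments is at
#'   most this
#' @param seed RNG seed for Monte-Carlo permutations
#' @return list of class `TIConfig`
#' @export
ti_config <- function(fold_cutoff = 1.5, alpha = 0.05,
                      expression_min_mean = 10, n_permutations = 10000,
                      seed = 1) {
  stopifnot(fold_cutoff > 1, alpha > 0, alpha < 1,
            expression_min_mean >= 0, n_permutations >= 1)
  structure(list(fold_cutoff = fold_cutoff, alpha = alpha,
                 expression_min_mean = expression_min_mean,
                 n_permutations = as.integer(n_permutations), seed = seed),
            class = "TIConfig")
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over genes of
#' count(g, s) / geometric-mean_g(count); genes with a zero count in any
#' sample are excluded from the median. Factors are rescaled so their
#' geometric mean is 1, making normalized counts comparable across samples
#' while leaving the TI (a ratio of ratios) scale-free.
#'
#' @param counts CountDataset or a genes x samples count matrix
#' @return named numeric vector of positive per-sample factors
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "CountDataset")) counts$counts else as.matrix(counts)
  if (ncol(m) == 1) return(stats::setNames(1, colnames(m)))
  keep <- rowSums(m == 0) == 0
  if (!any(keep))
    stop("no gene has nonzero counts in every sample; cannot compute ",
         "median-of-ratios size factors (pseudo-reference fallback is not applied)")
  lm_ <- log(m[keep, , drop = FALSE])
  logratio <- lm_ - rowMeans(lm_)
  sf <- exp(apply(logratio, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(m))
}

#' Normalized counts (counts divided by size factors)
#' @param ds CountDataset
#' @param size_factors optional precomputed factors
#' @return genes x samples matrix
#' @export
normalized_counts <- function(ds, size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(ds)
  sweep(ds$counts, 2, size_factors, "/")
}

#' Filter expressed genes
#'
#' Keeps genes whose normalized mean count is at least
#' `cfg$expression_min_mean` in all four (fraction, condition) groups
#' (boundary inclusive).
#'
#' @param counts CountDataset
#' @param cfg [ti_config()]
#' @param size_factors optional precomputed factors
#' @return character vector of gene ids passing the filter, file order
#' @export
filter_expressed <- function(counts, cfg = ti_config(), size_factors = NULL) {
  nm <- normalized_counts(counts, size_factors)
  ok <- rep(TRUE, nrow(nm))
  for (fr in c("cytoplasmic", "polysomal")) for (cond in c("NT", "T")) {
    idx <- group_columns(counts, fr, cond)
    ok <- ok & rowMeans(nm[, idx, drop = FALSE]) >= cfg$expression_min_mean
  }
  genes <- rownames(nm)[ok]
  if (length(genes) == 0)
    warning("no gene passes the expression filter")
  genes
}

#' Compute the Translational Index
#'
#' `x1 = mean(poly, T) / mean(cyto, T)` and `x2 = mean(poly, NT) /
#' mean(cyto, NT)` on normalized counts; `log2_ti = log2(x1 / x2)`. Genes
#' whose four group means are not all positive get `NA` (flagged, never
#' +/-Inf); the expression filter guarantees positivity for filtered genes.
#'
#' @param counts CountDataset
#' @param genes gene ids to evaluate (default: all)
#' @param size_factors optional precomputed factors
#' @return data.frame with `gene_id`, `x1`, `x2`, `log2_ti`
#' @export
compute_ti <- function(counts, genes = rownames(counts$counts),
                       size_factors = NULL) {
  nm <- normalized_counts(counts, size_factors)[genes, , drop = FALSE]
  gm <- function(fr, cond)
    rowMeans(nm[, group_columns(counts, fr, cond), drop = FALSE])
  m_pt <- gm("polysomal", "T"); m_ct <- gm("cytoplasmic", "T")
  m_pn <- gm("polysomal", "NT"); m_cn <- gm("cytoplasmic", "NT")
  ok <- m_pt > 0 & m_ct > 0 & m_pn > 0 & m_cn > 0
  x1 <- ifelse(ok, m_pt / m_ct, NA_real_)
  x2 <- ifelse(ok, m_pn / m_cn, NA_real_)
  data.frame(gene_id = genes, x1 = x1, x2 = x2,
             log2_ti = ifelse(ok, log2(x1 / x2), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

# --- permutation machinery ---------------------------------------------------

# Permutation test of group-mean log-ratio contrasts. `fractions` is a list
# of lists (t_idx, nt_idx, sign): the statistic is
# sum_f sign_f * (log2 mean(t_idx under permuted labels) -
#                 log2 mean(nt_idx under permuted labels)).
# Condition labels are permuted across the replicate index within each
# fraction; when every fraction has the same (nT, nNT) structure one label
# permutation is applied jointly to all fractions, otherwise labels are
# permuted independently per fraction. Exhaustive enumeration (identity
# included; p = count / n_distinct) when the number of distinct assignments
# is <= n_permutations, Monte-Carlo with p = (1 + count) / (1 + B) otherwise.
perm_test_core <- function(N, fractions, n_permutations, seed = 1) {
  nT <- vapply(fractions, function(f) length(f$t_idx), integer(1))
  nNT <- vapply(fractions, function(f) length(f$nt_idx), integer(1))
  joint <- all(nT == nT[1]) && all(nNT == nNT[1])
  if (joint) {
    n <- nT[1] + nNT[1]
    n_distinct <- choose(n, nT[1])
    exhaustive <- n_distinct <= n_permutations
    A <- if (exhaustive) utils::combn(n, nT[1])
         else with_seed(seed, cbind(seq_len(nT[1]),
                vapply(seq_len(n_permutations),
                       function(i) sample.int(n, nT[1]), integer(nT[1]))))
    asg <- lapply(fractions, function(f) A)
  } else {
    per_n <- nT + nNT
    per_dist <- choose(per_n, nT)
    n_distinct <- prod(per_dist)
    exhaustive <- n_distinct <= n_permutations
    if (exhaustive) {
      combos <- lapply(seq_along(fractions),
                       function(i) utils::combn(per_n[i], nT[i]))
      grid <- as.matrix(expand.grid(lapply(per_dist, seq_len)))
      asg <- lapply(seq_along(fractions),
                    function(i) combos[[i]][, grid[, i], drop = FALSE])
    } else {
      asg <- with_seed(seed, lapply(seq_along(fractions), function(i)
        cbind(seq_len(nT[i]),
              vapply(seq_len(n_permutations),
                     function(k) sample.int(per_n[i], nT[i]),
                     integer(nT[i])))))
    }
  }
  # identity assignment is column 1 in both modes (combn's first combination
  # is 1..nT; Monte-Carlo matrices are built with it prepended), so
  # p = count / K gives count / n_distinct when exhaustive and
  # (1 + #extreme) / (1 + B) when Monte-Carlo.
  K <- ncol(asg[[1]])
  G <- nrow(N)
  count <- numeric(G)
  stat_obs <- NULL
  aobs <- NULL
  chunk <- 2000L
  for (s in seq(1L, K, by = chunk)) {
    cols <- s:min(s + chunk - 1L, K)
    stat <- matrix(0, G, length(cols))
    bad <- matrix(FALSE, G, length(cols))
    for (i in seq_along(fractions)) {
      f <- fractions[[i]]
      ord <- c(f$t_idx, f$nt_idx)
      Ai <- asg[[i]][, cols, drop = FALSE]
      kT <- nrow(Ai); kNT <- length(ord) - kT
      WT <- matrix(0, ncol(N), length(cols))
      WNT <- WT
      WNT[ord, ] <- 1 / kNT
      rows <- matrix(ord[Ai], nrow = kT)
      idx <- cbind(as.vector(rows), rep(seq_along(cols), each = kT))
      WT[idx] <- 1 / kT
      WNT[idx] <- 0
      lT <- log2(N %*% WT)
      lNT <- log2(N %*% WNT)
      bad <- bad | !is.finite(lT) | !is.finite(lNT)
      stat <- stat + f$sign * (lT - lNT)
    }
    astat <- abs(stat)
    astat[bad] <- Inf
    if (s == 1L) {
      stat_obs <- stat[, 1]
      aobs <- astat[, 1]
    }
    count <- count + rowSums(astat >= aobs - 1e-9)
  }
  list(p = pmin(count / K, 1), stat_obs = stat_obs, n_distinct = n_distinct,
       exhaustive = exhaustive, n_used = K)
}

#' Permutation test of translational-efficiency change
#'
#' Two-sided permutation test of the fraction x condition interaction: the
#' statistic is the gene's log2 TI recomputed from permuted condition
#' labels, permuting T/NT labels across the replicate index within each
#' fraction (jointly across fractions when the replicate structure matches).
#' Exhaustive enumeration is used when the number of distinct assignments is
#' at most `cfg$n_permutations`; otherwise Monte-Carlo with
#' `p = (1 + #extreme) / (1 + B)`.
#'
#' @param counts CountDataset
#' @param genes gene ids to test
#' @param cfg [ti_config()]
#' @param size_factors optional precomputed factors
#' @return data.frame with `gene_id`, `p_value`, plus attributes
#'   `n_distinct` and `exhaustive`
#' @export
test_ti <- function(counts, genes, cfg = ti_config(), size_factors = NULL) {
  fr <- list(
    list(t_idx = group_columns(counts, "polysomal", "T"),
         nt_idx = group_columns(counts, "polysomal", "NT"), sign = +1),
    list(t_idx = group_columns(counts, "cytoplasmic", "T"),
         nt_idx = group_columns(counts, "cytoplasmic", "NT"), sign = -1))
  for (f in fr) {
    if (length(f$t_idx) < 2 || length(f$nt_idx) < 2) {
      frname <- counts$samples$fraction[c(f$t_idx, f$nt_idx)[1]]
      stop("need >= 2 replicates per group; too few in fraction '",
           frname, "'")
    }
  }
  nm <- normalized_counts(counts, size_factors)[genes, , drop = FALSE]
  res <- perm_test_core(nm, fr, cfg$n_permutations, cfg$seed)
  out <- data.frame(gene_id = genes, p_value = res$p,
                    stringsAsFactors = FALSE)
  attr(out, "n_distinct") <- res$n_distinct
  attr(out, "exhaustive") <- res$exhaustive
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; order-independent
#' under ties.
#'
#' @param p_values numeric vector in \[0, 1\]
#' @return vector of adjusted values (same length/order)
#' @export
adjust_fdr <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH")
}

#' Classify translational regulation
#'
#' `up` if `log2_ti >= log2(fold_cutoff)` and `fdr < alpha`; `down` if
#' `log2_ti <= -log2(fold_cutoff)` and `fdr < alpha`; `stable` otherwise.
#'
#' @param log2_fc vector of log2 TI (or any log2 fold change)
#' @param fdr vector of adjusted p-values
#' @param cfg [ti_config()]
#' @return character vector in `{"up", "down", "stable"}`
#' @export
classify_regulation <- function(log2_fc, fdr, cfg = ti_config()) {
  lc <- log2(cfg$fold_cutoff)
  out <- rep("stable", length(log2_fc))
  sig <- !is.na(fdr) & fdr < cfg$alpha & !is.na(log2_fc)
  out[sig & log2_fc >= lc] <- "up"
  out[sig & log2_fc <= -lc] <- "down"
  out
}

#' Full translatome analysis
#'
#' Size factors, expression filter, TI, permutation p-values, BH-FDR and
#' translational classification in one call.
#'
#' @param counts CountDataset
#' @param cfg [ti_config()]
#' @return data.frame (one row per expressed gene) with columns `gene_id`,
#'   `x1`, `x2`, `log2_ti`, `p_value`, `fdr`, `te_class`
#' @export
run_translatome <- function(counts, cfg = ti_config()) {
  sf <- estimate_size_factors(counts)
  genes <- filter_expressed(counts, cfg, sf)
  ti <- compute_ti(counts, genes, sf)
  tst <- test_ti(counts, genes, cfg, sf)
  ti$p_value <- tst$p_value
  ti$fdr <- adjust_fdr(ti$p_value)
  ti$te_class <- classify_regulation(ti$log2_ti, ti$fdr, cfg)
  attr(ti, "n_distinct") <- attr(tst, "n_distinct")
  attr(ti, "exhaustive") <- attr(tst, "exhaustive")
  ti
}
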