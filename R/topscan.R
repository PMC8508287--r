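# 5'TOP motif calling. A 5' terminal oligopyrimidine tract is a
# cap-adjacent C followed by a run of pyrimidines (C/T), characteristic of
# ribosomal-protein and translation-factor mRNAs and the substrate of
# mTORC1-sensitive translational control. The call requires the maximal
# pyrimidine run starting at position 1 to have length >= 5 (the initial C
# plus at least 4 more); a downstream G-rich region is reported but never
# gates the call, and long tracts are never disqualified.

#' Scan one or more 5'UTRs for the TOP motif
#'
#' @param utrs data.frame with `gene_id`, `sequence` (position 1 =
#'   transcription start site), or a named character vector of sequences
#' @return data.frame with `gene_id`, `is_top`, `pyrimidine_run`
#'   (consecutive C/T from position 1), `g_rich_downstream` (fraction of G
#'   >= 0.5 in the 10 bases after the run; informational only), `reason`
#' @export
scan_top_motif <- function(utrs) {
  if (!is.data.frame(utrs))
    utrs <- data.frame(gene_id = names(utrs), sequence = unname(utrs),
                       stringsAsFactors = FALSE)
  seqs <- toupper(utrs$sequence)
  stopifnot(all(nchar(seqs) >= 1), !any(grepl("[^ACGTN]", seqs)))
  run <- nchar(sub("[^CT].*$", "", paste0(seqs, "X")))
  first <- substr(seqs, 1, 1)
  after <- substr(seqs, run + 1, run + 10)
  n_after <- nchar(after)
  g_frac <- ifelse(n_after > 0,
                   nchar(gsub("[^G]", "", after)) / n_after, 0)
  is_top <- first == "C" & run >= 5
  reason <- ifelse(first == "N", "ambiguous base at position 1",
            ifelse(first != "C", "first base is not C",
            ifelse(run < 5, sprintf("pyrimidine run %d < 5", run),
                   sprintf("C + pyrimidine run of %d", run))))
  data.frame(gene_id = utrs$gene_id, is_top = is_top,
             pyrimidine_run = as.integer(run),
             g_rich_downstream = g_frac >= 0.5,
             reason = reason, stringsAsFactors = FALSE)
}

#' Venn counts of a gene set against a reference catalogue
#'
#' @param set_a,reference,universe character vectors of gene ids;
#'   `set_a` and `reference` must be subsets of `universe`
#' @return named list `(only_a, only_ref, both, neither)`; the four counts
#'   partition the universe
#' @export
overlap_counts <- function(set_a, reference, universe) {
  set_a <- unique(set_a); reference <- unique(reference)
  universe <- unique(universe)
  out <- setdiff(c(set_a, reference), universe)
  if (length(out) > 0)
    stop("gene outside the universe: ", out[1])
  both <- length(intersect(set_a, reference))
  list(only_a = length(set_a) - both,
       only_ref = length(reference) - both,
       both = both,
       neither = length(universe) - length(union(set_a, reference)))
}

#' Hypergeometric enrichment of a set overlap
#'
#' One-sided over-representation by default: the upper-tail probability
#' `P(X >= both)` of drawing at least the observed overlap when `|set_a|`
#' genes are drawn without replacement from a universe containing
#' `|reference|` successes. `alternative = "under"` gives the lower tail;
#' `"two.sided"` uses Fisher's exact test on the 2x2 table.
#'
#' @param both,only_a,only_ref,neither the four Venn counts
#'   (see [overlap_counts()])
#' @param alternative `"over"`, `"under"` or `"two.sided"`
#' @return p-value
#' @export
enrichment_test <- function(both, only_a, only_ref, neither,
                            alternative = c("over", "under", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(both >= 0, only_a >= 0, only_ref >= 0, neither >= 0)
  m <- both + only_ref          # reference (success) genes
  n <- only_a + neither         # non-reference genes
  k <- both + only_a            # draws = |set_a|
  switch(alternative,
    over = stats::phyper(both - 1, m, n, k, lower.tail = FALSE),
    under = stats::phyper(both, m, n, k, lower.tail = TRUE),
    two.sided = stats::fisher.test(matrix(c(both, only_a, only_ref, neither),
                                          2, 2))$p.value)
}

#' Annotate a TI table with TOP membership
#'
#' @param ti_table data.frame with at least `gene_id` and `te_class`
#'   (a `txn_class` column, if present, refines the fraction breakdown)
#' @param top either a [scan_top_motif()] data.frame or a character vector
#'   of TOP gene ids; genes not covered get `is_top = NA` and are excluded
#'   from the fractions
#' @return list with `table` (input plus `is_top` column) and `fractions`
#'   (data.frame of per-class TOP counts and fractions)
#' @export
annotate_top <- function(ti_table, top) {
  if (is.data.frame(top)) {
    is_top <- stats::setNames(top$is_top, top$gene_id)[ti_table$gene_id]
  } else {
    is_top <- ti_table$gene_id %in% top
  }
  ti_table$is_top <- unname(is_top)
  by <- if ("txn_class" %in% names(ti_table))
    interaction(ti_table$te_class, ti_table$txn_class, sep = "/")
  else factor(ti_table$te_class)
  keep <- !is.na(ti_table$is_top)
  tot <- tapply(keep, by, sum, default = 0)
  ntop <- tapply(ti_table$is_top & keep, by, sum, default = 0)
  fractions <- data.frame(class = names(tot),
                          n = as.integer(tot), n_top = as.integer(ntop),
                          top_fraction = ifelse(tot > 0, ntop / tot, NA_real_),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(table = ti_table, fractions = fractions)
}
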