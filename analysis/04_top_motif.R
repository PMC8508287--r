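#!/usr/bin/env Rscript
# Step 4: 5'TOP motif analysis. Scans every 5'UTR for a cap-adjacent C
# followed by >= 4 further pyrimidines, intersects the translationally
# up-regulated set with the reference TOP catalogue, and tests the overlap
# for hypergeometric over-representation. TOP mRNAs (ribosomal proteins,
# translation factors) concentrating in the translationally up class is the
# expected signature of selective polysome recruitment.

suppressMessages(library(polyTI))

utrs <- read_fasta_utrs("results/data/utrs.fa")
reference <- read_gene_list("results/data/top_reference.txt")
res <- utils::read.delim("results/ti_table.tsv", stringsAsFactors = FALSE)
tx <- utils::read.delim("results/txn_table.tsv", stringsAsFactors = FALSE)

calls <- scan_top_motif(utrs)
utils::write.table(calls, "results/top_calls.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("TOP motif called in %d of %d UTRs\n", sum(calls$is_top),
            nrow(calls)))

universe <- res$gene_id
te_up <- res$gene_id[res$te_class == "up"]
oc <- overlap_counts(te_up, intersect(reference, universe), universe)
p_enrich <- enrichment_test(oc$both, oc$only_a, oc$only_ref, oc$neither)
cat(sprintf("TI-up vs reference TOP list: both=%d only_up=%d only_ref=%d neither=%d\n",
            oc$both, oc$only_a, oc$only_ref, oc$neither))
cat(sprintf("hypergeometric over-representation p = %.3g\n", p_enrich))
utils::write.table(
  data.frame(only_te_up = oc$only_a, only_reference = oc$only_ref,
             both = oc$both, neither = oc$neither, p_value = p_enrich),
  "results/top_overlap.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

res$txn_class <- tx$txn_class[match(res$gene_id, tx$gene_id)]
ann <- annotate_top(res, calls)
utils::write.table(ann$fractions, "results/top_fractions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
up_rows <- ann$fractions[grep("^up/", ann$fractions$class), ]
if (sum(up_rows$n_top) > 0) {
  cat("transcriptional status of the TOP, translationally up genes:\n")
  print(data.frame(class = up_rows$class, n_top = up_rows$n_top,
                   pct_of_top_up = round(100 * up_rows$n_top /
                                           sum(up_rows$n_top), 1)))
}

jsonlite::write_json(
  list(step = "top_motif",
       inputs = c("results/data/utrs.fa", "results/data/top_reference.txt",
                  "results/ti_table.tsv"),
       outputs = c("results/top_calls.tsv", "results/top_overlap.tsv",
                   "results/top_fractions.tsv"),
       enrichment_p = p_enrich,
       package_version = as.character(utils::packageVersion("polyTI"))),
  "results/top_manifest.json", auto_unbox = TRUE, pretty = TRUE)
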