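test_that("transcriptional classes follow the cytoplasmic fold/FDR rule", {
  ds <- make_group_counts(cyto_nt = c(40, 40), cyto_t = c(40, 40),
                          poly_nt = c(40, 40), poly_t = c(40, 40))
  tx <- classify_transcriptional(ds, c("g1", "g2"), ti_config())
  expect_true(all(tx$txn_class == "stable"))
  expect_true(all(tx$log2_fc == 0))
  expect_true(all(tx$p_value == 1))
})

test_that("injected transcriptional shifts are recovered with high sensitivity", {
  # 6 replicates/group: C(12,6) = 924 joint label assignments give the
  # exhaustive permutation p a two-sided floor of ~0.0022, small enough for
  # BH at alpha = 0.05 to select strong effects
  cfg <- sim_config(n_genes = 400, replicates = 6,
                    txn_props = c(up = 0.1, down = 0.1, stable = 0.8),
                    te_props = c(up = 0, down = 0, stable = 1),
                    effect_range = c(1.5, 2.5),
                    dispersion_range = c(0.05, 0.1),
                    base_meanlog = log(500), base_sdlog = 0.3, seed = 41)
  truth <- simulate_gene_truth(cfg)
  ds <- simulate_counts(truth, cfg)
  tic <- ti_config(seed = 3)
  tx <- classify_transcriptional(ds, truth$gene_id, tic)
  m <- merge(truth, tx, by = "gene_id")
  for (cl in c("up", "down")) {
    sens <- mean(m$txn_class.y[m$txn_class.x == cl] == cl)
    expect_gt(sens, 0.9)
  }
  fp <- mean(m$txn_class.y[m$txn_class.x == "stable"] != "stable")
  expect_lt(fp, 0.05)
})

test_that("cross-classification reproduces row counts and percentages", {
  # feed class vectors with the published down-row structure
  te <- c(rep("down", 673), rep("up", 213))
  tx <- c(rep("stable", 315), rep("up", 340), rep("down", 18),
          rep("stable", 73), rep("down", 131), rep("up", 9))
  ids <- sprintf("g%04d", seq_along(te))
  tab <- cross_classify(stats::setNames(te, ids), stats::setNames(tx, ids), ids)
  expect_equal(tab$counts["down", "stable"], 315L)
  expect_equal(tab$counts["down", "up"], 340L)
  expect_equal(tab$row_percentages["down", "stable"], 46.8)
  expect_equal(tab$row_percentages["down", "up"], 50.5)
  expect_equal(tab$row_percentages["up", "down"], 61.5)
  expect_equal(sum(tab$counts), length(ids))
  # marginals equal the standalone class counts
  expect_equal(unname(rowSums(tab$counts)[c("up", "down")]), c(213L, 673L))

  empty <- cross_classify(character(0), character(0), character(0))
  expect_true(all(empty$counts == 0))
  expect_true(all(is.na(empty$row_percentages)))

  expect_error(cross_classify(stats::setNames("up", "g1"),
                              stats::setNames("up", "g2"), c("g1", "g2")),
               "missing a class")
})

test_that("class percentages follow count * 100 / total to 2 decimals", {
  expect_equal(unname(class_percentages(c(673, 213))), c(75.96, 24.04))
  expect_equal(unname(class_percentages(1, 1)), 100.00)
  expect_equal(unname(class_percentages(c(3, 1, 0))), c(75, 25, 0))
  expect_true(all(is.na(class_percentages(c(0, 0), 0))))
})

test_that("the modal cross-table cell recovers the injected class pair", {
  # regulated genes stay a minority in every group so that median-of-ratios
  # normalization keeps its anchor in the unregulated majority
  cfg <- sim_config(n_genes = 800, replicates = 6,
                    txn_props = c(up = 0.15, down = 0.15, stable = 0.7),
                    te_props = c(up = 0.15, down = 0.15, stable = 0.7),
                    effect_range = c(2, 2.5),
                    dispersion_range = c(0.02, 0.05),
                    base_meanlog = log(2000), base_sdlog = 0.2, seed = 53)
  truth <- simulate_gene_truth(cfg)
  ds <- simulate_counts(truth, cfg)
  tic <- ti_config(seed = 5)
  res <- run_translatome(ds, tic)
  tx <- classify_transcriptional(ds, res$gene_id, tic)
  called <- stats::setNames(paste(res$te_class,
                                  stats::setNames(tx$txn_class,
                                                  tx$gene_id)[res$gene_id]),
                            res$gene_id)
  tru <- stats::setNames(paste(truth$te_class, truth$txn_class),
                         truth$gene_id)[res$gene_id]
  # among genes with a given injected (te, txn) pair, the modal called pair
  # is that pair
  for (pair in unique(tru)) {
    cells <- table(called[tru == pair])
    expect_equal(names(which.max(cells)), pair)
  }
})
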