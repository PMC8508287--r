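test_that("the TOP call follows the cap-adjacent C + pyrimidine-run rule", {
  calls <- scan_top_motif(c(a = "ATTTTTTTGGACGT", b = "CTTTCGGGGGGGGGGAA",
                            c = "CTAGGACGT", d = "NTTTTTTTACGT",
                            e = "CCCCCCCCCCCCCCCCCCCCA"))
  expect_equal(calls$is_top, c(FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(calls$pyrimidine_run, c(0L, 5L, 2L, 0L, 20L))
  expect_true(calls$g_rich_downstream[2])
  expect_match(calls$reason[4], "ambiguous")
  # long pyrimidine tracts are never disqualified
  expect_true(calls$is_top[5])
})

test_that("the scanner agrees with the regex oracle on random sequences", {
  set.seed(19)
  seqs <- vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), replace = TRUE,
                 prob = c(0.2, 0.3, 0.2, 0.3)), collapse = ""), character(1))
  got <- scan_top_motif(stats::setNames(seqs, paste0("s", seq_along(seqs))))
  expect_equal(got$is_top, grepl("^C[CT]{4,}", seqs))
})

test_that("Venn counts partition the universe", {
  expect_equal(overlap_counts(c("1", "2", "3"), c("2", "3", "4"),
                              as.character(1:6)),
               list(only_a = 1L, only_ref = 1L, both = 2L, neither = 2L))
  u <- letters[1:5]
  expect_equal(overlap_counts(u, u, u),
               list(only_a = 0L, only_ref = 0L, both = 5L, neither = 0L))
  expect_equal(overlap_counts(c("a"), c("b"), u)$both, 0L)
  expect_error(overlap_counts(c("z"), c("a"), u), "outside the universe")

  set.seed(7)
  for (i in 1:10) {
    u <- sample(letters, 15)
    a <- sample(u, 6); r <- sample(u, 4)
    oc <- overlap_counts(a, r, u)
    expect_equal(oc$only_a + oc$only_ref + oc$both + oc$neither, 15L)
  }
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # universe 6, 3 reference, draw 3, observe all 3: C(3,3)C(3,0)/C(6,3)
  expect_equal(enrichment_test(both = 3, only_a = 0, only_ref = 0,
                               neither = 3), 1 / 20)
  expect_equal(enrichment_test(both = 4, only_a = 0, only_ref = 6,
                               neither = 0), 1)  # reference = universe
  expect_equal(enrichment_test(both = 0, only_a = 3, only_ref = 2,
                               neither = 5), 1)

  # brute force over all draws for small universes
  for (N in c(5, 8, 12)) for (K in c(2, floor(N / 2))) for (n in c(2, 3)) {
    draws <- utils::combn(N, n)
    for (x in 0:min(K, n)) {
      exact <- mean(apply(draws, 2, function(d) sum(d <= K)) >= x)
      expect_equal(enrichment_test(both = x, only_a = n - x,
                                   only_ref = K - x,
                                   neither = N - K - (n - x)), exact)
    }
  }
})

test_that("TOP annotation reports per-class fractions and finds enrichment", {
  tab <- data.frame(gene_id = paste0("g", 1:6),
                    te_class = c("up", "up", "down", "down", "stable", "stable"))
  ann <- annotate_top(tab, character(0))
  expect_true(all(ann$fractions$top_fraction == 0))

  # prevalence 0.8 in the te-up class vs 0.05 elsewhere
  cfg <- sim_config(n_genes = 1000,
                    te_props = c(up = 0.2, down = 0.1, stable = 0.7),
                    top_prev_te_up = 0.8, top_prev_other = 0.05, seed = 61)
  truth <- simulate_gene_truth(cfg)
  ann2 <- annotate_top(truth[, c("gene_id", "te_class")],
                       truth$gene_id[truth$is_top])
  fr <- ann2$fractions
  expect_gt(fr$top_fraction[fr$class == "up"],
            max(fr$top_fraction[fr$class != "up"]))
  oc <- overlap_counts(truth$gene_id[truth$te_class == "up"],
                       truth$gene_id[truth$is_top], truth$gene_id)
  expect_lt(enrichment_test(oc$both, oc$only_a, oc$only_ref, oc$neither),
            0.01)
})

test_that("missing TOP calls are excluded from the fractions", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    te_class = c("up", "up", "up"))
  calls <- scan_top_motif(c(g1 = "CTTTTTGGG", g2 = "ATTTTTGGG"))
  ann <- annotate_top(tab, calls)
  expect_true(is.na(ann$table$is_top[3]))
  expect_equal(ann$fractions$n[ann$fractions$class == "up"], 2L)
  expect_equal(ann$fractions$top_fraction[ann$fractions$class == "up"], 0.5)
})
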