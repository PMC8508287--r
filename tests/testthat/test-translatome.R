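test_that("median-of-ratios size factors match hand computation", {
  m <- matrix(c(10, 20, 30), 3, 4, dimnames = list(paste0("g", 1:3),
                                                   paste0("s", 1:4)))
  expect_equal(unname(estimate_size_factors(m)), rep(1, 4))

  # column 2 = 2 x column 1: ratios to the geometric mean are 1/sqrt(2) and
  # sqrt(2) for every gene, already at geometric mean 1
  m2 <- cbind(s1 = c(10, 50, 200), s2 = c(20, 100, 400))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))

  expect_equal(unname(estimate_size_factors(m[, 1, drop = FALSE])), 1)

  m3 <- cbind(s1 = c(5, 0), s2 = c(0, 7))
  rownames(m3) <- c("g1", "g2")
  expect_error(estimate_size_factors(m3), "no gene has nonzero counts")
})

test_that("expression filter requires the floor in all four groups", {
  ds <- make_group_counts(cyto_nt = c(100, 12), cyto_t = c(100, 11),
                          poly_nt = c(100, 15), poly_t = c(0, 10))
  cfg <- ti_config(expression_min_mean = 10)
  kept <- filter_expressed(ds, cfg, size_factors = rep(1, 12))
  expect_false("g1" %in% kept)  # zero mean in poly-T
  expect_true("g2" %in% kept)   # boundary mean of 10 is inclusive
})

test_that("TI arithmetic follows x1/x2 on group means", {
  ds <- make_group_counts(cyto_nt = c(10, 7), cyto_t = c(10, 7),
                          poly_nt = c(5, 7), poly_t = c(20, 7))
  ti <- compute_ti(ds, size_factors = rep(1, 12))
  expect_equal(ti$x1[1], 2)     # 20 / 10
  expect_equal(ti$x2[1], 0.5)   # 5 / 10
  expect_equal(ti$log2_ti[1], 2)
  expect_equal(ti$log2_ti[2], 0)  # all four means equal
})

test_that("permutation p-values equal the exhaustive oracle for 2+2 and 3+3", {
  for (reps in c(2, 3)) {
    cfg <- sim_config(n_genes = 40, replicates = reps, seed = 17 + reps)
    ds <- simulate_counts(simulate_gene_truth(cfg), cfg)
    tic <- ti_config(seed = 1)
    genes <- filter_expressed(ds, tic)
    got <- test_ti(ds, genes, tic)
    expect_true(attr(got, "exhaustive"))
    expect_equal(attr(got, "n_distinct"), choose(2 * reps, reps))
    expect_equal(got$p_value, oracle_ti_perm(ds, genes))
  }
})

test_that("a null statistic gives p = 1 and strong effects saturate p", {
  # all samples identical: every permuted statistic is exactly 0
  ds <- make_group_counts(c(50, 10), c(50, 10), c(50, 10), c(50, 10))
  p <- test_ti(ds, c("g1", "g2"), ti_config())$p_value
  expect_equal(p, c(1, 1))

  # near-noiseless strong shift in a minority of genes: their observed
  # |stat| strictly beats every reassignment except its own complement,
  # the two-sided floor of 2 / C(6, 3)
  cfg <- sim_config(n_genes = 100, replicates = 3,
                    te_props = c(up = 0.1, down = 0, stable = 0.9),
                    txn_props = c(up = 0, down = 0, stable = 1),
                    effect_range = c(3, 3),
                    dispersion_range = c(1e-6, 1e-6),
                    libsize_range = c(1, 1),
                    base_meanlog = log(20000), base_sdlog = 0, seed = 23)
  truth2 <- simulate_gene_truth(cfg)
  ds2 <- simulate_counts(truth2, cfg)
  p2 <- test_ti(ds2, rownames(ds2$counts), ti_config())$p_value
  expect_true(all(p2[truth2$te_class == "up"] == 2 / choose(6, 3)))
})

test_that("the test refuses designs with fewer than 2 replicates per group", {
  ds <- make_group_counts(c(10), c(10), c(8), c(8), reps = 2)
  ds1 <- ds
  keep <- ds$samples$sample_id != "poly_T_r2"
  ds1 <- count_dataset(ds$counts[, keep, drop = FALSE], ds$samples[keep, ])
  expect_error(test_ti(ds1, "g1", ti_config()), "polysomal")
})

test_that("BH adjustment matches hand computation and handles edge vectors", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.3), 0.3)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(adjust_fdr(p), oracle_bh(p))
  }
})

test_that("classification applies the fold and FDR thresholds strictly", {
  cfg <- ti_config(fold_cutoff = 1.5, alpha = 0.05)
  # a log2 TI of -0.99 is a 1.99-fold repression: down when significant
  expect_equal(classify_regulation(-0.99, 0.01, cfg), "down")
  expect_equal(classify_regulation(0, 0.0001, cfg), "stable")
  expect_equal(classify_regulation(0.5, 0.001, cfg), "stable")  # 1.41 < 1.5
  expect_equal(classify_regulation(0.99, 0.2, cfg), "stable")   # not significant
  expect_equal(classify_regulation(log2(1.5), 0.049, cfg), "up")
})

test_that("the full run is internally consistent and library-scale invariant", {
  cfg <- sim_config(n_genes = 150, replicates = 3, seed = 37)
  ds <- simulate_counts(simulate_gene_truth(cfg), cfg)
  tic <- ti_config(seed = 2)
  res <- run_translatome(ds, tic)
  expect_equal(nrow(res), length(filter_expressed(ds, tic)))
  expect_equal(sum(table(res$te_class)), nrow(res))
  expect_true(all(res$fdr >= res$p_value - 1e-12))

  # rescaling one library moves every normalized count by a common constant,
  # so the TI of genes expressed under both normalizations is unchanged
  scaled <- ds
  scaled$counts[, 7] <- scaled$counts[, 7] * 3
  res2 <- run_translatome(scaled, tic)
  common <- merge(res[, c("gene_id", "log2_ti")],
                  res2[, c("gene_id", "log2_ti")], by = "gene_id")
  expect_gt(nrow(common), 100)
  expect_lt(max(abs(common$log2_ti.x - common$log2_ti.y)), 1e-6)
})
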