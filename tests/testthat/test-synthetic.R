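test_that("default preset reproduces the 115-array two-class design", {
  gt <- dc_group_table()
  expect_equal(sum(gt$n), 115L)
  expect_equal(sum(gt$n[gt$class == "inflammatory"]), 79L)

  sim <- simulate_expression(synthetic_config(n_genes = 120, seed = 5))
  expect_equal(nrow(sim$sheet), 115L)
  expect_equal(sum(sim$sheet$class == "inflammatory"), 79L)
  expect_equal(dim(sim$expression), c(120L, 115L))
  expect_equal(colnames(sim$expression), sim$sheet$sample_id)
  expect_equal(sim$qc$sample_id, sim$sheet$sample_id)
  expect_false(anyNA(sim$expression))
  # planted annotation covers exactly the requested numbers
  expect_equal(c(sum(sim$truth$signature$direction == "up"),
                 sum(sim$truth$signature$direction == "down")), c(36L, 18L))
})

test_that("matrix dimensions track arbitrary group configurations", {
  for (sizes in list(c(5L, 7L), c(12L, 3L))) {
    cfg <- synthetic_config(n_genes = 40, group_sizes = two_group_sizes(sizes[1], sizes[2]),
                            n_signature_up = 2, n_signature_down = 2, seed = 1)
    sim <- simulate_expression(cfg)
    expect_equal(dim(sim$expression), c(40L, sum(sizes)))
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(n_genes = 0), "n_genes")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(effect_size = -1), "effect_size")
  expect_error(synthetic_config(qc_fail_fraction = 1.5), "qc_fail_fraction")
  expect_error(synthetic_config(n_genes = 10, n_signature_up = 8,
                                n_signature_down = 8), "n_signature")
})

test_that("the generator is reproducible from its seed", {
  cfg <- synthetic_config(n_genes = 50, n_signature_up = 5,
                          n_signature_down = 5, seed = 42)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$truth, b$truth)
  c <- simulate_expression(synthetic_config(n_genes = 50, n_signature_up = 5,
                                            n_signature_down = 5, seed = 43))
  expect_false(identical(a$expression, c$expression))
})

test_that("zero effect size leaves planted genes exchangeable between classes", {
  cfg <- synthetic_config(n_genes = 600, group_sizes = two_group_sizes(30, 30),
                          n_signature_up = 250, n_signature_down = 250,
                          effect_size = 0, seed = 17)
  sim <- simulate_expression(cfg)
  inf <- sim$sheet$class == "inflammatory"
  pvals <- apply(sim$expression[sim$truth$signature$gene_id, ], 1L, function(v)
    t.test(v[inf], v[!inf])$p.value)
  rate <- mean(pvals < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(abs(rate - 0.05), tol)
})

test_that("planted class separation increases with effect size", {
  diffs <- vapply(c(0, 1, 2), function(es) {
    cfg <- synthetic_config(n_genes = 300, group_sizes = two_group_sizes(40, 40),
                            n_signature_up = 50, n_signature_down = 0,
                            effect_size = es, seed = 31)
    sim <- simulate_expression(cfg)
    inf <- sim$sheet$class == "inflammatory"
    up <- sim$truth$signature$gene_id
    mean(rowMeans(sim$expression[up, inf]) - rowMeans(sim$expression[up, !inf]))
  }, numeric(1))
  # s.e. of each mean difference is about noise_sd * sqrt(2/40) / sqrt(50)
  se1 <- 0.5 * sqrt(2 / 40) / sqrt(50)
  expect_gt(diffs[2], diffs[1] + 3 * se1)
  expect_gt(diffs[3], diffs[2] + 3 * se1)
})

test_that("qc failure fraction is honoured in expectation", {
  cfg <- synthetic_config(n_genes = 10, n_signature_up = 2, n_signature_down = 1,
                          qc_fail_fraction = 0.3, seed = 8)
  fails <- vapply(1:30, function(i) {
    cfg2 <- cfg
    cfg2$seed <- cfg$seed + i
    sim <- simulate_expression(cfg2)
    mean(sim$qc$actin_ratio > 3 | sim$qc$gapdh_ratio > 3)
  }, numeric(1))
  expect_lt(abs(mean(fails) - 0.3), 3 * sqrt(0.3 * 0.7 / (30 * 115)))
})

test_that("Ct tables invert exactly to the planted fold changes at zero noise", {
  cfg <- synthetic_config(n_genes = 50, n_signature_up = 3, n_signature_down = 2,
                          seed = 12)
  sim <- simulate_expression(cfg)
  conds <- c(lps = "inflammatory", dex = "non_inflammatory")
  ct <- simulate_ct_table(cfg, sim$truth, conds, n_replicates = 2,
                          log2_fc = 3, noise_sd = 0)
  fc <- fold_change(ct)
  up <- sim$truth$signature$gene_id[sim$truth$signature$direction == "up"]
  down <- sim$truth$signature$gene_id[sim$truth$signature$direction == "down"]
  expect_equal(unname(fc$fold[up, "lps"]), rep(8, length(up)))
  expect_equal(unname(fc$fold[up, "dex"]), rep(1 / 8, length(up)))
  expect_equal(unname(fc$fold[down, "lps"]), rep(1 / 8, length(down)))
  expect_equal(unname(fc$fold[, "untreated"]), rep(1, 5))
})

test_that("unknown gene ids in Ct generation are rejected", {
  cfg <- synthetic_config(n_genes = 20, n_signature_up = 2,
                          n_signature_down = 1, seed = 1)
  sim <- simulate_expression(cfg)
  expect_error(
    simulate_ct_table(cfg, sim$truth, c(lps = "inflammatory"),
                      gene_ids = c(sim$truth$signature$gene_id, "nope_at")),
    "unknown gene id")
})

test_that("fold-change recovery error scales as noise_sd over sqrt(replicates)", {
  # Monte-Carlo: with sd 0.25 on target Ct and 3 replicates the mean
  # absolute log2 error of recovered fold changes is approximately
  # 0.25/sqrt(3), within +/-50%.
  cfg <- synthetic_config(n_genes = 60, n_signature_up = 25,
                          n_signature_down = 25, noise_sd = 0.25, seed = 23)
  sim <- simulate_expression(cfg)
  conds <- c(a = "inflammatory", b = "inflammatory", c = "non_inflammatory",
             d = "non_inflammatory")
  errs <- unlist(lapply(1:5, function(i) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + i
    ct <- simulate_ct_table(cfg2, sim$truth, conds, n_replicates = 3, log2_fc = 3)
    fc <- fold_change(ct)
    sgn <- outer(ifelse(sim$truth$signature$direction == "up", 1, -1),
                 ifelse(conds == "inflammatory", 1, -1))
    abs(log2(fc$fold[, names(conds)]) - 3 * sgn)
  }))
  target <- 0.25 / sqrt(3)
  expect_gt(mean(errs), target * 0.5)
  expect_lt(mean(errs), target * 1.5)
})
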