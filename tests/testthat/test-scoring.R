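mk_ct <- function(...) {
  ct <- rbind(...)
  df <- data.frame(gene_id = ct[, 1], condition = ct[, 2],
                   replicate = as.integer(ct[, 3]),
                   ct_target = as.numeric(ct[, 4]),
                   ct_18s = as.numeric(ct[, 5]),
                   stringsAsFactors = FALSE)
  attr(df, "reference") <- "untreated"
  df
}

test_that("fold_change implements the 2^-ddCt arithmetic", {
  ct <- mk_ct(
    c("g1", "untreated", 1, 26, 12),
    c("g1", "same", 1, 26, 12),      # ddCt = 0 -> fold 1
    c("g1", "lps", 1, 25, 12),       # one cycle earlier -> fold 2
    c("g2", "untreated", 1, 30, 12),
    c("g2", "same", 1, 31, 13),      # equal housekeeping shift -> fold 1
    c("g2", "lps", 1, 33, 12))       # three cycles later -> fold 1/8
  fc <- fold_change(ct)
  expect_equal(unname(fc$fold["g1", c("untreated", "same", "lps")]), c(1, 1, 2))
  expect_equal(unname(fc$fold["g2", c("same", "lps")]), c(1, 1 / 8))
})

test_that("replicate fold changes average arithmetically", {
  # replicates engineered to give folds 2, 4 and 6 -> cell mean 4
  ct <- mk_ct(
    c("g1", "untreated", 1, 20, 12),
    c("g1", "stim", 1, 20 - log2(2), 12),
    c("g1", "stim", 2, 20 - log2(4), 12),
    c("g1", "stim", 3, 20 - log2(6), 12))
  fc <- fold_change(ct)
  expect_equal(unname(fc$fold["g1", "stim"]), 4)
  expect_equal(unname(fc$n_replicates["g1", "stim"]), 3L)
})

test_that("fold_change validates its inputs", {
  ct <- mk_ct(c("g1", "stim", 1, 20, 12))
  expect_error(fold_change(ct), "reference")
  ct2 <- mk_ct(c("g1", "untreated", 1, 20, 12),
               c("g1", "stim", 1, 21, 12),
               c("g2", "stim", 1, 21, 12))
  expect_error(fold_change(ct2), "g2")
  ct3 <- mk_ct(c("g1", "untreated", 1, -1, 12))
  expect_error(fold_change(ct3), "positive")
})

test_that("thresholds are the mean of the two class medians", {
  fc <- rbind(gA = c(4, 8, 16, 0.5, 1, 2))
  colnames(fc) <- c("i1", "i2", "i3", "n1", "n2", "n3")
  refs <- c(i1 = "inflammatory", i2 = "inflammatory", i3 = "inflammatory",
            n1 = "non_inflammatory", n2 = "non_inflammatory",
            n3 = "non_inflammatory")
  th <- derive_thresholds(fc, refs, c(gA = "up"))
  expect_equal(th$median_inflammatory, 8)
  expect_equal(th$median_noninflammatory, 1)
  expect_equal(th$threshold, 4.5)
  # even replicate count: median is the midpoint
  fc2 <- rbind(gA = c(2, 4, 1, 1))
  colnames(fc2) <- c("i1", "i2", "n1", "n2")
  refs2 <- c(i1 = "inflammatory", i2 = "inflammatory",
             n1 = "non_inflammatory", n2 = "non_inflammatory")
  expect_equal(derive_thresholds(fc2, refs2, c(gA = "up"))$median_inflammatory, 3)
})

test_that("degenerate and invalid threshold inputs are handled", {
  fc <- rbind(gA = c(2, 2))
  colnames(fc) <- c("i1", "n1")
  refs <- c(i1 = "inflammatory", n1 = "non_inflammatory")
  expect_warning(th <- derive_thresholds(fc, refs, c(gA = "up")), "margin")
  expect_equal(th$threshold, 2)
  expect_error(derive_thresholds(fc, c(i1 = "inflammatory"), c(gA = "up")),
               "per class")
  expect_error(derive_thresholds(fc, refs, c(gB = "up")), "gA")
})

test_that("the scoring rule matches its 8-case enumeration oracle", {
  th <- data.frame(gene_id = "g", direction = NA, threshold = 4.5,
                   stringsAsFactors = FALSE)
  for (direction in c("up", "down"))
    for (claimed in c("inflammatory", "non_inflammatory"))
      for (value in c(6, 3)) {
        th$direction <- direction
        got <- score_condition(c(g = value), th, claimed)$score
        expect_identical(got, score_oracle(value, 4.5, direction, claimed),
                         info = paste(direction, claimed, value))
      }
})

test_that("a value exactly at the threshold always scores 0", {
  for (direction in c("up", "down"))
    for (claimed in c("inflammatory", "non_inflammatory")) {
      th <- data.frame(gene_id = "g", direction = direction, threshold = 2)
      expect_identical(score_condition(c(g = 2), th, claimed)$score, 0L)
    }
})

test_that("scores under the two claims are complementary off the threshold", {
  set.seed(15)
  th <- data.frame(gene_id = paste0("g", 1:50),
                   direction = sample(c("up", "down"), 50, TRUE),
                   threshold = runif(50, 0.5, 4))
  values <- setNames(runif(50, 0.1, 5), th$gene_id)
  s_inf <- score_condition(values, th, "inflammatory")$score
  s_ninf <- score_condition(values, th, "non_inflammatory")$score
  at <- values == th$threshold
  expect_true(all((s_inf + s_ninf)[!at] == 1L))
  expect_true(all((s_inf + s_ninf)[at] == 0L))
})

test_that("scoring is invariant to rescaling a gene's folds and threshold", {
  th <- data.frame(gene_id = c("g1", "g2"), direction = c("up", "down"),
                   threshold = c(2, 3))
  values <- c(g1 = 5, g2 = 1)
  base <- score_condition(values, th, "inflammatory")$score
  for (c_scale in c(0.1, 7)) {
    th2 <- transform(th, threshold = threshold * c_scale)
    expect_identical(score_condition(values * c_scale, th2,
                                     "inflammatory")$score, base)
  }
})

test_that("concordance reproduces the printed percent pairs with half-up rounding", {
  cases <- list(c(51, 54, 94), c(54, 54, 100), c(43, 54, 80),
                c(46, 54, 85), c(48, 54, 89), c(52, 54, 96),
                c(53, 54, 98), c(35, 44, 80), c(40, 44, 91), c(0, 10, 0))
  for (cs in cases) {
    out <- concordance(rep(c(1L, 0L), c(cs[1], cs[2] - cs[1])))
    expect_equal(out$percent, cs[3], info = paste(cs[1], "/", cs[2]))
    expect_equal(out$k_of_n, sprintf("%d/%d", cs[1], cs[2]))
    expect_equal(out$fraction, cs[1] / cs[2])
  }
  expect_equal(concordance(data.frame(score = c(1L, 1L, 0L)))$percent, 67)
})

test_that("class calls follow the majority vote with ties to non-inflammatory", {
  th <- data.frame(gene_id = paste0("g", 1:4), direction = "up", threshold = 1)
  all_inf <- call_class(setNames(rep(2, 4), th$gene_id), th)
  expect_equal(all_inf$class, "inflammatory")
  expect_equal(all_inf$margin, 1)
  half <- call_class(setNames(c(2, 2, 0.5, 0.5), th$gene_id), th)
  expect_equal(half$class, "non_inflammatory")
  expect_equal(half$margin, 0)
})

test_that("class calls agree with the claim whenever concordance exceeds 1/2", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(3:9, 1)
    th <- data.frame(gene_id = paste0("g", seq_len(n)),
                     direction = sample(c("up", "down"), n, TRUE),
                     threshold = runif(n, 0.5, 3))
    values <- setNames(runif(n, 0.1, 4), th$gene_id)
    for (claimed in c("inflammatory", "non_inflammatory")) {
      conc <- concordance(score_condition(values, th, claimed))$fraction
      if (conc > 0.5)
        expect_equal(call_class(values, th)$class, claimed)
    }
  }
})

test_that("median/threshold pipeline matches a brute-force recomputation", {
  set.seed(31)
  genes <- paste0("g", 1:20)
  conds <- c(paste0("i", 1:3), paste0("n", 1:4))
  refs <- setNames(rep(c("inflammatory", "non_inflammatory"), c(3, 4)), conds)
  m <- matrix(2^rnorm(20 * 7), 20, 7, dimnames = list(genes, conds))
  dirs <- setNames(sample(c("up", "down"), 20, TRUE), genes)
  th <- derive_thresholds(m, refs, dirs)
  for (g in genes) {
    mi <- median(sort(m[g, 1:3]))
    mn <- median(sort(m[g, 4:7]))
    expect_identical(th$threshold[th$gene_id == g], (mi + mn) / 2)
  }
})

test_that("zero-noise synthetic panels score perfectly consistent conditions", {
  cfg <- synthetic_config(n_genes = 60, n_signature_up = 6,
                          n_signature_down = 4, seed = 19)
  sim <- simulate_expression(cfg)
  conds <- c(i1 = "inflammatory", i2 = "inflammatory",
             n1 = "non_inflammatory", n2 = "non_inflammatory",
             q_inf = "inflammatory", q_ninf = "non_inflammatory")
  ct <- simulate_ct_table(cfg, sim$truth, conds, noise_sd = 0)
  fc <- fold_change(ct)
  dirs <- with(sim$truth$signature, setNames(direction, gene_id))
  th <- derive_thresholds(fc, conds[1:4], dirs)
  for (q in c("q_inf", "q_ninf")) {
    sc <- scorecard(fc, q, th, conds[[q]])
    expect_equal(sc$concordance$fraction, 1)
    expect_equal(sc$call$class, conds[[q]])
  }
  # the reference condition itself is never scored
  expect_error(scorecard(fc, "untreated", th), "not scored")
})

test_that("scorecard auto-claims through the class call and prints a summary", {
  th <- data.frame(gene_id = c("g1", "g2"), direction = c("up", "down"),
                   threshold = c(1, 1))
  m <- matrix(c(3, 0.2), 2, 1, dimnames = list(c("g1", "g2"), "stim"))
  sc <- scorecard(m, "stim", th)
  expect_equal(sc$claimed_class, "inflammatory")
  expect_equal(sc$concordance$percent, 100)
  expect_output(print(sc), "100%")
})
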