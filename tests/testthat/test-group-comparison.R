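# ANOVA (raw and summary paths), post hoc corrections, the Levene gate,
# demographic tests, and the full per-feature comparison.

test_that("F is zero for identical group values and matches oneway.test otherwise", {
  g <- list(a = rep(1, 5), b = rep(1, 5), c = rep(1, 5))
  expect_equal(anova_oneway(g)$F, 0)
  expect_equal(anova_oneway(g)$p, 1)

  set.seed(8)
  for (i in 1:20) {
    sam <- list(rnorm(10, 0), rnorm(12, 0.5), rnorm(9, 1))
    mine <- anova_oneway(sam)
    ref <- oneway.test(v ~ g,
                       data = data.frame(v = unlist(sam),
                                         g = rep(letters[1:3], lengths(sam))),
                       var.equal = TRUE)
    expect_equal(mine$F, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("two-group F equals the squared pooled t statistic", {
  set.seed(21)
  x <- rnorm(15); y <- rnorm(18, 0.4)
  F <- anova_oneway(list(x, y))$F
  t <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(F, unname(t)^2, tolerance = 1e-10)
})

test_that("summary-statistics ANOVA is exactly consistent with the raw-data path", {
  set.seed(4)
  sam <- list(rnorm(20), rnorm(25, 0.3), rnorm(30, 0.6))
  a1 <- anova_oneway(sam)
  a2 <- anova_from_summary(lengths(sam), sapply(sam, mean), sapply(sam, sd))
  expect_lt(abs(a1$F - a2$F), 1e-9)
  expect_equal(anova_from_summary(c(5, 5), c(2, 2), c(1, 1))$F, 0)
  expect_error(anova_from_summary(c(5, 5), c(1, 2), c(1, NA)),
               class = "sptask_error_incomplete_summary")
  expect_error(anova_oneway(list(rnorm(5), 1)),
               class = "sptask_error_insufficient_data")
})

test_that("F is invariant under shifts and rescalings of the data", {
  set.seed(9)
  sam <- list(rnorm(10), rnorm(10, 1), rnorm(10, 2))
  F0 <- anova_oneway(sam)$F
  expect_equal(anova_oneway(lapply(sam, function(x) x + 100))$F, F0,
               tolerance = 1e-9)
  expect_equal(anova_oneway(lapply(sam, function(x) x * 3.7))$F, F0,
               tolerance = 1e-9)
  expect_gte(F0, 0)
})

test_that("post hoc corrections follow their multiplication rules", {
  set.seed(2)
  sam <- list(a = rnorm(20), b = rnorm(20, 0.4), c = rnorm(20, 0.8))
  bon <- posthoc_pairwise(sam, "bonferroni")
  expect_equal(bon$p_corrected, pmin(1, bon$p_raw * 3))
  tam <- posthoc_pairwise(sam, "tamhane_t2")
  expect_equal(tam$p_corrected, pmin(1, 1 - (1 - tam$p_raw)^3))
  expect_true(all(bon$p_corrected >= bon$p_raw))
  expect_true(all(tam$p_corrected >= tam$p_raw))

  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  expect_true(all(posthoc_pairwise(same, "bonferroni")$p_corrected == 1))

  sep <- list(a = rnorm(50), b = rnorm(50, 2), c = rnorm(50, 4))
  expect_true(all(posthoc_pairwise(sep, "bonferroni")$p_corrected < 0.001))
})

test_that("the Levene gate picks the method matching variance homogeneity", {
  set.seed(14)
  pick_eq <- replicate(200, choose_posthoc(list(rnorm(30), rnorm(30), rnorm(30))))
  expect_gte(mean(pick_eq == "bonferroni"), 0.9)
  pick_het <- replicate(200, choose_posthoc(list(rnorm(30, sd = 1),
                                                 rnorm(30, sd = sqrt(5)),
                                                 rnorm(30, sd = 1))))
  expect_gte(mean(pick_het == "tamhane_t2"), 0.9)
  expect_equal(choose_posthoc(list(rep(1, 5), rep(2, 5))), "bonferroni")
})

test_that("demographic tests cover t, chi-square and rank-sum with sane nulls", {
  md <- data.frame(
    participant_id = sprintf("P%02d", 1:60),
    group = rep(c("BPD", "MDD", "HC"), each = 20),
    age = rep(c(21, 24, 27, 30), 15),
    sex = rep(c("F", "M"), 30),
    education = rep(1:4, 15),
    hamd = c(rep(c(16, 18, 20, 22), 10), rep(NA, 20)),
    stringsAsFactors = FALSE)
  res <- demographic_tests(md)
  expect_setequal(res$variable, c("age", "sex", "education", "hamd"))
  # identical distributions across groups: nothing significant
  expect_true(all(res$p > 0.99))

  # 2x2 chi-square with Yates continuity correction, hand-computed
  tab <- matrix(c(30, 20, 10, 40), 2, byrow = TRUE)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  hand <- sum((abs(tab - e) - 0.5)^2 / e)
  expect_equal(unname(chisq.test(tab)$statistic), hand, tolerance = 1e-10)

  md_bad <- md; md_bad$sex[md_bad$group == "HC"] <- "F"
  expect_error(demographic_tests(md_bad), class = "sptask_error_sparse_table")
})

test_that("null feature matrices yield roughly the nominal significant fraction", {
  set.seed(33)
  fm <- make_fm(n_per_group = 25)
  cmp <- compare_all_features(fm)
  expect_equal(nrow(cmp), 108L)
  expect_true(all(c("p_bpd_hc", "p_mdd_hc", "p_bpd_mdd") %in% names(cmp)))
  expect_true(all(cmp$F >= 0))
  # 108 null tests at alpha = 0.05: binomial 99.9% upper bound
  expect_lte(sum(cmp$significant), qbinom(0.999, 108, 0.05))
})

test_that("a planted MDD-vs-HC shift is detected with corrected p < 0.05 in >= 80% of runs", {
  set.seed(61)
  hits <- logical(100)
  cols <- feature_columns()[1:12]
  for (i in 1:100) {
    n <- c(BPD = 77, MDD = 53, HC = 79)
    g <- rep(names(n), n)
    m <- matrix(rnorm(sum(n) * 12), ncol = 12, dimnames = list(NULL, cols))
    fm <- data.frame(participant_id = seq_len(sum(n)), group = g, m,
                     check.names = FALSE)
    # 0.7 SD elevation of task2.freq3-like column in MDD only
    fm[["task2.freq3"]] <- rnorm(sum(n)) + 0.7 * (g == "MDD")
    cmp <- compare_all_features(fm)
    row <- cmp[cmp$feature == "task2.freq3", ]
    hits[i] <- row$significant && row$p_mdd_hc < 0.05
  }
  expect_gte(mean(hits), 0.8)
})

test_that("comparison requires at least two groups", {
  fm <- make_fm(n_per_group = 10, groups = "BPD")
  expect_error(compare_all_features(fm),
               class = "sptask_error_insufficient_data")
})

test_that("BH adjustment across features is available and more conservative", {
  set.seed(44)
  fm <- make_fm(n_per_group = 20)
  cmp <- compare_all_features(fm, p_adjust = "BH")
  expect_true(all(cmp$p_adjusted >= cmp$p - 1e-12))
  expect_lte(sum(cmp$significant), sum(cmp$p < 0.05))
})
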