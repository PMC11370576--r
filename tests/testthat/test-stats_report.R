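test_that("nest_aggregate collapses nested observations to unit means", {
  d <- data.frame(group = c("a", "a", "a", "b"),
                  unit = c("d1", "d1", "d2", "d3"),
                  value = c(1.2, 1.4, 2.0, 3.0))
  agg <- nest_aggregate(d)
  expect_equal(agg$value, c(1.3, 2.0, 3.0))
  expect_equal(agg$group, c("a", "a", "b"))
  # permutation of observations changes nothing
  shuffled <- nest_aggregate(d[sample(nrow(d)), ])
  expect_equal(shuffled$value[order(shuffled$unit)], c(1.3, 2.0, 3.0))
  # one observation per unit is the identity
  solo <- data.frame(group = "a", unit = c("u1", "u2"), value = c(5, 7))
  expect_equal(nest_aggregate(solo)$value, c(5, 7))
})

test_that("one-way ANOVA matches the hand-derivable example and the SS oracle", {
  res <- one_way_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$f, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))

  # identical groups give F = 0
  expect_equal(one_way_anova(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$f, 0)

  set.seed(123)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    sizes <- sample(3:8, k, replace = TRUE)
    values <- rnorm(sum(sizes), mean = rep(runif(k, 0, 3), sizes))
    groups <- rep(letters[1:k], sizes)
    got <- one_way_anova(values, groups)
    want <- oracle_anova(values, groups)
    expect_lt(abs(got$f - want$f), 1e-10)
    expect_lt(abs(got$p_value - want$p_value), 1e-10)
  }
  expect_error(one_way_anova(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("post-hoc comparisons: Bonferroni multiplies capped, Tukey covers all pairs", {
  set.seed(5)
  values <- rnorm(18, rep(c(0, 0.5, 2), each = 6))
  groups <- rep(c("ctl", "ova", "ova-fpm"), each = 6)
  bon <- pairwise_posthoc(values, groups, "bonferroni")
  expect_equal(nrow(bon), 3)  # k(k-1)/2
  expect_true(all(bon$p_adj >= 0 & bon$p_adj <= 1))

  # Bonferroni adjusted p >= raw pairwise p, always
  for (i in seq_len(nrow(bon))) {
    a <- values[groups == bon$group1[i]]
    b <- values[groups == bon$group2[i]]
    raw <- stats::t.test(a, b, var.equal = TRUE)$p.value
    expect_gte(bon$p_adj[i] + 1e-15, raw)
  }

  tuk <- pairwise_posthoc(values, groups, "tukey")
  expect_equal(nrow(tuk), 3)
  expect_setequal(c(tuk$group1, tuk$group2),
                  c("ctl", "ova", "ova-fpm"))
  expect_true(all(tuk$p_adj >= 0 & tuk$p_adj <= 1))

  # near-identical groups: everything non-significant
  flat <- c(1, 2, 3, 1.1, 2.1, 3.1, 0.9, 1.9, 2.9)
  bflat <- pairwise_posthoc(flat, rep(c("a", "b", "c"), each = 3),
                            "bonferroni")
  expect_true(all(bflat$p_adj == 1))
})

test_that("two-sample test handles the classical and degenerate cases", {
  expect_equal(two_sample_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(two_sample_test(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_error(two_sample_test(c(0, 0, 0, 0), c(1, 1, 1, 1)), "degenerate")
  expect_equal(two_sample_test(c(2, 2), c(2, 2))$p_value, 1)

  set.seed(77)
  for (i in 1:100) {
    a <- rnorm(sample(3:10, 1)); b <- rnorm(sample(3:10, 1), 0.5)
    got <- two_sample_test(a, b)
    want <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(got$t, unname(want$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, want$p.value, tolerance = 1e-12)
  }
  # Welch flag changes the degrees of freedom under unequal variance
  a <- c(1, 2, 3, 4); b <- c(10, 30, 50, 70, 90)
  expect_lt(two_sample_test(a, b, var_equal = FALSE)$df,
            two_sample_test(a, b)$df)
})

test_that("group summaries report mean and SEM with the n-1 SD", {
  gs <- group_summary(c(1, 2, 3), rep("g", 3))
  expect_equal(gs$mean, 2)
  expect_equal(gs$sem, 1 / sqrt(3))
  expect_equal(sem(c(1, 2, 3)), sd(c(1, 2, 3)) / sqrt(3))
})

test_that("nested aggregation then ANOVA is invariant to duplicating a dish mean", {
  d <- data.frame(group = rep(c("a", "b"), each = 4),
                  unit = rep(c("d1", "d2", "d3", "d4"), each = 2),
                  value = c(1, 3, 4, 6, 2, 8, 7, 9))
  agg <- nest_aggregate(d)
  base <- one_way_anova(agg$value, agg$group)
  # replace each dish's neurons by two copies of its mean: same dish means
  dup <- data.frame(group = rep(agg$group, each = 2),
                    unit = rep(agg$unit, each = 2),
                    value = rep(agg$value, each = 2))
  agg2 <- nest_aggregate(dup)
  expect_equal(one_way_anova(agg2$value, agg2$group), base)
})
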