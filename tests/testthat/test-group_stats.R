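test_that("the 2-SD filter is single-pass with documented small-n behaviour", {
  f <- filter_2sd(c(1, 2, 3))
  expect_equal(nrow(f$retained), 3)
  expect_equal(nrow(f$excluded), 0)

  # mean 20, SD ~44.7: the outlier is within 2 SD of the mean it inflates
  f2 <- filter_2sd(c(0, 0, 0, 0, 100))
  expect_equal(nrow(f2$retained), 5)

  # mean 5, SD ~15.8, bound 36.6: 50 is excluded in one pass
  f3 <- filter_2sd(c(rep(0, 9), 50))
  expect_equal(nrow(f3$retained), 9)
  expect_equal(f3$excluded$value, 50)

  expect_warning(filter_2sd(c(1, 2)), "n < 3")

  # permutation invariance of the retained multiset
  set.seed(137)
  v <- rnorm(20); v[1] <- 10
  a <- sort(filter_2sd(v)$retained$value)
  b <- sort(filter_2sd(sample(v))$retained$value)
  expect_equal(a, b)
})

test_that("the pooled t test matches its contract on plain and degenerate input", {
  a <- c(1, 2, 3)
  r <- group_t_test(a, a)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 4)

  r2 <- group_t_test(a, a + 10)
  expect_lt(r2$p_value, 0.001)
  expect_equal(r2$direction, "a<b")

  r3 <- group_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(r3$p_value, 1)
  r4 <- group_t_test(c(2, 2, 2), c(5, 5))
  expect_equal(r4$p_value, 0)
  expect_true(is.infinite(r4$statistic))
})

test_that("one within level reduces the two-way ANOVA to F = t^2", {
  set.seed(139)
  d <- data.frame(
    id = paste0("s", 1:12),
    value = c(rnorm(6), rnorm(6, 1)),
    group_label = rep(c("WT", "HET"), each = 6),
    div = 17
  )
  a <- two_way_anova(d, "group_label", "div")
  tt <- group_t_test(d$value[d$group_label == "WT"],
                     d$value[d$group_label == "HET"])
  expect_equal(a$F[a$effect == "group_label"], tt$statistic^2,
               tolerance = 1e-9)
  expect_equal(a$p_value[a$effect == "group_label"], tt$p_value,
               tolerance = 1e-9)
})

test_that("the repeated-measures ANOVA partitions subject variance", {
  set.seed(149)
  n <- 8; divs <- c(17, 21, 27)
  subj_eff <- rnorm(2 * n, sd = 3)        # large stable subject offsets
  d <- expand.grid(id = paste0("s", 1:(2 * n)), div = divs)
  d$group_label <- rep(rep(c("WT", "HET"), each = n), times = length(divs))
  d$value <- subj_eff[as.integer(sub("s", "", d$id))] +
    0.5 * (d$div == 27) + rnorm(nrow(d), sd = 0.5)
  rm_fit <- two_way_anova(d, "group_label", "div", repeated = TRUE)
  plain <- two_way_anova(d, "group_label", "div", repeated = FALSE)
  f_rm <- rm_fit$F[rm_fit$effect == "div"]
  f_plain <- plain$F[plain$effect == "div"]
  # removing subject variance from the error term sharpens the within test
  expect_gt(f_rm, f_plain)
  expect_equal(rm_fit$df2[rm_fit$effect == "div"], (2 * n - 2) * 2)

  d_missing <- d[-1, ]
  expect_warning(two_way_anova(d_missing, "group_label", "div",
                               repeated = TRUE), "dropping 1")
})

test_that("post hoc adjustments match closed forms and dominance relations", {
  expect_equal(posthoc_adjust(0.03, "sidak"), 0.03)
  expect_equal(posthoc_adjust(0.03, "holm_sidak"), 0.03)
  expect_equal(posthoc_adjust(0.03, "bonferroni_dunn"), 0.03)

  p <- c(0.01, 0.2, 0.04, 0.8, 0.001, 0.5)
  expect_equal(posthoc_adjust(p, "sidak")[1], 1 - 0.99^6, tolerance = 1e-12)
  expect_equal(posthoc_adjust(p, "bonferroni_dunn"), pmin(1, 6 * p))

  hs <- posthoc_adjust(p, "holm_sidak")
  sk <- posthoc_adjust(p, "sidak")
  expect_true(all(hs <= sk + 1e-12))
  expect_true(all(hs >= p))
  expect_true(all(sk >= p))
  # monotone in the raw p-values
  expect_true(all(diff(hs[order(p)]) >= 0))

  expect_error(posthoc_adjust(c(0.1, 1.2)), "in \\[0, 1\\]")
})

test_that("the t test holds its nominal type-I error", {
  set.seed(151)
  n_rep <- 2000
  rej <- mean(vapply(seq_len(n_rep), function(i) {
    group_t_test(rnorm(8), rnorm(8))$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})
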