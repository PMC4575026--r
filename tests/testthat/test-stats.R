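# independent one-way ANOVA oracle: plain sums of squares
anova_oracle <- function(values, groups) {
  g <- split(values, groups)
  grand <- mean(values)
  ss_between <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ss_within <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  df1 <- length(g) - 1
  df2 <- length(values) - length(g)
  F <- (ss_between / df1) / (ss_within / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

cohort_frame <- function(values, groups, measurement = "m") {
  data.frame(animal = paste0("a", seq_along(values)), group = groups,
             measurement = measurement, value = values)
}

test_that("ANOVA F matches hand computation and the SS oracle", {
  tab <- cohort_frame(c(1, 2, 3, 2, 3, 4), rep(c("g1", "g2"), each = 3))
  res <- anova_tukey(tab, "m")
  expect_equal(res$F, 1.5)
  expect_equal(unname(res$df), c(1, 4))

  set.seed(41)
  for (i in 1:25) {
    ng <- sample(2:4, 1)
    sizes <- sample(2:8, ng, replace = TRUE)
    groups <- rep(paste0("g", seq_len(ng)), sizes)
    values <- rnorm(length(groups), mean = rep(rnorm(ng, 0, 2), sizes))
    res <- anova_tukey(cohort_frame(values, groups), "m")
    oracle <- anova_oracle(values, groups)
    expect_equal(res$F, oracle$F, tolerance = 1e-10)
    expect_equal(res$p_anova, oracle$p, tolerance = 1e-10)
  }
})

test_that("identical constant groups are flagged degenerate", {
  tab <- cohort_frame(rep(5, 6), rep(c("a", "b"), each = 3))
  res <- anova_tukey(tab, "m")
  expect_true(res$degenerate)
  expect_true(all(res$pairwise$diff == 0))
})

test_that("Tukey flags only the separated group", {
  tab <- cohort_frame(c(1, 2, 3, 2, 3, 4, 10, 11, 12),
                      rep(c("A", "B", "C"), each = 3))
  res <- anova_tukey(tab, "m")
  pw <- res$pairwise
  involves_c <- pw$group_a == "C" | pw$group_b == "C"
  expect_true(all(pw$significant[involves_c]))
  expect_false(any(pw$significant[!involves_c]))

  # brute-force studentized-range check of the adjusted p values
  mse <- 1  # within-group variance of each triplet is 1
  for (i in seq_len(nrow(pw))) {
    se <- sqrt(mse / 2 * (1 / 3 + 1 / 3))
    q_obs <- abs(pw$diff[i]) / se
    p_manual <- ptukey(q_obs, nmeans = 3, df = 6, lower.tail = FALSE)
    expect_equal(pw$p_adj[i], p_manual, tolerance = 1e-8)
  }
})

test_that("Tukey results are invariant under group relabeling", {
  set.seed(43)
  values <- rnorm(18, rep(c(0, 1, 3), each = 6))
  tab1 <- cohort_frame(values, rep(c("A", "B", "C"), each = 6))
  tab2 <- cohort_frame(values, rep(c("zeta", "eta", "theta"), each = 6))
  r1 <- anova_tukey(tab1, "m")
  r2 <- anova_tukey(tab2, "m")
  expect_equal(sort(r1$pairwise$p_adj), sort(r2$pairwise$p_adj),
               tolerance = 1e-12)
})

test_that("adjusted p decreases as the mean difference grows", {
  set.seed(47)
  noise <- rnorm(12)
  p_at_shift <- vapply(c(0.5, 1.5, 3, 6), function(shift) {
    v <- noise + rep(c(0, shift), each = 6)
    anova_tukey(cohort_frame(v, rep(c("a", "b"), each = 6)), "m")$pairwise$p_adj
  }, 1)
  expect_true(all(diff(p_at_shift) < 0))
})

test_that("undersized groups raise an error naming the group", {
  tab <- cohort_frame(c(1, 2, 3, 9), c("a", "a", "a", "tiny"))
  expect_error(anova_tukey(tab, "m"), "tiny")
  expect_error(anova_tukey(tab, "absent"), "no rows")
})

test_that("delta-delta-Ct fold changes follow 2^(-ddCt)", {
  expect_equal(as.numeric(ddct_fold_change(25, 20, 24, 20)), 0.5)
  expect_equal(as.numeric(ddct_fold_change(22, 20, 24, 20)), 4)
  expect_equal(as.numeric(ddct_fold_change(24, 20, 24, 20)), 1)
  # self-calibration for arbitrary Ct pairs
  set.seed(53)
  for (i in 1:20) {
    a <- runif(1, 5, 35); b <- runif(1, 5, 35)
    expect_equal(as.numeric(ddct_fold_change(a, b, a, b)), 1)
  }
  # technical replicates averaged before differencing
  expect_equal(as.numeric(ddct_fold_change(c(24, 26), 20, 24, 20)), 0.5)
  expect_error(ddct_fold_change(NA, 20, 24, 20), "finite")
})

test_that("Mac-1 field averaging", {
  expect_equal(mac1_average(c(18, 20, 20)), 19.333, tolerance = 1e-3)
  expect_equal(mac1_average(c(0, 0, 0)), 0)
  expect_equal(mac1_average(c(4, 4, 4)), 4)
  expect_error(mac1_average(numeric(0)), "empty")
  expect_error(mac1_average(c(1, 2)), "expected 3")
  expect_equal(mac1_average(c(1, 2), n_required = NULL), 1.5)
  expect_error(mac1_average(c(-1, 2, 3)), ">= 0")
})
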