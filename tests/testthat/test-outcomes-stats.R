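toy_pe <- function() {
  tibble::tibble(
    eye_id = rep(sprintf("e%d", 1:3), times = 2),
    source = rep(c("K", "TK"), each = 3),
    pe = c(0.3, -0.6, 0.1, 0, 0, 0)
  )
}

test_that("prediction-error summaries report paired group statistics", {
  out <- summarize_pe(toy_pe())
  k <- out[out$source == "K", ]
  expect_equal(k$n, 3)
  expect_equal(k$mean_pe, mean(c(0.3, -0.6, 0.1)))
  expect_equal(k$sd_pe, sd(c(0.3, -0.6, 0.1)))
  expect_equal(k$pct_within_0.5D, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(k$pct_within_1.0D, 100)
  tk <- out[out$source == "TK", ]
  expect_equal(c(tk$mean_pe, tk$sd_pe, tk$pct_within_0.5D), c(0, 0, 100))

  # percentages reproduce cumulative_within on the same input
  cw <- cumulative_within(c(0.3, -0.6, 0.1), c(0.5, 1))
  expect_equal(unname(unlist(k[, c("pct_within_0.5D", "pct_within_1.0D")])),
               cw$pct_within)

  # unpaired designs are rejected with the cell named
  expect_error(summarize_pe(toy_pe()[-1, ]), "e1.*K")
})

test_that("one-way ANOVA agrees with brute-force sums of squares", {
  d <- tibble::tibble(
    y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
    g = rep(c("a", "b", "c"), each = 3)
  )
  out <- one_way_anova(d, y, g)
  # brute force decomposition
  means <- tapply(d$y, d$g, mean)
  ssb <- sum(3 * (means - mean(d$y))^2)
  ssw <- sum((d$y - means[d$g])^2)
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(out$statistic, f_oracle, tolerance = 1e-12)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 6)
  expect_equal(out$p_value, pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups give F = 0, p = 1
  same <- tibble::tibble(y = rep(c(1, 2, 5), 3), g = rep(c("a", "b", "c"), each = 3))
  out <- one_way_anova(same, y, g)
  expect_equal(out$statistic, 0, tolerance = 1e-12)
  expect_equal(out$p_value, 1)

  # two groups: F equals the squared pooled-variance t statistic
  set.seed(71)
  d2 <- tibble::tibble(y = rnorm(16), g = rep(c("a", "b"), each = 8))
  tt <- t.test(y ~ g, data = d2, var.equal = TRUE)
  expect_equal(one_way_anova(d2, y, g)$statistic, unname(tt$statistic^2),
               tolerance = 1e-10)

  expect_error(one_way_anova(d2[1:9, ], y, g), "at least two")
})

test_that("Tukey HSD reports mean differences with adjusted p-values", {
  set.seed(72)
  d <- tibble::tibble(y = rnorm(30, rep(c(0, 0.5, 1), each = 10)),
                      g = rep(c("a", "b", "c"), each = 10))
  out <- tukey_hsd(d, y, g)
  expect_equal(nrow(out), 3)
  means <- tapply(d$y, d$g, mean)
  i <- which(out$group1 == "b" & out$group2 == "a")
  expect_equal(out$difference[i], unname(means["b"] - means["a"]),
               tolerance = 1e-12)

  # adjusted p >= unadjusted pairwise p
  raw <- stats::pairwise.t.test(d$y, d$g, p.adjust.method = "none")$p.value
  expect_gte(out$p_adj[i], raw["b", "a"] - 1e-12)

  # identical groups: all adjusted p = 1
  same <- tibble::tibble(y = rep(c(1, 2, 3), 3),
                         g = rep(c("a", "b", "c"), each = 3))
  expect_true(all(tukey_hsd(same, y, g)$p_adj > 1 - 1e-9))
})

test_that("Cochran's Q matches its closed form and reduces to McNemar", {
  # 4 subjects x 3 conditions, column totals 3/2/1, row totals 2/1/3/0
  x <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
  out <- cochran_q(x)
  expect_equal(out$statistic, 3)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, pchisq(3, 2, lower.tail = FALSE))

  # identical columns carry no signal
  same <- cbind(c(1, 0, 1, 1), c(1, 0, 1, 1))
  expect_equal(cochran_q(same)$statistic, 0)
  expect_equal(cochran_q(same)$p_value, 1)

  # invariant under row and column permutation
  set.seed(73)
  x2 <- matrix(rbinom(60, 1, 0.5), ncol = 3)
  expect_equal(cochran_q(x2)$statistic,
               cochran_q(x2[sample(nrow(x2)), c(3, 1, 2)])$statistic,
               tolerance = 1e-12)

  # k = 2 equals McNemar's chi-square without continuity correction
  y2 <- matrix(rbinom(80, 1, 0.6), ncol = 2)
  mn <- stats::mcnemar.test(table(factor(y2[, 1], 0:1),
                                  factor(y2[, 2], 0:1)), correct = FALSE)
  expect_equal(cochran_q(y2)$statistic, unname(mn$statistic),
               tolerance = 1e-12)

  expect_error(cochran_q(x[, 1, drop = FALSE]), "two condition")
  expect_error(cochran_q(matrix(c(0, 2), 1)), "0/1")
})

test_that("pairwise Cochran follow-up matches the two-condition test", {
  set.seed(74)
  x <- matrix(rbinom(90, 1, c(0.8, 0.8, 0.4)), ncol = 3, byrow = TRUE)
  colnames(x) <- c("K", "TK", "TCRP")
  out <- pairwise_cochran_q(x)
  expect_equal(nrow(out), 3)
  i <- which(out$group1 == "K" & out$group2 == "TCRP")
  expect_equal(out$statistic[i], cochran_q(x[, c(1, 3)])$statistic)
  expect_equal(out$p_value, out$p_adj)   # unadjusted by default
  bonf <- pairwise_cochran_q(x, p_adjust = "bonferroni")
  expect_equal(bonf$p_adj, pmin(1, bonf$p_value * 3))
  # invariant to column order within a pair
  expect_equal(out$statistic[i], cochran_q(x[, c(3, 1)])$statistic)
})

test_that("effect size f matches its ANOVA sums-of-squares definition", {
  expect_equal(cohens_f(c(1, 1, 1), c(0.4, 0.5, 0.6)), 0)
  expect_equal(cohens_f(c(-0.5, 0.5), c(1, 1)), 0.5)

  # oracle: f from raw balanced data via SSB/N and SSW/(N-k)
  set.seed(75)
  k <- 4; n <- 12
  y <- rnorm(k * n, rep(c(0, 0.2, 0.5, 0.9), each = n))
  g <- rep(letters[1:k], each = n)
  means <- tapply(y, g, mean)
  sds <- tapply(y, g, sd)
  ssb <- n * sum((means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  f_oracle <- sqrt(ssb / (k * n)) / sqrt(ssw / (k * n - k))
  expect_equal(cohens_f(means, sds), f_oracle, tolerance = 1e-12)

  expect_error(cohens_f(c(1, 2), c(0, 0)), "undefined")
})

test_that("noncentral-F power behaves like the central case at f = 0 and grows", {
  expect_equal(anova_power(0, 4, 23, 0.05)$power, 0.05, tolerance = 1e-9)
  out <- anova_power(0.57, 4, 23, 0.05)
  expect_equal(out$ncp, 0.57^2 * 4 * 23)
  expect_equal(out$df1, 3)
  expect_equal(out$df2, 88)
  # monotone in f and in n over a grid
  fs <- seq(0, 0.8, by = 0.1)
  expect_true(all(diff(vapply(fs, function(f)
    anova_power(f, 4, 20)$power, numeric(1))) > 0))
  ns <- seq(5, 40, by = 5)
  expect_true(all(diff(vapply(ns, function(n)
    anova_power(0.3, 4, n)$power, numeric(1))) > 0))
  expect_error(anova_power(-0.1, 4, 20), "f >= 0")
})
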