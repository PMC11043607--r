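#' Group-level prediction-error summaries
#'
#' Per keratometry source: `n`, mean and sample SD (denominator `n - 1`) of
#' the prediction error, and the percentage (and count) of eyes within each
#' absolute threshold. Every eye must contribute one prediction error per
#' group (paired design); missing cells abort with the eye and group named.
#'
#' @param data Long per-eye table with one prediction error per eye and
#'   group.
#' @param pe,group,eye Tidy-eval columns holding the prediction error (D),
#'   the group label and the eye identifier; defaults `pe`, `source`,
#'   `eye_id`.
#' @param thresholds Absolute-PE thresholds in dioptres (default 0.5 and
#'   1.0).
#' @return Tibble with one row per group: `n`, `mean_pe`, `sd_pe`, then
#'   `n_within_*` / `pct_within_*` per threshold.
#' @export
summarize_pe <- function(data, pe = pe, group = source, eye = eye_id,
                         thresholds = c(0.5, 1)) {
  counts <- data |>
    dplyr::count(dplyr::pick({{ eye }}), dplyr::pick({{ group }}))
  tab <- tidyr::pivot_wider(counts, names_from = 2, values_from = "n")
  if (anyNA(tab)) {
    i <- which(is.na(tab), arr.ind = TRUE)[1, ]
    abort(sprintf("Eye \"%s\" has no prediction error in group \"%s\".",
                  as.character(tab[[1]][i[1]]), names(tab)[i[2]]))
  }
  base <- data |>
    dplyr::group_by(dplyr::pick({{ group }})) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_pe = mean({{ pe }}),
      sd_pe = sd({{ pe }}),
      .groups = "drop"
    )
  within <- data |>
    dplyr::group_by(dplyr::pick({{ group }})) |>
    dplyr::reframe(cumulative_within({{ pe }}, thresholds)) |>
    tidyr::pivot_wider(
      names_from = "threshold",
      values_from = c("n_within", "pct_within"),
      names_glue = "{.value}_{format(threshold)}D"
    )
  dplyr::left_join(base, within, by = names(base)[1])
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA of a numeric response across
#' groups, fitted with [stats::aov()].
#'
#' @param data Long data frame.
#' @param value,group Tidy-eval columns: numeric response and group label.
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 2, 3, 4), g = rep(c("a", "b"), each = 3))
#' one_way_anova(d, y, g)
#' @export
one_way_anova <- function(data, value, group) {
  d <- prepare_groups(data, {{ value }}, {{ group }})
  fit <- aov(y ~ g, data = d)
  tab <- summary(fit)[[1]]
  tibble(
    statistic = tab[["F value"]][1],
    df1 = tab[["Df"]][1],
    df2 = tab[["Df"]][2],
    p_value = tab[["Pr(>F)"]][1]
  )
}

#' Tukey honest significant differences
#'
#' All pairwise group comparisons after a one-way ANOVA, with
#' studentized-range adjusted p-values, via [stats::TukeyHSD()].
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level of the intervals.
#' @return Tibble with one row per pair: `group1`, `group2`, `difference`
#'   (mean of `group1` minus mean of `group2`), `conf_low`, `conf_high`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(data, value, group, conf_level = 0.95) {
  d <- prepare_groups(data, {{ value }}, {{ group }})
  fit <- aov(y ~ g, data = d)
  th <- TukeyHSD(fit, conf.level = conf_level)$g
  pair <- strsplit(rownames(th), "-", fixed = TRUE)
  tibble(
    group1 = vapply(pair, `[`, "", 1),
    group2 = vapply(pair, `[`, "", 2),
    difference = unname(th[, "diff"]),
    conf_low = unname(th[, "lwr"]),
    conf_high = unname(th[, "upr"]),
    p_adj = unname(th[, "p adj"])
  )
}

#' Cochran's Q test for paired binary outcomes
#'
#' Tests whether the success proportion differs across `k` paired conditions
#' (e.g. "within 0.5 D" indicators per keratometry source on the same eyes).
#' With column totals `C_j`, row totals `R_i` and grand total `N`,
#' \deqn{Q = (k - 1)\,\frac{k \sum_j C_j^2 - N^2}{k N - \sum_i R_i^2},}
#' referred to a chi-square distribution with `k - 1` degrees of freedom.
#' Rows with all-equal outcomes contribute nothing; if every row is
#' all-equal the table carries no information and `Q = 0`, `p = 1` is
#' returned. For `k = 2` the statistic equals McNemar's chi-square without
#' continuity correction.
#'
#' @param data Data frame or matrix of 0/1 values, one row per subject and
#'   one column per condition (complete cases only).
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' x <- rbind(c(1, 1, 0), c(1, 0, 0), c(1, 1, 1), c(0, 0, 0))
#' cochran_q(x)   # Q = 3
#' @export
cochran_q <- function(data) {
  x <- as.matrix(data)
  if (!nrow(x) || ncol(x) < 2) {
    abort("`data` needs at least one row and two condition columns.")
  }
  if (anyNA(x)) abort("`data` must be complete (no missing cells).")
  if (!all(x %in% c(0, 1))) abort("`data` must contain only 0/1 values.")
  k <- ncol(x)
  col_tot <- colSums(x)
  row_tot <- rowSums(x)
  n_tot <- sum(x)
  denom <- k * n_tot - sum(row_tot^2)
  q <- if (denom == 0) 0 else (k - 1) * (k * sum(col_tot^2) - n_tot^2) / denom
  tibble(
    statistic = q,
    df = k - 1,
    p_value = pchisq(q, df = k - 1, lower.tail = FALSE)
  )
}

#' Pairwise Cochran's Q follow-up
#'
#' [cochran_q()] applied to every pair of condition columns. P-values are
#' unadjusted by default; `p_adjust = "bonferroni"` (or any
#' [stats::p.adjust()] method) is available.
#'
#' @inheritParams cochran_q
#' @param p_adjust Multiplicity adjustment method (default `"none"`).
#' @return Tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `df`, `p_value`, `p_adj`.
#' @export
pairwise_cochran_q <- function(data, p_adjust = "none") {
  x <- as.matrix(data)
  if (ncol(x) < 2) abort("`data` needs at least two condition columns.")
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(x)))
  pairs <- combn(seq_len(ncol(x)), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    dplyr::bind_cols(
      tibble(group1 = labels[i1], group2 = labels[i2]),
      cochran_q(x[, c(i1, i2), drop = FALSE])
    )
  })
  res$p_adj <- stats::p.adjust(res$p_value, method = p_adjust)
  res
}

#' Cohen's effect size f from group summaries
#'
#' `f = sigma_means / sigma_within`, with the between-group SD in population
#' form (denominator `k`, the G*Power convention) and the within-group SD
#' pooled as the root mean square of the group SDs (equal group sizes
#' assumed).
#'
#' @param means Numeric vector of group means.
#' @param sds Numeric vector of group SDs (same length).
#' @return Effect size f (scalar).
#' @examples
#' cohens_f(c(-0.5, 0.5), c(1, 1))   # 0.5
#' @export
cohens_f <- function(means, sds) {
  check_finite(means = means, sds = sds)
  if (length(means) != length(sds) || length(means) < 2) {
    abort("`means` and `sds` must be equal-length vectors of 2+ groups.")
  }
  pooled <- sqrt(mean(sds^2))
  if (pooled == 0) abort("Zero pooled within-group SD; f is undefined.")
  sqrt(mean((means - mean(means))^2)) / pooled
}

#' Power of a balanced one-way ANOVA (noncentral F)
#'
#' Power of the level-`alpha` F test for `k` groups of `n` observations at
#' effect size f: noncentrality \eqn{\lambda = f^2 k n}, numerator df
#' `k - 1`, denominator df `k (n - 1)`, and
#' \eqn{power = P(F'(df_1, df_2, \lambda) > F_{crit})}. Monotone increasing
#' in both `f` and `n`; at `f = 0` the power equals `alpha`.
#'
#' @param f Cohen's effect size f (>= 0).
#' @param k Number of groups (>= 2).
#' @param n Observations per group (>= 2).
#' @param alpha Type-I error level, in (0, 1).
#' @return One-row tibble: `f`, `k`, `n`, `alpha`, `ncp`, `df1`, `df2`,
#'   `f_crit`, `power`.
#' @examples
#' anova_power(0.57, 4, 23)$power   # about 0.999
#' @export
anova_power <- function(f, k, n, alpha = 0.05) {
  check_finite(f = f, k = k, n = n, alpha = alpha)
  if (f < 0 || k < 2 || n < 2 || alpha <= 0 || alpha >= 1) {
    abort("Need f >= 0, k >= 2, n >= 2 and alpha in (0, 1).")
  }
  df1 <- k - 1
  df2 <- k * (n - 1)
  ncp <- f^2 * k * n
  f_crit <- qf(1 - alpha, df1, df2)
  tibble(
    f = f, k = k, n = n, alpha = alpha, ncp = ncp, df1 = df1, df2 = df2,
    f_crit = f_crit,
    power = pf(f_crit, df1, df2, ncp = ncp, lower.tail = FALSE)
  )
}

## ---- internal -------------------------------------------------------------

prepare_groups <- function(data, value, group) {
  d <- tibble(
    y = dplyr::pull(data, {{ value }}),
    g = factor(dplyr::pull(data, {{ group }}))
  )
  sizes <- table(d$g)
  if (length(sizes) < 2 || any(sizes < 2)) {
    abort("Need at least two groups with at least two observations each.")
  }
  check_finite(value = d$y)
  d
}
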