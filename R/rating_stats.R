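#' Per-method rating summaries
#'
#' Mean and sample standard deviation (n-1 denominator) of the Likert
#' grades per registration method, over all (dataset x rater) records.
#'
#' @param ratings A [rating_table()], or any data.frame with `method` and
#'   `grade` columns (validated grades are only guaranteed for the former).
#' @return A `data.frame` with columns `method`, `n`, `mean_grade`,
#'   `sd_grade`, ordered by increasing mean (best method first).
#' @export
summarize_methods <- function(ratings) {
  ratings <- as_rating_df(ratings, c("method", "grade"))
  if (!nrow(ratings)) stopf("empty rating table")
  sp <- split(ratings$grade, ratings$method)
  out <- data.frame(method = names(sp),
                    n = vapply(sp, length, 1L),
                    mean_grade = vapply(sp, mean, 1),
                    sd_grade = vapply(sp, sd, 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$mean_grade), , drop = FALSE]
}

#' Insufficient-registration rate for one method
#'
#' Counts ratings at the insufficient end of the scale (grade >= `cutoff`;
#' default 5, so 5, 5.5 and 6 — "no alignment / non-convergence" territory)
#' and expresses them as a percentage of all ratings of that method across
#' raters.
#'
#' @param ratings A [rating_table()].
#' @param method Method label (one of `3P`, `TIE`, `EL`, `ANTS`).
#' @param cutoff Lowest grade counted as insufficient (default 5; half-steps
#'   above the cutoff are included).
#' @return A list with `count`, `total` and `percent`.
#' @export
insufficiency_rate <- function(ratings, method, cutoff = 5) {
  ratings <- as_rating_df(ratings, c("method", "grade"))
  method <- toupper(method)
  g <- ratings$grade[ratings$method == method]
  if (!length(g)) stopf("no ratings for method %s", method)
  count <- sum(g >= cutoff)
  list(count = count, total = length(g),
       percent = 100 * count / length(g))
}

#' One-way ANOVA over methods with Bonferroni post-hoc comparisons
#'
#' Fixed-effects one-way ANOVA of grade by registration method, followed by
#' all pairwise comparisons. Effect sizes are Cohen's d computed against the
#' ANOVA-pooled standard deviation (the square root of the within-group
#' mean square, which for equal group sizes is the root of the average
#' group variance); p-values are Bonferroni-multiplied by the number of
#' pairwise comparisons and capped at 1.
#'
#' Observations default to per-dataset mean grades across raters
#' (`pool = "dataset_mean"`), one observation per (dataset, method);
#' `pool = "all"` instead treats every single rating as an observation.
#'
#' @param ratings A [rating_table()].
#' @param pool `"dataset_mean"` (default) or `"all"`.
#' @return A list of class `anova_posthoc`: `F`, `df_between`, `df_within`,
#'   `p`, `pooled_sd`, and `comparisons` (a `data.frame` with one row per
#'   method pair: `mean_difference`, `cohens_d`, `t`, `p_bonferroni`,
#'   `n_comparisons`).
#' @export
anova_posthoc <- function(ratings, pool = c("dataset_mean", "all")) {
  ratings <- as_rating_df(ratings, c("dataset_id", "method", "grade"))
  pool <- match.arg(pool)
  df <- if (pool == "dataset_mean") {
    agg <- aggregate(grade ~ dataset_id + method, data = as.data.frame(ratings),
                     FUN = mean)
    agg
  } else {
    as.data.frame(ratings)[, c("dataset_id", "method", "grade")]
  }
  counts <- table(df$method)
  if (length(counts) < 2L) stopf("ANOVA needs at least 2 methods")
  if (any(counts < 2L)) {
    stopf("method(s) with fewer than 2 observations: %s",
          paste(names(counts)[counts < 2], collapse = ", "))
  }
  df$method <- factor(df$method)
  fit <- aov(grade ~ method, data = df)
  tab <- summary(fit)[[1]]
  F_stat <- tab[["F value"]][1]
  df_between <- tab[["Df"]][1]
  df_within <- tab[["Df"]][2]
  p_overall <- tab[["Pr(>F)"]][1]
  ms_within <- tab[["Mean Sq"]][2]
  pooled_sd <- sqrt(ms_within)

  means <- tapply(df$grade, df$method, mean)
  ns <- tapply(df$grade, df$method, length)
  pairs <- combn(names(means), 2)
  n_comp <- ncol(pairs)
  comparisons <- do.call(rbind, lapply(seq_len(n_comp), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diff <- means[[a]] - means[[b]]
    se <- pooled_sd * sqrt(1 / ns[[a]] + 1 / ns[[b]])
    t_stat <- if (se > 0) diff / se else 0
    p_raw <- if (se > 0) 2 * pt(-abs(t_stat), df_within) else 1
    data.frame(method_a = a, method_b = b,
               mean_difference = diff,
               cohens_d = if (pooled_sd > 0) diff / pooled_sd else 0,
               t = t_stat,
               p_bonferroni = min(1, p_raw * n_comp),
               n_comparisons = n_comp,
               stringsAsFactors = FALSE)
  }))
  structure(list(F = F_stat, df_between = df_between, df_within = df_within,
                 p = p_overall, pooled_sd = pooled_sd,
                 comparisons = comparisons, pool = pool),
            class = "anova_posthoc")
}

#' @export
print.anova_posthoc <- function(x, ...) {
  cat(sprintf("<anova_posthoc> F(%d, %d) = %.2f, p = %.3g (pooled SD %.4f, %s)\n",
              x$df_between, x$df_within, x$F, x$p, x$pooled_sd, x$pool))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test with Satterthwaite degrees of freedom, used for
#' dichotomous grouping variables (e.g. participant sex).
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2 with finite
#'   variance).
#' @return A list with `t`, `df` and `p`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stopf("each group needs at least 2 values")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) return(list(t = 0, df = Inf, p = 1))
    stopf("both groups have zero variance; Welch's t is undefined")
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pairwise inter-rater agreement
#'
#' For every pair of raters, Spearman's rho (average ranks for ties) and
#' Kendall's tau-b (tie-corrected) over the (dataset, method) items both
#' raters graded, with the usual asymptotic p-values. Spearman is the
#' primary measure here because raters may grade around different personal
#' baselines, which rank correlation ignores; tau-b adds sensitivity to the
#' heavy ties of a 6-point scale.
#'
#' @param ratings A [rating_table()].
#' @param min_overlap Minimum number of common items per pair (default 3).
#' @return A `data.frame` with one row per rater pair: `rater_a`,
#'   `rater_b`, `n_items`, `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p`.
#' @export
interrater_agreement <- function(ratings, min_overlap = 3L) {
  ratings <- as_rating_df(ratings, c("dataset_id", "method", "rater_id", "grade"))
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) < 2L) stopf("need at least 2 raters")
  key <- paste(ratings$dataset_id, ratings$method, sep = "\r")
  pairs <- combn(raters, 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ka <- key[ratings$rater_id == a]; ga <- ratings$grade[ratings$rater_id == a]
    kb <- key[ratings$rater_id == b]; gb <- ratings$grade[ratings$rater_id == b]
    common <- intersect(ka, kb)
    if (length(common) < min_overlap) {
      stopf("raters %s and %s share only %d item(s); need >= %d",
            a, b, length(common), min_overlap)
    }
    va <- ga[match(common, ka)]
    vb <- gb[match(common, kb)]
    rho <- cor(rank(va), rank(vb))
    tau <- cor(va, vb, method = "kendall")
    sp_p <- suppressWarnings(cor.test(va, vb, method = "spearman",
                                      exact = FALSE)$p.value)
    kd_p <- suppressWarnings(cor.test(va, vb, method = "kendall",
                                      exact = FALSE)$p.value)
    data.frame(rater_a = a, rater_b = b, n_items = length(common),
               spearman_rho = rho, spearman_p = sp_p,
               kendall_tau = tau, kendall_p = kd_p,
               stringsAsFactors = FALSE)
  }))
  out
}
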