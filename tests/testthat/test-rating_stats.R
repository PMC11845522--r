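# rating table with the given per-method grade vectors, single rater
ratings_from_grades <- function(grades_by_method, rater = "R1") {
  do.call(rbind, lapply(names(grades_by_method), function(m) {
    g <- grades_by_method[[m]]
    data.frame(dataset_id = sprintf("d%03d", seq_along(g)), method = m,
               rater_id = rater, grade = g, stringsAsFactors = FALSE)
  }))
}

# numeric vector with exactly the requested mean and SD
with_moments <- function(n, mean, sd) {
  z <- seq_len(n)
  mean + sd * (z - mean(z)) / sd(z)
}

test_that("method summaries report sample moments", {
  tab <- rating_table(dataset_id = c("a", "b", "c", "a", "b"),
                      method = c("TIE", "TIE", "TIE", "3P", "3P"),
                      rater_id = "R1",
                      grade = c(2, 2, 2, 1, 3))
  s <- summarize_methods(tab)
  tie <- s[s$method == "TIE", ]
  expect_equal(tie$mean_grade, 2)
  expect_equal(tie$sd_grade, 0)
  p3 <- s[s$method == "3P", ]
  expect_equal(p3$mean_grade, 2)
  expect_equal(p3$sd_grade, sqrt(2))

  # constructed moments are reproduced
  tab2 <- ratings_from_grades(list(TIE = with_moments(153, 2.21, 1.15)))
  s2 <- summarize_methods(tab2)
  expect_equal(s2$mean_grade, 2.21, tolerance = 1e-12)
  expect_equal(s2$sd_grade, 1.15, tolerance = 1e-12)
})

test_that("insufficiency counts grades at 5 and above including half-steps", {
  g <- c(rep(2, 10), 5, 5.5, 6)
  tab <- ratings_from_grades(list(EL = g))
  r <- insufficiency_rate(tab, "EL")
  expect_equal(r$count, 3)
  expect_equal(r$percent, 100 * 3 / 13)

  expect_equal(insufficiency_rate(ratings_from_grades(list(EL = rep(2, 5))),
                                  "EL")$percent, 0)
  expect_equal(insufficiency_rate(ratings_from_grades(list(EL = rep(6, 5))),
                                  "EL")$percent, 100)

  # count is monotone non-decreasing as the cutoff is lowered
  counts <- sapply(seq(6, 1, by = -0.5), function(cut) {
    insufficiency_rate(tab, "EL", cutoff = cut)$count
  })
  expect_true(all(diff(counts) >= 0))
  expect_true(all(sapply(seq(1, 6, 0.5), function(cut) {
    p <- insufficiency_rate(tab, "EL", cutoff = cut)$percent
    p >= 0 && p <= 100
  })))
})

test_that("ANOVA and pooled-SD effect sizes follow the stated conventions", {
  # identical groups: F = 0, all d = 0
  g <- with_moments(20, 3, 1)
  tab0 <- ratings_from_grades(list(TIE = g, `3P` = g, EL = g, ANTS = g))
  a0 <- anova_posthoc(tab0)
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_true(all(abs(a0$comparisons$cohens_d) < 1e-12))
  expect_true(all(a0$comparisons$p_bonferroni == 1))

  # two groups, means 0 and 1, both SD 1, equal n: d = 1
  tab1 <- ratings_from_grades(list(TIE = with_moments(30, 0, 1),
                                   ANTS = with_moments(30, 1, 1)))
  a1 <- anova_posthoc(tab1)
  cmp <- a1$comparisons
  expect_equal(abs(cmp$cohens_d), 1, tolerance = 1e-9)
  expect_equal(a1$df_between, 1)
  expect_equal(a1$df_within, 58)

  # F is exactly invariant to shifting and scaling of the grades
  tab2 <- ratings_from_grades(list(TIE = with_moments(25, 2.2, 1.1),
                                   EL = with_moments(25, 3.4, 1.0),
                                   ANTS = with_moments(25, 3.5, 1.3)))
  f_base <- anova_posthoc(tab2)$F
  tab_shift <- tab2; tab_shift$grade <- tab_shift$grade + 7
  tab_scale <- tab2; tab_scale$grade <- tab_scale$grade * 3.5
  expect_equal(anova_posthoc(tab_shift)$F, f_base, tolerance = 1e-9)
  expect_equal(anova_posthoc(tab_scale)$F, f_base, tolerance = 1e-9)

  # Bonferroni p >= raw p, capped at 1
  expect_true(all(a1$comparisons$p_bonferroni <=
                    pmin(1, a1$comparisons$n_comparisons)))
  expect_error(anova_posthoc(ratings_from_grades(list(TIE = c(2, 3)))),
               "2 methods")
})

test_that("Welch's t matches its closed form", {
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1))
  w <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(w$t), 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4, tolerance = 1e-12)

  set.seed(8)
  big <- welch_t(rnorm(1e4, 0, 1), rnorm(1e4, 1, 1))
  expect_lt(big$p, 1e-10)
  expect_error(welch_t(c(1), c(1, 2)), "at least 2")
})

test_that("inter-rater agreement reports rho and tie-corrected tau-b", {
  items <- expand.grid(dataset_id = sprintf("d%02d", 1:8),
                       method = c("TIE", "EL"), stringsAsFactors = FALSE)
  set.seed(9)
  g1 <- sample(seq(1, 6, 0.5), nrow(items), replace = TRUE)
  tab_same <- rbind(
    data.frame(items, rater_id = "A", grade = g1),
    data.frame(items, rater_id = "B", grade = g1))
  agree <- interrater_agreement(rating_table(tab_same$dataset_id,
                                             tab_same$method,
                                             tab_same$rater_id,
                                             tab_same$grade))
  expect_equal(agree$spearman_rho, 1)
  expect_equal(agree$kendall_tau, 1)

  tab_rev <- rbind(
    data.frame(items, rater_id = "A", grade = g1),
    data.frame(items, rater_id = "B", grade = 7 - g1))
  rev <- interrater_agreement(rating_table(tab_rev$dataset_id,
                                           tab_rev$method,
                                           tab_rev$rater_id, tab_rev$grade))
  expect_equal(rev$spearman_rho, -1)
  expect_equal(rev$kendall_tau, -1)

  # tau-b against the O(n^2) concordant/discordant oracle, tied data
  va <- c(1, 2, 2, 3); vb <- c(1, 3, 2, 4)
  small <- rbind(
    data.frame(dataset_id = sprintf("d%d", 1:4), method = "TIE",
               rater_id = "A", grade = va),
    data.frame(dataset_id = sprintf("d%d", 1:4), method = "TIE",
               rater_id = "B", grade = vb))
  ag <- interrater_agreement(rating_table(small$dataset_id, small$method,
                                          small$rater_id, small$grade))
  expect_equal(ag$kendall_tau, oracle_tau_b(va, vb), tolerance = 1e-12)

  for (s in 1:3) {
    set.seed(s + 40)
    ga <- sample(seq(1, 6, 0.5), 12, replace = TRUE)
    gb <- sample(seq(1, 6, 0.5), 12, replace = TRUE)
    two <- rbind(
      data.frame(dataset_id = sprintf("d%02d", 1:12), method = "EL",
                 rater_id = "A", grade = ga),
      data.frame(dataset_id = sprintf("d%02d", 1:12), method = "EL",
                 rater_id = "B", grade = gb))
    ag2 <- interrater_agreement(rating_table(two$dataset_id, two$method,
                                             two$rater_id, two$grade))
    expect_equal(ag2$kendall_tau, oracle_tau_b(ga, gb), tolerance = 1e-12)
    expect_equal(ag2$spearman_rho, cor(rank(ga), rank(gb)), tolerance = 1e-12)
  }
})
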