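test_that("JZS Bayes factors reproduce published values from (t, n)", {
  # paired, n = 21: BF10 printed 26.960
  expect_equal(jzs_bf10(3.705, 20, 21), 26.960, tolerance = 0.01)
  # paired, n = 12: BF10 printed 0.866
  expect_equal(jzs_bf10(1.685, 11, 12), 0.866, tolerance = 0.01)
  # independent, 12 vs 15: BF10 printed 2.545
  expect_equal(jzs_bf10(2.364, 25, 12 * 15 / 27), 2.545, tolerance = 0.01)
})

test_that("quadrature agrees with Monte-Carlo integration of the prior", {
  # independent oracle: average the noncentral-t density over Cauchy draws
  mc_bf10 <- function(t, df, n_eff, r = 0.707, draws = 2e5, seed = 99) {
    set.seed(seed)
    delta <- stats::rcauchy(draws, 0, r)
    dens <- suppressWarnings(dt(t, df, ncp = delta * sqrt(n_eff)))
    list(bf = mean(dens) / dt(t, df),
         se = sd(dens / dt(t, df)) / sqrt(draws))
  }
  for (t in c(0, 1.5, 3, 6)) {
    for (n in c(5, 12, 21, 50)) {
      mc <- mc_bf10(t, n - 1, n)
      q <- jzs_bf10(t, n - 1, n)
      expect_lt(abs(q - mc$bf), 3 * mc$se)
    }
  }
  # t = 0 favours the null
  expect_lt(jzs_bf10(0, 11, 12), 1)
})

test_that("BF10 is symmetric and increasing in |t|", {
  ts <- seq(0, 6, by = 0.5)
  bf <- vapply(ts, function(t) jzs_bf10(t, 11, 12), numeric(1))
  expect_true(all(diff(bf) > 0))
  expect_equal(jzs_bf10(-2.5, 11, 12), jzs_bf10(2.5, 11, 12), tolerance = 1e-8)
  expect_lt(bf[1], 1)
})

test_that("Cohen's d formulas match published effect sizes", {
  expect_equal(cohens_d_paired(3.705, 21), 0.808, tolerance = 1e-3)
  expect_equal(cohens_d_paired(1.685, 12), 0.486, tolerance = 1e-3)
  expect_equal(cohens_d_independent(2.364, 12, 15), 0.916, tolerance = 1e-3)
  expect_equal(cohens_d_independent(1.335, 12, 15), 0.517, tolerance = 1e-3)
  expect_equal(cohens_d_paired(0, 10), 0)
  expect_equal(cohens_d_independent(0, 5, 5), 0)
})

test_that("t-tests match direct formulas and flag degenerate input", {
  spec <- synthetic_ratings_spec(n_subjects = 12, dimensions = "patterns",
                                 delta = 1.2, seed = 31)
  tab <- generate_synthetic_ratings(spec)
  x <- tab$rating[tab$condition == "B"]
  y <- tab$rating[tab$condition == "A"]
  res <- paired_ttest(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
  expect_equal(res$df, 11)
  expect_equal(res$cohens_d, mean(d) / sd(d), tolerance = 1e-12)  # d = t/sqrt(n)
  expect_equal(res$p_two_tailed, 2 * pt(-abs(res$t), 11), tolerance = 1e-12)

  ind <- independent_ttest(x, y)
  sp <- sqrt((11 * var(x) + 11 * var(y)) / 22)
  expect_equal(ind$t, (mean(x) - mean(y)) / (sp * sqrt(1 / 12 + 1 / 12)),
               tolerance = 1e-12)
  expect_equal(ind$df, 22)

  expect_error(paired_ttest(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("identical paired samples cannot support a difference", {
  x <- c(10, 20, 30, 25, 15)
  expect_error(paired_ttest(x, x), "zero variance")
  # near-identical: t ~ 0, BF < 1
  res <- paired_ttest(x, x + c(1e-6, -1e-6, 1e-6, -1e-6, 1e-6))
  expect_lt(abs(res$t), 1)
  expect_lt(res$bf10, 1)
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.3, 5), 1.0)
  expect_equal(bonferroni(0.3, 5, cap = FALSE), 1.5)
  expect_equal(bonferroni(c(0.001, 0.2), 17), c(0.017, 1))
  expect_error(bonferroni(1.2, 3), "\\[0, 1\\]")
})

test_that("Bayes-factor interpretation uses the 3 and 1/3 thresholds", {
  expect_equal(interpret_bf(28.09), "supports_H1")
  expect_equal(interpret_bf(0.194), "supports_H0")
  expect_equal(interpret_bf(1.0), "insensitive")
  expect_equal(interpret_bf(c(3, 1 / 3)), c("insensitive", "insensitive"))
  expect_error(interpret_bf(0), "positive")
})

test_that("repeated-measures ANOVA matches stats::aov and conserves SS", {
  tab <- generate_synthetic_timing(synthetic_timing_spec(
    n_subjects = 10, weber = 0.2, bias = 0.1, video_effect = 0.05, seed = 17))
  res <- rm_anova_2way(tab)
  ss <- attr(res, "ss")
  expect_lt(abs(sum(ss[1:7]) - ss["total"]) / ss["total"], 1e-10)

  cells <- aggregate(produced_s ~ subject + target_s + video_type, tab, mean)
  cells <- data.frame(s = factor(cells$subject), a = factor(cells$target_s),
                      b = factor(cells$video_type), y = cells$produced_s)
  oracle <- ss_oracle(cells)
  for (k in names(oracle)) {
    expect_lt(abs(ss[[k]] - oracle[[k]]) / max(oracle[["total"]], 1), 1e-10)
  }

  fit <- summary(aov(y ~ a * b + Error(s / (a * b)), data = cells))
  f_aov <- c(fit[["Error: s:a"]][[1]]$`F value`[1],
             fit[["Error: s:b"]][[1]]$`F value`[1],
             fit[["Error: s:a:b"]][[1]]$`F value`[1])
  expect_equal(res$F, f_aov, tolerance = 1e-8)

  # exchangeability: permuting subject labels leaves F unchanged
  tab2 <- tab
  perm <- sample(unique(tab$subject))
  tab2$subject <- perm[tab$subject]
  expect_equal(rm_anova_2way(tab2)$F, res$F, tolerance = 1e-10)
})

test_that("zero-noise timing gives F = 0 for video type, p -> 0 for interval", {
  tab <- generate_synthetic_timing(synthetic_timing_spec(weber = 0, bias = 0.1))
  res <- rm_anova_2way(tab)
  expect_equal(res$F[res$effect == "video_type"], 0)
  expect_equal(res$p[res$effect == "target_s"], 0)
  drop_cell <- !(tab$subject == 1 & tab$target_s == 1 &
                   tab$video_type == "control")
  expect_error(rm_anova_2way(tab[drop_cell, ]), "missing cells")
})

test_that("practice criterion thresholds the target-produced correlation", {
  t3 <- c(1, 2, 4, 1, 2, 4)
  expect_true(practice_criterion(t3, t3)$pass)
  expect_false(practice_criterion(t3, -t3)$pass)
  expect_false(practice_criterion(t3, rep(2, 6))$pass)
  set.seed(12)
  noisy <- t3 * (1 + rnorm(6, 0, 0.1))
  expect_true(practice_criterion(t3, noisy)$pass)
  expect_error(practice_criterion(1:2, 1:2), "3 paired trials")
})

test_that("inversion exclusion requires strictly increasing means", {
  expect_true(inversion_exclusion(c(1.75, 2.41, 4.38)))
  expect_false(inversion_exclusion(c(4.0, 2.0, 1.0)))
  expect_false(inversion_exclusion(c(2.0, 2.0, 3.0)))
})

test_that("the questionnaire report has the published table's shape", {
  spec <- synthetic_ratings_spec(n_subjects = 12, delta = 0.8, seed = 21)
  tab <- generate_synthetic_ratings(spec)
  a <- tab[tab$condition == "B", c("subject", "dimension", "rating")]
  b <- tab[tab$condition == "A", c("subject", "dimension", "rating")]
  rep_ <- ascq_compare(a, b, design = "paired")
  expect_equal(nrow(rep_), 17)
  expect_named(rep_, c("dimension", "bf10", "t", "df", "p", "cohens_d",
                       "p_bonferroni", "interpretation"))
  expect_true(all(rep_$df == 11))
  expect_true(all(rep_$p_bonferroni >= rep_$p - 1e-15))
  expect_true(all(rep_$interpretation %in%
                    c("supports_H1", "supports_H0", "insensitive")))
  # self-comparison cannot support a difference (jitter avoids zero variance)
  set.seed(2)
  a2 <- a
  a2$rating <- a2$rating + rnorm(nrow(a2), 0, 1e-3)
  self <- ascq_compare(a, a2, design = "paired")
  expect_true(all(self$interpretation != "supports_H1"))
  expect_true(all(abs(self$t) < 2))
  # CSV serialization round-trips
  f <- withr::local_tempfile(fileext = ".csv")
  ascq_compare(a, b, design = "paired", out = f)
  expect_equal(nrow(read.csv(f)), 17)
})

test_that("null-effect reports rarely reach corrected significance", {
  n_sig <- vapply(1:20, function(r) {
    tab <- generate_synthetic_ratings(
      synthetic_ratings_spec(n_subjects = 12, delta = 0, seed = 9000 + r))
    a <- tab[tab$condition == "A", ]
    b <- tab[tab$condition == "B", ]
    sum(ascq_compare(a, b, design = "paired")$p_bonferroni < 0.05)
  }, numeric(1))
  # family-wise error rate is controlled at ~5%: over 20 null families of
  # 17 tests, expect about one significant dimension in total
  expect_lte(sum(n_sig), 4)
})
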