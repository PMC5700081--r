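#' JZS Bayes-factor configuration
#'
#' The default Jeffreys-Zellner-Siow prior places a Cauchy distribution
#' with scale 0.707 (half-width at half-maximum) on the standardized
#' effect size under the alternative.
#'
#' @param prior_scale Cauchy scale `r` (> 0), default 0.707.
#' @return A `bf_config` list.
#' @export
bf_config <- function(prior_scale = 0.707) {
  stopifnot(prior_scale > 0)
  structure(list(prior_scale = prior_scale), class = "bf_config")
}

#' JZS default Bayes factor for a t statistic
#'
#' Computes `BF10`, the ratio of the marginal likelihood of `t` under a
#' Cauchy(0, r) prior on the standardized effect to its likelihood under
#' the point null. The Cauchy prior is integrated as a normal scale
#' mixture: the marginal under the alternative is
#' \deqn{m_1(t) = \int_0^\infty (1 + N g r^2)^{-1/2}
#'   \left(1 + \frac{t^2}{\nu (1 + N g r^2)}\right)^{-(\nu+1)/2}
#'   \pi(g)\, dg,}
#' with \eqn{\pi(g)} inverse-gamma(1/2, 1/2) and `N` the effective sample
#' size, against \eqn{m_0(t) \propto (1 + t^2/\nu)^{-(\nu+1)/2}}.
#' The integral is evaluated in log space by adaptive quadrature after
#' mapping \eqn{(0, \infty)} to the unit interval via `g = u / (1 - u)`.
#'
#' For a paired design `n_eff = n`; for two independent groups
#' `n_eff = n1 * n2 / (n1 + n2)`.
#'
#' @param t Observed t statistic.
#' @param df Degrees of freedom (paired: `n - 1`; independent:
#'   `n1 + n2 - 2`).
#' @param n_eff Effective sample size (> 0).
#' @param config A [bf_config()].
#' @return `BF10` (> 0); values above 1 favour a difference.
#' @export
jzs_bf10 <- function(t, df, n_eff, config = bf_config()) {
  stopifnot(is.finite(t), df >= 1, n_eff > 0)
  r2 <- config$prior_scale^2
  nu <- df
  log_m0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  # inverse-gamma(1/2, 1/2) log density
  log_pi_g <- function(g) 0.5 * log(0.5) - lgamma(0.5) - 1.5 * log(g) - 0.5 / g
  integrand <- function(u) {
    g <- u / (1 - u)
    q <- 1 + n_eff * g * r2
    log_m1 <- -0.5 * log(q) - (nu + 1) / 2 * log1p(t^2 / (nu * q))
    # Jacobian of g = u / (1 - u): dg = du / (1 - u)^2
    v <- exp(log_m1 - log_m0 + log_pi_g(g) - 2 * log1p(-u))
    v[!is.finite(v)] <- 0
    v
  }
  res <- tryCatch(
    integrate(integrand, 0, 1, rel.tol = 1e-8, subdivisions = 500L),
    error = function(e) stop("Bayes-factor quadrature failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (res$value <= 0 || !is.finite(res$value)) {
    stop("Bayes-factor quadrature did not converge (value = ", res$value,
         ", abs.error = ", res$abs.error, ")", call. = FALSE)
  }
  res$value
}

#' Cohen's d from a paired t statistic
#'
#' `d = t / sqrt(n)`: the standardized mean within-subject difference.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs (>= 2).
#' @return Cohen's d (signed).
#' @export
cohens_d_paired <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

#' Cohen's d from an independent-groups t statistic
#'
#' `d = t * sqrt(1/n1 + 1/n2)` under the pooled equal-variance model.
#'
#' @param t Pooled-variance t statistic.
#' @param n1,n2 Group sizes (each >= 2).
#' @return Cohen's d (signed).
#' @export
cohens_d_independent <- function(t, n1, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  t * sqrt(1 / n1 + 1 / n2)
}

ttest_result <- function(t, df, p, d, bf10, design, n1, n2 = NA_integer_) {
  structure(
    list(t = t, df = df, p_two_tailed = p, cohens_d = d, bf10 = bf10,
         design = design, n1 = n1, n2 = n2),
    class = "ttest_result"
  )
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("%s t(%g) = %.3f, p = %.4g, d = %.3f, BF10 = %.4g\n",
              x$design, x$df, x$t, x$p_two_tailed, x$cohens_d, x$bf10))
  invisible(x)
}

#' Paired t-test with JZS Bayes factor
#'
#' Classical two-tailed paired t-test augmented with Cohen's d
#' (`t / sqrt(n)`) and the JZS default Bayes factor.
#'
#' @param x,y Paired samples of equal length (>= 2).
#' @param config A [bf_config()].
#' @return A `ttest_result` with fields `t`, `df`, `p_two_tailed`,
#'   `cohens_d`, `bf10`, `design`.
#' @export
paired_ttest <- function(x, y, config = bf_config()) {
  if (length(x) != length(y)) stop("paired samples must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  if (sd(x - y) == 0) {
    stop("zero variance of paired differences; t is undefined", call. = FALSE)
  }
  ht <- t.test(x, y, paired = TRUE)
  n <- length(x)
  t <- unname(ht$statistic)
  ttest_result(t, unname(ht$parameter), ht$p.value, cohens_d_paired(t, n),
               jzs_bf10(t, n - 1, n, config), "paired", n)
}

#' Independent-groups t-test with JZS Bayes factor
#'
#' Pooled equal-variance two-tailed t-test (df = `n1 + n2 - 2`) with
#' Cohen's d and the JZS Bayes factor at
#' `n_eff = n1 * n2 / (n1 + n2)`.
#'
#' @inheritParams paired_ttest
#' @export
independent_ttest <- function(x, y, config = bf_config()) {
  if (length(x) < 2 || length(y) < 2) stop("need at least 2 per group", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) stop("zero variance in both groups", call. = FALSE)
  ht <- t.test(x, y, var.equal = TRUE)
  n1 <- length(x)
  n2 <- length(y)
  t <- unname(ht$statistic)
  ttest_result(t, unname(ht$parameter), ht$p.value,
               cohens_d_independent(t, n1, n2),
               jzs_bf10(t, n1 + n2 - 2, n1 * n2 / (n1 + n2), config),
               "independent", n1, n2)
}

#' Bonferroni correction
#'
#' Multiplies p-values by the number of comparisons `m`. By default the
#' result is capped at 1; the uncapped mode exists because published
#' tables sometimes print uncapped products.
#'
#' @param p_values Vector of p-values in \[0, 1\].
#' @param m Number of comparisons (>= 1).
#' @param cap Cap adjusted values at 1 (default `TRUE`).
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m, cap = TRUE) {
  stopifnot(m >= 1)
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- p_values * m
  if (cap) out <- pmin(out, 1)
  out
}

#' Interpret a Bayes factor against the conventional thresholds
#'
#' `BF10 > 3` is read as evidence for a difference (alternative),
#' `BF10 < 1/3` as evidence for no difference (null), anything between
#' as insensitive.
#'
#' @param bf10 Bayes factor(s) (> 0).
#' @return Character vector in `{"supports_H1", "supports_H0",
#'   "insensitive"}`.
#' @export
interpret_bf <- function(bf10) {
  if (any(bf10 <= 0)) stop("BF10 must be positive", call. = FALSE)
  ifelse(bf10 > 3, "supports_H1",
         ifelse(bf10 < 1 / 3, "supports_H0", "insensitive"))
}

#' Two-way repeated-measures ANOVA
#'
#' Classical fully within-subject two-factor ANOVA on the subject x
#' factor-A x factor-B cell means: each main effect and the interaction
#' is tested against its own subject-by-effect error stratum. Effect
#' sizes are partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`); classical eta squared
#' (`SS_effect / SS_total`) is included alongside.
#'
#' Degenerate zero-noise data follow the convention: an effect with zero
#' sum of squares has `F = 0`; a positive effect over a zero error
#' stratum has `F = Inf`, `p = 0`.
#'
#' @param data Data frame with columns `subject`, `produced_s` (response)
#'   and the two factors (defaults `target_s` and `video_type`, the
#'   temporal-production design). Replicates within a cell are averaged;
#'   every subject must have every cell (no imputation).
#' @param response,factor_a,factor_b Column names.
#' @return An `anova_result`: tibble with one row per effect
#'   (`A`, `B`, `A:B`) carrying `F`, `df1`, `df2`, `p`, `partial_eta_sq`,
#'   `eta_sq`, plus the full sums-of-squares table as attribute `"ss"`.
#' @export
rm_anova_2way <- function(data, response = "produced_s",
                          factor_a = "target_s", factor_b = "video_type") {
  need <- c("subject", response, factor_a, factor_b)
  if (!all(need %in% names(data))) {
    stop("data must contain columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  df <- data.frame(
    s = factor(data$subject), a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]]), y = data[[response]]
  )
  cells <- aggregate(y ~ s + a + b, data = df, FUN = mean)
  n <- nlevels(cells$s)
  na <- nlevels(cells$a)
  nb <- nlevels(cells$b)
  if (nrow(cells) != n * na * nb) {
    stop("missing cells: every subject needs every factor combination",
         call. = FALSE)
  }
  g <- mean(cells$y)
  m_s <- tapply(cells$y, cells$s, mean)
  m_a <- tapply(cells$y, cells$a, mean)
  m_b <- tapply(cells$y, cells$b, mean)
  m_ab <- tapply(cells$y, list(cells$a, cells$b), mean)
  m_as <- tapply(cells$y, list(cells$a, cells$s), mean)
  m_bs <- tapply(cells$y, list(cells$b, cells$s), mean)
  ss_total <- sum((cells$y - g)^2)
  ss_s <- na * nb * sum((m_s - g)^2)
  ss_a <- n * nb * sum((m_a - g)^2)
  ss_b <- n * na * sum((m_b - g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, nb)) -
                      outer(rep(1, na), m_b) + g)^2)
  ss_as <- nb * sum((m_as - outer(m_a, rep(1, n)) -
                       outer(rep(1, na), m_s) + g)^2)
  ss_bs <- na * sum((m_bs - outer(m_b, rep(1, n)) -
                       outer(rep(1, nb), m_s) + g)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs
  eff <- function(name, ss_e, df1, ss_err, df2) {
    ms_e <- ss_e / df1
    ms_err <- ss_err / df2
    f <- if (ss_e <= 1e-300) 0 else if (ms_err <= 0) Inf else ms_e / ms_err
    p <- if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE)
    tibble::tibble(effect = name, F = f, df1 = df1, df2 = df2, p = p,
                   partial_eta_sq = if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0,
                   eta_sq = if (ss_total > 0) ss_e / ss_total else 0)
  }
  out <- rbind(
    eff("A", ss_a, na - 1, ss_as, (na - 1) * (n - 1)),
    eff("B", ss_b, nb - 1, ss_bs, (nb - 1) * (n - 1)),
    eff("A:B", ss_ab, (na - 1) * (nb - 1), ss_abs, (na - 1) * (nb - 1) * (n - 1))
  )
  out$effect <- c(factor_a, factor_b, paste0(factor_a, ":", factor_b))
  attr(out, "ss") <- c(subjects = ss_s, A = ss_a, B = ss_b, `A:B` = ss_ab,
                       `A:subjects` = ss_as, `B:subjects` = ss_bs,
                       `A:B:subjects` = ss_abs, total = ss_total)
  class(out) <- c("anova_result", class(out))
  out
}

#' Practice-session screening for the temporal-production task
#'
#' A practice block passes when the Pearson correlation between target
#' and produced intervals is at least 0.5; participants repeat the
#' practice otherwise.
#'
#' @param targets,produced Numeric vectors of equal length (>= 3 trials).
#' @return List with `pass` (logical), `r` and `reason`.
#' @export
practice_criterion <- function(targets, produced) {
  if (length(targets) != length(produced) || length(targets) < 3) {
    stop("need at least 3 paired trials", call. = FALSE)
  }
  if (sd(produced) == 0 || sd(targets) == 0) {
    return(list(pass = FALSE, r = NA_real_,
                reason = "zero variance in produced or target intervals"))
  }
  r <- cor(targets, produced)
  list(pass = r >= 0.5, r = r,
       reason = if (r >= 0.5) "ok" else "target-produced correlation below 0.5")
}

#' Exclusion rule for temporally inverted production
#'
#' A participant whose mean produced intervals are not strictly
#' increasing in the target duration (including ties) is excluded as
#' temporally inverted.
#'
#' @param mean_produced_by_target Numeric vector of per-target mean
#'   produced intervals, ordered by increasing target duration (length
#'   3 in the standard 1/2/4 s design).
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
inversion_exclusion <- function(mean_produced_by_target) {
  stopifnot(length(mean_produced_by_target) >= 2)
  all(diff(mean_produced_by_target) > 0)
}

#' Dimension-wise questionnaire comparison report
#'
#' Runs one t-test per questionnaire dimension between two rating tables
#' (paired or independent design), with Cohen's d, the JZS Bayes factor,
#' Bonferroni-adjusted p-values and the Bayes-factor interpretation --
#' the structure of a published comparison table.
#'
#' @param table_a,table_b Long-format tables with columns `subject`,
#'   `dimension`, `rating` (e.g. the two conditions of
#'   [generate_synthetic_ratings()] output). Both must cover the same
#'   dimensions; a paired design additionally requires matching subjects.
#' @param design `"paired"` or `"independent"`.
#' @param config A [bf_config()].
#' @param bonferroni_m Multiplier for the correction (default: number of
#'   dimensions).
#' @param cap Cap adjusted p-values at 1.
#' @param out Optional CSV path to serialize the report to.
#' @return Tibble with one row per dimension: `dimension`, `bf10`, `t`,
#'   `df`, `p`, `p_bonferroni`, `cohens_d`, `interpretation`.
#' @export
ascq_compare <- function(table_a, table_b, design = c("paired", "independent"),
                         config = bf_config(), bonferroni_m = NULL,
                         cap = TRUE, out = NULL) {
  design <- match.arg(design)
  dims <- sort(unique(table_a$dimension))
  if (!setequal(dims, unique(table_b$dimension))) {
    stop("tables must share the same dimensions", call. = FALSE)
  }
  m <- bonferroni_m %||% length(dims)
  rows <- lapply(dims, function(d) {
    a <- table_a[table_a$dimension == d, ]
    b <- table_b[table_b$dimension == d, ]
    if (design == "paired") {
      a <- a[order(a$subject), ]
      b <- b[order(b$subject), ]
      if (!identical(a$subject, b$subject)) {
        stop("paired design requires matching subjects for dimension '", d,
             "'", call. = FALSE)
      }
      res <- paired_ttest(a$rating, b$rating, config)
    } else {
      res <- independent_ttest(a$rating, b$rating, config)
    }
    tibble::tibble(dimension = d, bf10 = res$bf10, t = res$t, df = res$df,
                   p = res$p_two_tailed, cohens_d = res$cohens_d)
  })
  rep <- do.call(rbind, rows)
  rep$p_bonferroni <- bonferroni(rep$p, m, cap = cap)
  rep$interpretation <- interpret_bf(rep$bf10)
  rep <- rep[match(unique(table_a$dimension), rep$dimension), ]
  if (!is.null(out)) write.csv(rep, out, row.names = FALSE)
  rep
}

#' Recompute Bayes factors and effect sizes from printed summary statistics
#'
#' Given a table of published t statistics with their designs and sample
#' sizes, recomputes `BF10` and Cohen's d -- the route by which published
#' Bayesian t-test tables can be reproduced when raw data are not
#' deposited.
#'
#' @param summary_table Data frame with columns `t`, `design` (`"paired"`
#'   or `"independent"`), `n1`, and `n2` (ignored for paired rows).
#'   Additional columns pass through.
#' @param config A [bf_config()].
#' @return The input with `df`, `bf10` and `cohens_d` columns appended.
#' @export
bf_from_summary <- function(summary_table, config = bf_config()) {
  stopifnot(all(c("t", "design", "n1") %in% names(summary_table)))
  n <- nrow(summary_table)
  df <- bf <- d <- numeric(n)
  for (i in seq_len(n)) {
    ti <- summary_table$t[i]
    if (summary_table$design[i] == "paired") {
      n1 <- summary_table$n1[i]
      df[i] <- n1 - 1
      bf[i] <- jzs_bf10(ti, n1 - 1, n1, config)
      d[i] <- cohens_d_paired(ti, n1)
    } else {
      n1 <- summary_table$n1[i]
      n2 <- summary_table$n2[i]
      df[i] <- n1 + n2 - 2
      bf[i] <- jzs_bf10(ti, n1 + n2 - 2, n1 * n2 / (n1 + n2), config)
      d[i] <- cohens_d_independent(ti, n1, n2)
    }
  }
  summary_table$df <- df
  summary_table$bf10 <- bf
  summary_table$cohens_d <- d
  summary_table
}
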