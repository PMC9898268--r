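# Inferential statistics for the learning study, written out explicitly so
# every number can be checked against published values and against base-R /
# car oracles in the tests: paired t, unbiased variance, mean-centered
# Levene, two-way within-subject ANOVA with sphericity corrections and
# partial eta squared, Bonferroni paired post-hocs, correlations, Cohen's d.

test_result <- function(method, statistic, df, df2 = NA_real_, p_value,
                        effect_size = NA_real_, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n = NA_integer_) {
  tibble(method = method, statistic = statistic, df = df, df2 = df2,
         p_value = p_value, effect_size = effect_size, estimate = estimate,
         ci_low = ci_low, ci_high = ci_high, n = n)
}

#' Paired-sample t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on differences `d = x - y`, df = n - 1,
#' two-sided p; `effect_size` is paired Cohen's d = mean(d)/sd(d) and the CI
#' is the 95% t interval for the mean difference.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return One-row result tibble.
#' @examples
#' with(swim_learning_rates, paired_t(b[speed == "low"], b[speed == "high"]))
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) < 1e-15) abort("zero-variance differences")
  n <- length(d)
  se <- sd(d) / sqrt(n)
  t <- mean(d) / se
  ci <- mean(d) + c(-1, 1) * qt(0.975, n - 1) * se
  test_result("paired t", statistic = t, df = n - 1,
              p_value = 2 * pt(-abs(t), n - 1),
              effect_size = mean(d) / sd(d), estimate = mean(d),
              ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Unbiased sample variance
#'
#' @param x Numeric vector of length >= 2.
#' @return Scalar variance with the n - 1 denominator.
#' @export
sample_variance <- function(x) {
  if (length(x) < 2) abort("need at least 2 values")
  sum((x - mean(x))^2) / (length(x) - 1)
}

#' Levene's test for homogeneity of variance (mean-centered)
#'
#' One-way ANOVA F on the absolute deviations `z_ij = |x_ij - center_j|`,
#' df = (k - 1, N - k). `center = "mean"` is the original Levene test;
#' `center = "median"` gives the Brown-Forsythe variant.
#'
#' @param groups List of numeric vectors (each length >= 2), or a data frame
#'   with columns `value` and `group`.
#' @param center `"mean"` (default) or `"median"`.
#' @return One-row result tibble (`statistic` is F, `df`/`df2` the two
#'   degrees of freedom).
#' @export
levene_mean_centered <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  k <- length(groups)
  stopifnot(k >= 2, all(lengths(groups) >= 2))
  cfun <- if (center == "mean") mean else median
  z <- purrr::map(groups, ~abs(.x - cfun(.x)))
  N <- sum(lengths(z))
  zbar <- mean(unlist(z))
  ss_between <- sum(purrr::map_dbl(z, ~length(.x) * (mean(.x) - zbar)^2))
  ss_within <- sum(purrr::map_dbl(z, ~sum((.x - mean(.x))^2)))
  df1 <- k - 1; df2 <- N - k
  if (ss_within < 1e-30) {
    if (ss_between < 1e-30) {
      return(test_result("Levene (mean-centered)", statistic = 0, df = df1,
                         df2 = df2, p_value = 1, n = N))
    }
    warn("zero within-group spread of deviations: F is infinite")
    return(test_result("Levene (mean-centered)", statistic = Inf, df = df1,
                       df2 = df2, p_value = 0, n = N))
  }
  F <- (ss_between / df1) / (ss_within / df2)
  test_result(sprintf("Levene (%s-centered)", center), statistic = F,
              df = df1, df2 = df2, p_value = pf(F, df1, df2, lower.tail = FALSE),
              n = N)
}

#' Two-way fully within-subject ANOVA
#'
#' Classical repeated-measures sum-of-squares decomposition for a balanced
#' complete subject x A x B table: each effect is tested against its own
#' subject-interaction error term (A against A x subject, etc.). Partial eta
#' squared is `SS_effect / (SS_effect + SS_error)`. For effects with more
#' than one numerator df, Greenhouse-Geisser and Huynh-Feldt sphericity
#' epsilons are computed from the covariance of the effect's orthonormal
#' contrast scores, and a corrected p is reported using the
#' Greenhouse-Geisser epsilon when it is below 0.75 and Huynh-Feldt
#' otherwise; 2-level effects are exempt (epsilon = 1).
#'
#' @param data Long tibble.
#' @param value,subject,a,b Column names (strings) of the measurement, the
#'   subject id, and the two within-subject factors.
#' @return Tibble with one row per effect (`A`, `B`, `A:B`): `ss_effect`,
#'   `ss_error`, `df`, `df2`, `statistic` (F), `p_value`, `pes` (partial eta
#'   squared), `epsilon_gg`, `epsilon_hf`, `p_corrected`,
#'   `correction`.
#' @export
rm_anova2 <- function(data, value = "value", subject = "subject",
                      a = "a", b = "b") {
  df <- tibble(
    y = as.numeric(data[[value]]),
    s = factor(data[[subject]]),
    A = factor(data[[a]]),
    B = factor(data[[b]])
  )
  if (anyNA(df)) abort("missing values in the table")
  counts <- table(df$s, df$A, df$B)
  if (any(counts != 1)) abort("table must be balanced and complete (one value per subject x cell)")
  ns <- nlevels(df$s); na <- nlevels(df$A); nb <- nlevels(df$B)
  if (ns < 2) abort("need at least 2 subjects")
  gm <- mean(df$y)
  m_s <- tapply(df$y, df$s, mean)
  m_a <- tapply(df$y, df$A, mean)
  m_b <- tapply(df$y, df$B, mean)
  m_as <- tapply(df$y, list(df$A, df$s), mean)   # na x ns
  m_bs <- tapply(df$y, list(df$B, df$s), mean)
  m_ab <- tapply(df$y, list(df$A, df$B), mean)
  ss_a <- ns * nb * sum((m_a - gm)^2)
  ss_b <- ns * na * sum((m_b - gm)^2)
  ss_ab <- ns * sum((sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm)^2)
  ss_s <- na * nb * sum((m_s - gm)^2)
  ss_as <- nb * sum((sweep(sweep(m_as, 1, m_a), 2, m_s) + gm)^2)
  ss_bs <- na * sum((sweep(sweep(m_bs, 1, m_b), 2, m_s) + gm)^2)
  ss_tot <- sum((df$y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  effects <- list(
    list(name = "A", ss = ss_a, ss_err = ss_as,
         df1 = na - 1, df2 = (na - 1) * (ns - 1)),
    list(name = "B", ss = ss_b, ss_err = ss_bs,
         df1 = nb - 1, df2 = (nb - 1) * (ns - 1)),
    list(name = "A:B", ss = ss_ab, ss_err = ss_abs,
         df1 = (na - 1) * (nb - 1), df2 = (na - 1) * (nb - 1) * (ns - 1))
  )
  # orthonormal contrasts for sphericity epsilons
  onc <- function(p) {
    C <- stats::contr.helmert(p)
    sweep(C, 2, sqrt(colSums(C^2)), "/")
  }
  cell <- tapply(df$y, list(df$s, interaction(df$A, df$B, lex.order = TRUE)),
                 mean)  # ns x (na*nb), A slow, B fast
  contr <- list(
    A = kronecker(onc(na), matrix(1 / sqrt(nb), nb, 1)),
    B = kronecker(matrix(1 / sqrt(na), na, 1), onc(nb)),
    `A:B` = kronecker(onc(na), onc(nb))
  )
  purrr::map_dfr(effects, function(e) {
    F <- (e$ss / e$df1) / (e$ss_err / e$df2)
    p <- pf(F, e$df1, e$df2, lower.tail = FALSE)
    eps_gg <- eps_hf <- 1
    correction <- "none"
    p_corr <- p
    if (e$df1 > 1) {
      Cm <- contr[[e$name]]
      Sc <- cov(cell %*% Cm)
      q <- nrow(Sc)
      eps_gg <- sum(diag(Sc))^2 / (q * sum(Sc^2))
      eps_hf <- min((ns * q * eps_gg - 2) / (q * (ns - 1 - q * eps_gg)), 1)
      if (eps_gg < 0.75) {
        correction <- "greenhouse-geisser"
        eps_use <- eps_gg
      } else {
        correction <- "huynh-feldt"
        eps_use <- max(eps_hf, 1 / q)
      }
      p_corr <- pf(F, e$df1 * eps_use, e$df2 * eps_use, lower.tail = FALSE)
    }
    tibble(effect = e$name, ss_effect = e$ss, ss_error = e$ss_err,
           df = e$df1, df2 = e$df2, statistic = F, p_value = p,
           pes = e$ss / (e$ss + e$ss_err),
           epsilon_gg = eps_gg, epsilon_hf = eps_hf,
           p_corrected = p_corr, correction = correction)
  })
}

#' Bonferroni-corrected pairwise paired comparisons
#'
#' For a within-subject factor, collapses to subject x level means, runs a
#' paired t test for every level pair, multiplies p by the number of pairs
#' (capped at 1), and reports the mean difference with its per-pair 95%
#' paired-t CI.
#'
#' @param data Long tibble.
#' @param value,subject,factor Column names (strings).
#' @return Tibble with one row per pair: `level_1`, `level_2`,
#'   `mean_difference`, `ci_low`, `ci_high`, `statistic`, `df`, `p_value`
#'   (raw), `p_adjusted`.
#' @export
bonferroni_pairwise <- function(data, value = "value", subject = "subject",
                                factor = "factor") {
  df <- tibble(y = as.numeric(data[[value]]),
               s = base::factor(data[[subject]]),
               f = base::factor(data[[factor]]))
  if (nlevels(df$f) < 2) abort("factor needs at least 2 levels")
  m <- df %>%
    group_by(.data$s, .data$f) %>%
    summarise(y = mean(.data$y), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "f", values_from = "y")
  levs <- levels(df$f)
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  k <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    res <- paired_t(m[[pr[1]]], m[[pr[2]]])
    tibble(level_1 = pr[1], level_2 = pr[2],
           mean_difference = res$estimate,
           ci_low = res$ci_low, ci_high = res$ci_high,
           statistic = res$statistic, df = res$df,
           p_value = res$p_value,
           p_adjusted = pmin(res$p_value * k, 1))
  })
}

#' Pearson or Spearman correlation with a two-sided test
#'
#' Pearson: `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 df. Spearman: the
#' same t approximation applied to the rank correlation (adequate for the
#' sample sizes in this design; ranks use midranks for ties).
#'
#' @param x,y Equal-length numeric vectors (n >= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row result tibble (`statistic` is t; `estimate` is r or rho).
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) < 1e-15 || sd(y) < 1e-15) abort("zero variance in a variable")
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  r_cl <- min(max(r, -1), 1)
  if (abs(r_cl) >= 1 - 1e-15) {
    t <- sign(r_cl) * Inf
    p <- 0
  } else {
    t <- r_cl * sqrt((n - 2) / (1 - r_cl^2))
    p <- 2 * pt(-abs(t), n - 2)
  }
  test_result(paste0(method, " correlation"), statistic = t, df = n - 2,
              p_value = p, estimate = r_cl, n = n)
}

#' Cohen's d effect size
#'
#' Paired: `mean(x - y) / sd(x - y)`. Unpaired: mean difference over the
#' pooled SD.
#'
#' @param x,y Numeric vectors; equal length when `paired`.
#' @param paired Logical (default TRUE, matching the within-subject design).
#' @return Scalar d.
#' @export
cohens_d <- function(x, y, paired = TRUE) {
  if (paired) {
    stopifnot(length(x) == length(y))
    d <- x - y
    if (sd(d) < 1e-15) {
      abort(sprintf(
        "zero SD of differences (constant difference %.4g): d undefined",
        mean(d)))
    }
    return(mean(d) / sd(d))
  }
  stopifnot(length(x) >= 2, length(y) >= 2)
  n1 <- length(x); n2 <- length(y)
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp < 1e-15) abort("zero pooled SD: d undefined")
  (mean(x) - mean(y)) / sp
}

#' Shapiro-Wilk normality screen
#'
#' Reported alongside the parametric tests (alpha = 0.05 by convention);
#' the battery never auto-switches tests on its outcome.
#'
#' @param x Numeric vector (3 <= n <= 5000).
#' @return One-row result tibble (`statistic` is W).
#' @export
normality_check <- function(x) {
  sw <- shapiro.test(x)
  test_result("Shapiro-Wilk", statistic = unname(sw$statistic),
              df = NA_real_, p_value = sw$p.value, n = length(x))
}
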