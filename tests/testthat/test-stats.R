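low_b <- swim_learning_rates$b[swim_learning_rates$speed == "low"]
high_b <- swim_learning_rates$b[swim_learning_rates$speed == "high"]

test_that("paired t follows the textbook formula and base-R oracle", {
  r <- paired_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  withr::with_seed(3, {
    x <- rnorm(12); y <- rnorm(12, 0.4)
  })
  mine <- paired_t(x, y)
  base <- t.test(x, y, paired = TRUE)
  expect_equal(mine$statistic, unname(base$statistic))
  expect_equal(mine$p_value, base$p.value)
  expect_equal(c(mine$ci_low, mine$ci_high), unname(base$conf.int),
               tolerance = 1e-12, ignore_attr = TRUE)
  # antisymmetry
  expect_equal(paired_t(y, x)$statistic, -mine$statistic)
  expect_error(paired_t(x, x), "zero-variance")
})

test_that("the reported learning-rate comparison reproduces", {
  r <- paired_t(low_b, high_b)
  expect_equal(round(r$statistic, 3), -1.373)
  expect_equal(r$df, 6)
  expect_equal(round(r$p_value, 3), 0.219)
})

test_that("sample variance is unbiased and matches the reported values", {
  expect_equal(sample_variance(c(1, 2, 3)), 1)
  expect_equal(round(sample_variance(low_b), 5), 0.00644)
  expect_equal(round(sample_variance(high_b), 5), 0.03042)
  expect_error(sample_variance(1), "2 values")
})

test_that("mean-centered Levene matches the reported F and the car oracle", {
  r <- levene_mean_centered(list(low_b, high_b))
  expect_equal(round(r$statistic, 3), 6.070)
  expect_equal(c(r$df, r$df2), c(1, 12))
  expect_equal(round(r$p_value, 3), 0.030)
  # independent oracle on random groups
  withr::with_seed(9, {
    g <- list(rnorm(10, sd = 1), rnorm(8, sd = 2), rnorm(12, sd = 0.5))
  })
  mine <- levene_mean_centered(g)
  df <- data.frame(value = unlist(g),
                   grp = factor(rep(seq_along(g), lengths(g))))
  oracle <- car::leveneTest(value ~ grp, data = df, center = mean)
  expect_equal(mine$statistic, oracle$`F value`[1], tolerance = 1e-9)
  expect_equal(mine$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("Levene handles degenerate spread patterns", {
  same <- list(c(1, 2, 3), c(4, 5, 6))
  expect_equal(levene_mean_centered(same)$statistic, 0)
  expect_warning(r <- levene_mean_centered(list(c(0, 0), c(-1, 1))),
                 "infinite")
  expect_equal(r$statistic, Inf)
  # invariance to per-group constant shifts
  withr::with_seed(2, g <- list(rnorm(9), rnorm(9, sd = 3)))
  shifted <- purrr::map2(g, c(5, -2), `+`)
  expect_equal(levene_mean_centered(g)$statistic,
               levene_mean_centered(shifted)$statistic, tolerance = 1e-12)
})

test_that("within-subject ANOVA decomposition matches the aov oracle", {
  withr::with_seed(31, {
    d <- expand.grid(subject = factor(1:7), a = factor(c("s1", "s16")),
                     b = factor(c("low", "high")))
    d$value <- rnorm(nrow(d)) + as.numeric(d$a) * 0.5 +
      rnorm(7)[as.integer(d$subject)]
  })
  mine <- rm_anova2(d, value = "value", subject = "subject", a = "a", b = "b")
  oracle <- summary(aov(value ~ a * b + Error(subject / (a * b)), data = d))
  o_f <- c(oracle[["Error: subject:a"]][[1]]$`F value`[1],
           oracle[["Error: subject:b"]][[1]]$`F value`[1],
           oracle[["Error: subject:a:b"]][[1]]$`F value`[1])
  expect_equal(mine$statistic, o_f, tolerance = 1e-9)
  o_p <- c(oracle[["Error: subject:a"]][[1]]$`Pr(>F)`[1],
           oracle[["Error: subject:b"]][[1]]$`Pr(>F)`[1],
           oracle[["Error: subject:a:b"]][[1]]$`Pr(>F)`[1])
  expect_equal(mine$p_value, o_p, tolerance = 1e-9)
  expect_true(all(mine$pes >= 0 & mine$pes <= 1))
  # total SS decomposes exactly
  ss_subject <- 4 * sum((tapply(d$value, d$subject, mean) - mean(d$value))^2)
  expect_equal(sum(mine$ss_effect) + sum(mine$ss_error) + ss_subject,
               sum((d$value - mean(d$value))^2), tolerance = 1e-9)
})

test_that("a null factor gives F = 0 and 2-level F equals paired t squared", {
  withr::with_seed(13, {
    d <- expand.grid(subject = factor(1:6), a = factor(c("x", "y")),
                     b = factor(c("p", "q")))
    d$value <- rnorm(nrow(d))
  })
  # make factor b exactly null: copy values across its levels
  d$value[d$b == "q"] <- d$value[d$b == "p"]
  res <- rm_anova2(d, value = "value", subject = "subject", a = "a", b = "b")
  expect_equal(res$statistic[res$effect == "B"], 0, tolerance = 1e-9)
  # collapse b and compare 2-level factor a with the paired t
  coll <- aggregate(value ~ subject + a, data = d, FUN = mean)
  tt <- paired_t(coll$value[coll$a == "x"], coll$value[coll$a == "y"])
  expect_equal(res$statistic[res$effect == "A"], tt$statistic^2,
               tolerance = 1e-9)
})

test_that("sphericity epsilons appear only for factors above 2 levels", {
  withr::with_seed(41, {
    d <- expand.grid(subject = factor(1:7), a = factor(paste0("c", 1:5)),
                     b = factor(c("low", "high")))
    d$value <- rnorm(nrow(d))
  })
  res <- rm_anova2(d, value = "value", subject = "subject", a = "a", b = "b")
  a_row <- res[res$effect == "A", ]
  expect_true(a_row$epsilon_gg > 1 / 4 && a_row$epsilon_gg <= 1)
  expect_true(a_row$correction %in% c("greenhouse-geisser", "huynh-feldt"))
  b_row <- res[res$effect == "B", ]
  expect_equal(b_row$epsilon_gg, 1)
  expect_equal(b_row$correction, "none")
  expect_equal(b_row$p_corrected, b_row$p_value)
})

test_that("Bonferroni post-hocs match per-pair paired t tests", {
  withr::with_seed(7, {
    d <- expand.grid(subject = factor(1:8), f = factor(c("a", "b", "c")))
    d$value <- rnorm(nrow(d)) + as.numeric(d$f) * 0.3
  })
  res <- bonferroni_pairwise(d, value = "value", subject = "subject",
                             factor = "f")
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_true(all(res$p_adjusted <= 1))
  wide <- tidyr::pivot_wider(d, names_from = "f", values_from = "value")
  direct <- paired_t(wide$a, wide$b)
  ab <- res[res$level_1 == "a" & res$level_2 == "b", ]
  expect_equal(ab$mean_difference, direct$estimate)
  expect_equal(c(ab$ci_low, ab$ci_high),
               c(direct$ci_low, direct$ci_high))
  expect_equal(ab$p_adjusted, min(direct$p_value * 3, 1))
  # 2 levels: adjusted p equals raw p
  d2 <- d[d$f != "c", ]
  d2$f <- droplevels(d2$f)
  r2 <- bonferroni_pairwise(d2, value = "value", subject = "subject",
                            factor = "f")
  expect_equal(r2$p_adjusted, r2$p_value)
  # 11 levels -> 55 comparisons
  d11 <- expand.grid(subject = factor(1:4), f = factor(paste0("k", 1:11)))
  d11$value <- rnorm(nrow(d11))
  expect_equal(nrow(bonferroni_pairwise(d11, value = "value",
                                        subject = "subject", factor = "f")),
               55)
})

test_that("correlations match their oracles and orderings", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlation(x, 2 * x + 1)$estimate, 1)
  cub <- correlation(x, x^3)
  expect_lt(cub$estimate, 1)
  expect_equal(correlation(x, x^3, method = "spearman")$estimate, 1)
  withr::with_seed(10, {
    a <- rnorm(30); b <- 0.6 * a + rnorm(30)
  })
  mine <- correlation(a, b)
  base <- cor.test(a, b)
  expect_equal(mine$estimate, unname(base$estimate))
  expect_equal(mine$p_value, base$p.value)
  # large-sample consistency at rho = 0.5
  withr::with_seed(77, {
    z <- rnorm(10000); w <- 0.5 * z + sqrt(0.75) * rnorm(10000)
  })
  expect_lt(abs(correlation(z, w)$estimate - 0.5), 0.03)
  expect_error(correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("Cohen's d follows its formulas and sampling behaviour", {
  expect_error(cohens_d(c(1, 2), c(1, 2)), "zero SD")
  expect_error(cohens_d(c(2, 3, 4), c(1, 2, 3)), "zero SD")  # constant diff
  x <- c(0.5, 1.5, -0.5, 0.5, 0.5)        # differences vs 0 mean 0.5 sd 1
  expect_equal(cohens_d(x + 1, rep(1, 5)), mean(x) / sd(x))
  withr::with_seed(21, {
    a <- rnorm(10000, 1); b <- rnorm(10000, 0)
  })
  expect_lt(abs(cohens_d(a, b, paired = FALSE) - 1), 0.05)
})

test_that("the normality screen wraps Shapiro-Wilk faithfully", {
  withr::with_seed(14, x <- rnorm(25))
  mine <- normality_check(x)
  base <- shapiro.test(x)
  expect_equal(mine$statistic, unname(base$statistic))
  expect_equal(mine$p_value, base$p.value)
})
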