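test_that("degree-0 fit equals the hand-computed transition-count MLE", {
  m0 <- fit_dmm(c(1, 1, 2, 1, 2, 2), degree = 0)
  expect_equal(m0$supports[[1]],
               matrix(c(1 / 3, 2 / 3, 1 / 2, 1 / 2), 2, byrow = TRUE),
               ignore_attr = TRUE)
  # property: degree-0 equals the count ratio on random sequences
  withr::with_seed(17, {
    for (i in 1:5) {
      x <- sample(1:3, 200, replace = TRUE)
      fit <- fit_dmm(x, degree = 0)
      counts <- matrix(0, 3, 3)
      for (t in 1:199) counts[x[t], x[t + 1]] <- counts[x[t], x[t + 1]] + 1
      expect_equal(fit$supports[[1]], counts / rowSums(counts),
                   ignore_attr = TRUE)
    }
  })
})

test_that("a constant sequence concentrates all mass on self-transition", {
  fit <- fit_dmm(rep(1, 10), degree = 1, m = 2)
  expect_gt(fit$supports[[1]][1, 1], 0.999)
  expect_gt(fit$supports[[2]][1, 1], 0.999)
  # unvisited source rows stay at the uniform default
  expect_equal(fit$supports[[1]][2, ], c(0.5, 0.5), tolerance = 0.2)
})

test_that("fit_dmm validates its inputs", {
  expect_error(fit_dmm(c(1, 2), degree = 3), "shorter")
  expect_error(fit_dmm(c(1, 5), degree = 0, m = 3), "alphabet")
})

test_that("transition_at interpolates the supports exactly", {
  s <- make_strategy_supports("linear", 3, 1)
  mdl <- new_dmm(s, n = 10)
  expect_equal(transition_at(mdl, 5), (s[[1]] + s[[2]]) / 2)
  expect_equal(transition_at(mdl, 0), s[[1]])
  s3 <- random_smooth_supports(4, 3, seed = 1)
  mdl3 <- new_dmm(s3, n = 9)
  expect_equal(transition_at(mdl3, 6), s3[[3]], tolerance = 1e-9)  # t/n = 2/3
  expect_error(transition_at(mdl, 11), "outside")
})

test_that("transition_at rows sum to 1 on a dense grid for fitted models", {
  x <- simulate_dmm(new_dmm(random_smooth_supports(4, 3, seed = 5), n = 800),
                    800, 1, seed = 6)
  fit <- fit_dmm(x, degree = 3)
  for (t in seq(0, 800, length.out = 1000)) {
    P <- transition_at(fit, t)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-9)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("appearance probabilities propagate the initial distribution", {
  id2 <- new_dmm(list(diag(2)), n = 5)
  p <- appearance_probabilities(id2, p0 = c(1, 0))
  expect_equal(p, matrix(rep(c(1, 0), each = 6), 6), ignore_attr = TRUE)
  unif <- new_dmm(list(matrix(0.5, 2, 2)), n = 4)
  p2 <- appearance_probabilities(unif, p0 = c(1, 0))
  expect_equal(p2[2:5, ], matrix(0.5, 4, 2), ignore_attr = TRUE)
  drift <- new_dmm(list(matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
                        matrix(c(0, 1, 0, 1), 2, byrow = TRUE)), n = 2)
  p3 <- appearance_probabilities(drift, p0 = c(1, 0))
  expect_equal(p3, rbind(c(1, 0), c(0.5, 0.5), c(0, 1)), ignore_attr = TRUE)
  expect_equal(rowSums(p3), rep(1, 3))
  expect_error(appearance_probabilities(id2, p0 = c(0.5, 0.2)), "distribution")
})

test_that("simulation is seeded, deterministic and law-abiding", {
  id3 <- new_dmm(list(diag(3)), n = 20)
  expect_equal(simulate_dmm(id3, 20, initial = 2, seed = 1), rep(2, 21))
  P <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.6, 0.3,
                0.3, 0.3, 0.4), 3, byrow = TRUE)
  hom <- new_dmm(list(P), n = 100000)
  x <- simulate_dmm(hom, 100000, initial = 1, seed = 8)
  expect_identical(x, simulate_dmm(hom, 100000, initial = 1, seed = 8))
  emp <- prop.table(table(factor(x[-length(x)], 1:3),
                          factor(x[-1], 1:3)), 1)
  expect_lt(max(abs(emp - P)), 0.01)
  expect_error(simulate_dmm(id3, 5, initial = 7, seed = 1), "initial")
})

test_that("information criteria follow the stated formulas", {
  certain <- new_dmm(list(matrix(c(0, 1, 0, 1), 2, byrow = TRUE)), n = 1)
  ic <- information_criteria(certain, c(1, 2))
  expect_equal(ic$loglik, 0)
  expect_equal(ic$npar, 2)
  expect_equal(ic$aic, 4)
  # npar arithmetic at the study's scale
  x11 <- rep(1:11, length.out = 500)
  fit11 <- fit_dmm(x11, degree = 3, maxit = 20)
  expect_equal(information_criteria(fit11, x11)$npar, 440)
})

test_that("higher-degree fits never lose log-likelihood (nesting)", {
  withr::with_seed(23, {
    seqs <- list(
      sample(1:3, 80, replace = TRUE),
      rep(c(1, 1, 2, 3), 25),
      simulate_dmm(new_dmm(make_strategy_supports("linear", 4, 1), n = 300),
                   300, 1, seed = 31)
    )
  })
  for (x in seqs) {
    f0 <- fit_dmm(x, degree = 0)
    f1 <- fit_dmm(x, degree = 1)
    f3 <- fit_dmm(x, degree = 3)
    expect_gte(f1$loglik, f0$loglik - 1e-6)
    expect_gte(f3$loglik, f1$loglik - 1e-6)
  }
})

test_that("degree-1 supports are recovered from simulated data", {
  s <- make_strategy_supports("linear", 3, 1)
  x <- simulate_dmm(new_dmm(s, n = 5000), 5000, 1, seed = 11)
  fit <- fit_dmm(x, degree = 1)
  err <- max(abs(fit$supports[[1]] - s[[1]]),
             abs(fit$supports[[2]] - s[[2]]))
  expect_lt(err, 0.05)
})

test_that("a homogeneous chain fits with nearly equal supports", {
  P <- matrix(c(0.7, 0.2, 0.1,
                0.1, 0.8, 0.1,
                0.2, 0.3, 0.5), 3, byrow = TRUE)
  errs <- sapply(c(500, 5000), function(n) {
    x <- simulate_dmm(new_dmm(list(P), n = n), n, 1, seed = 1)
    fit <- fit_dmm(x, degree = 1)
    mean(abs(fit$supports[[1]] - fit$supports[[2]]))
  })
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1])   # drift estimate shrinks with n
})

test_that("degree-3 supports are recovered after simulate -> refit", {
  s <- random_smooth_supports(m = 5, degree = 3, seed = 42)
  x <- simulate_dmm(new_dmm(s, n = 10000), 10000, 1, seed = 3)
  fit <- fit_dmm(x, degree = 3)
  err <- mean(mapply(function(A, B) mean(abs(A - B)), fit$supports, s))
  expect_lt(err, 0.05)
})

test_that("the least-squares estimator is a sane alternative", {
  s <- make_strategy_supports("linear", 3, 1)
  x <- simulate_dmm(new_dmm(s, n = 4000), 4000, 1, seed = 19)
  fit <- fit_dmm(x, degree = 1, method = "ls")
  err <- max(abs(fit$supports[[1]] - s[[1]]),
             abs(fit$supports[[2]] - s[[2]]))
  expect_lt(err, 0.15)   # LS trades efficiency for a closed form
  for (P in fit$supports) {
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-9)
  }
})

test_that("character and nucleotide-style alphabets are supported", {
  fit <- fit_dmm("aacgtacgt", degree = 0)
  expect_equal(fit$m, 4)
  expect_equal(fit$alphabet, c("a", "c", "g", "t"))
  expect_equal(fit$supports[[1]]["a" == fit$alphabet, ],
               c(1 / 3, 2 / 3, 0, 0), ignore_attr = TRUE)
})

test_that("tidy and glance summarise a fitted model", {
  fit <- fit_dmm(c(1, 2, 1, 2, 2, 1), degree = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 4)
  expect_true(all(c("support", "from", "to", "probability") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$degree, 1)
  expect_equal(gl$npar, 4)
})
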