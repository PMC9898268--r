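test_that("strategy presets build the advertised support structure", {
  blind <- make_strategy_supports("blind", m = 4, degree = 3)
  expect_length(blind, 4)
  for (P in blind) {
    expect_equal(P, matrix(0.25, 4, 4), ignore_attr = TRUE)
  }
  lin <- make_strategy_supports("linear", m = 3, degree = 1)
  expect_equal(lin[[1]][, 1], rep(0.85, 3))
  expect_equal(lin[[2]][, 3], rep(0.85, 3))
  anc <- make_strategy_supports("anchored_local", m = 5, degree = 3)
  # interior supports concentrate on their anchor column
  expect_true(all(anc[[2]][, 2] >= 0.8))
  expect_true(all(anc[[3]][, 4] >= 0.8))
  hyb <- make_strategy_supports("hybrid_nonlocal", m = 6, degree = 3)
  anchors <- sapply(hyb, function(P) which.max(P[1, ]))
  expect_equal(anchors[1], 1)
  expect_equal(anchors[4], 6)
  # interior anchors jump to non-adjacent patterns
  expect_true(all(abs(diff(anchors[1:2])) > 1 | abs(diff(anchors[2:3])) > 1))
})

test_that("strategy presets reject invalid requests", {
  expect_error(make_strategy_supports("linear", m = 3, degree = 0),
               "degree >= 1")
  expect_error(make_strategy_supports("unknown", m = 3, degree = 1))
})

test_that("every generated support matrix is row-stochastic", {
  for (st in c("blind", "linear", "anchored_local", "hybrid_nonlocal")) {
    for (m in c(2, 5, 11)) {
      sup <- make_strategy_supports(st, m = m, degree = 3)
      for (P in sup) {
        expect_equal(rowSums(P), rep(1, m), tolerance = 1e-12)
        expect_true(all(P >= 0))
      }
    }
  }
  rs <- random_smooth_supports(m = 6, degree = 3, seed = 2)
  for (P in rs) expect_equal(rowSums(P), rep(1, 6), tolerance = 1e-12)
})

test_that("blind supports yield near-uniform state frequencies", {
  sup <- make_strategy_supports("blind", m = 4, degree = 3)
  x <- simulate_dmm(new_dmm(sup, n = 10000), n = 10000, initial = 1,
                    seed = 99)
  freq <- tabulate(x, 4) / length(x)
  expect_true(all(abs(freq - 0.25) < 0.03))
})

test_that("performance series follows the exponential law", {
  noiseless <- gen_performance_series(0.3, 0.2, 0.5, sigma = 0,
                                      n_sessions = 16, seed = 1)
  t <- 1:16
  expect_equal(noiseless$freq_hz, 0.3 * exp(-0.2 * t) + 0.5)
  # Monte-Carlo average over many seeds converges to the noiseless curve
  sims <- sapply(1:1000, function(s) {
    gen_performance_series(0.3, 0.2, 0.5, sigma = 0.02, n_sessions = 16,
                           seed = s)$freq_hz
  })
  expect_true(all(abs(rowMeans(sims) - noiseless$freq_hz) < 0.005))
  # seeded determinism
  expect_identical(
    gen_performance_series(0.3, 0.2, 0.5, 0.05, 16, seed = 7),
    gen_performance_series(0.3, 0.2, 0.5, 0.05, 16, seed = 7))
})

test_that("rendered traces carry the labelled cycles", {
  tem <- make_crp_templates(3)
  labs <- rep(c(1, 2, 3, 2), each = 5)
  g <- gen_angle_traces(labs, tem, cycle_period = 1, noise_sd = 0, seed = 1)
  expect_equal(nrow(g$trace), length(seq(-0.5, 20.5, by = 0.01)))
  expect_equal(diff(range(g$trace$t_s)), 21, tolerance = 1e-9)
  # bit-identical under the same seed
  g2 <- gen_angle_traces(labs, tem, cycle_period = 1, noise_sd = 0, seed = 1)
  expect_identical(g$trace, g2$trace)
  expect_error(gen_angle_traces(c(1, 4), tem, seed = 1), "template")
})

test_that("trace rendering round-trips through the kinematics chain", {
  tem <- list(rep(0, 100), rep(90, 100))
  labs <- rep(c(1, 2), each = 10)
  g <- gen_angle_traces(labs, tem, cycle_period = 1.25, noise_sd = 0,
                        sensor_noise_sd = 0, seed = 3)
  filt <- lowpass_fourier(g$trace, cutoff = 8)
  cyc <- segment_cycles(filt)
  # cycle count = labels minus the two dropped edge cycles
  expect_equal(nrow(cyc), length(labs) - 2)
  crp <- compute_crp(filt, cyc)
  M <- crp_matrix(crp, unwrap = FALSE)
  truth <- labs[2:(length(labs) - 1)]
  # template ~ 0 degrees recovered within 10 degrees RMS away from edges
  rms0 <- sqrt(rowMeans(wrap_deg(M[truth == 1, 11:90, drop = FALSE])^2))
  expect_true(all(rms0 < 10))
  # recovered boundaries match the generator's cycle grid within 2 samples
  b_true <- g$boundaries[2:(length(g$boundaries) - 2)]
  expect_true(all(abs(filt$t_s[cyc$start_idx] - b_true) <= 0.02 + 1e-9))
})

test_that("a full synthetic learner is internally consistent", {
  sim <- simulate_learner(strategy = "anchored_local", m = 5, degree = 3,
                          n_sessions = 4, trials_per_session = 2,
                          cycles_per_trial = c(3, 6), seed = 21,
                          render = "none")
  expect_equal(nrow(sim$performance), 4)
  expect_true(all(sim$labels$pattern %in% 1:5))
  counts <- dplyr::count(sim$labels, session, trial)
  expect_true(all(counts$n >= 3 & counts$n <= 6))
  # trial-resolution dwell holds the pattern within each trial
  sim2 <- simulate_learner(m = 4, n_sessions = 3, trials_per_session = 2,
                           cycles_per_trial = c(4, 6), seed = 5,
                           render = "none", labels_at = "trial")
  per_trial <- dplyr::summarise(
    dplyr::group_by(sim2$labels, session, trial),
    one = dplyr::n_distinct(pattern), .groups = "drop")
  expect_true(all(per_trial$one == 1))
  # curve rendering: one curve per cycle, template + noise
  sim3 <- simulate_learner(m = 3, n_sessions = 2, trials_per_session = 2,
                           cycles_per_trial = c(4, 5), crp_noise_sd = 1,
                           seed = 9, render = "curves")
  expect_equal(nrow(sim3$curves), nrow(sim3$labels))
  err <- purrr::map2_dbl(sim3$curves$crp, sim3$curves$pattern, function(cv, p) {
    max(abs(cv - sim3$truth$templates[[p]]))
  })
  expect_true(all(err < 5))  # 1-degree noise stays near the template
})
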