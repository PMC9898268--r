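# Shared fixtures, all generated in code.

# n curves per template, iid Gaussian grid noise: the separated-template
# clustering condition.
template_curves <- function(levels, n_per, sigma = 5, L = 100, seed = 1) {
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(levels, function(mu) {
      matrix(rnorm(n_per * L, mu, sigma), n_per, L)
    }))
  })
  list(X = X, truth = rep(seq_along(levels), each = n_per))
}

# one-trial sinusoidal trace tibble
sine_trace <- function(f_knee = 1, f_elbow = 1, phase_elbow = 0,
                       dur = 10, fs = 100) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)  # integer periods: exact FFT bins
  tibble::tibble(
    learner = 1L, session = 1L, trial = 1L, speed = "low", t_s = t,
    elbow_deg = cos(2 * pi * f_elbow * t + phase_elbow),
    knee_deg = cos(2 * pi * f_knee * t)
  )
}

# adjusted Rand index (independent implementation for label agreement)
rand_adjusted <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  (sij - expected) / (maxi - expected)
}
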