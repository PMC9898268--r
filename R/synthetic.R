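# Seeded synthetic learners with known search strategies. Each learner is a
# drifting Markov chain over m coordination patterns whose support matrices
# encode a search-strategy preset; the chain's labels are rendered back into
# 100 Hz elbow/knee angle traces through per-pattern CRP templates, so the
# whole kinematics -> clustering -> DMM chain can be tested against ground
# truth. Session performance follows the exponential learning law
# f(t) = a * exp(-b * t) + c plus Gaussian noise.

#' Support matrices for a named exploration-strategy preset
#'
#' Builds the `degree + 1` row-stochastic support matrices of a drifting
#' Markov model realizing one of four search-strategy archetypes:
#' \describe{
#'   \item{blind}{Random search: every row of every support is uniform.}
#'   \item{linear}{Gradual drift from a start pattern to a target pattern:
#'     the first support concentrates on pattern 1, the last on pattern `m`,
#'     intermediate supports interpolate linearly.}
#'   \item{anchored_local}{History-dependent search through successive
#'     anchors: interior supports each concentrate mass on one intermediate
#'     pattern, visiting patterns in order.}
#'   \item{hybrid_nonlocal}{Discontinuous search: interior supports jump
#'     mass to non-adjacent patterns before settling on the target.}
#' }
#'
#' @param strategy One of `"blind"`, `"linear"`, `"anchored_local"`,
#'   `"hybrid_nonlocal"`.
#' @param m Number of coordination patterns (>= 2).
#' @param degree Polynomial drift degree (>= 0; `"linear"` and the anchored
#'   presets need >= 1).
#' @param anchor_mass Probability mass placed on a support's anchor pattern
#'   (default 0.85); the remainder is spread uniformly.
#' @return List of `degree + 1` row-stochastic m x m matrices.
#' @examples
#' make_strategy_supports("anchored_local", m = 5, degree = 3)
#' @export
make_strategy_supports <- function(strategy, m, degree, anchor_mass = 0.85) {
  stopifnot(m >= 2, degree >= 0)
  strategy <- match.arg(strategy,
                        c("blind", "linear", "anchored_local", "hybrid_nonlocal"))
  concentrated <- function(j) {
    P <- matrix((1 - anchor_mass) / (m - 1), m, m)
    P[, j] <- anchor_mass
    P
  }
  uniform <- matrix(1 / m, m, m)
  if (strategy == "blind") {
    return(replicate(degree + 1, uniform, simplify = FALSE))
  }
  if (degree < 1) {
    abort(sprintf("strategy '%s' requires degree >= 1", strategy))
  }
  if (strategy == "linear") {
    u <- seq(0, 1, length.out = degree + 1)
    return(purrr::map(u, function(w) {
      (1 - w) * concentrated(1) + w * concentrated(m)
    }))
  }
  if (strategy == "anchored_local") {
    # anchors walk 1 -> m through interior patterns in order
    anchors <- round(seq(1, m, length.out = degree + 1))
    return(purrr::map(anchors, concentrated))
  }
  # hybrid_nonlocal: start at 1, end at m, interior supports jump to
  # non-adjacent patterns (alternating far ends of the remaining range)
  anchors <- c(1, rep(NA_integer_, degree - 1), m)
  interior <- setdiff(seq_len(m), c(1, 2, m, m - 1))
  if (length(interior) == 0) interior <- setdiff(seq_len(m), c(1, m))
  if (length(interior) == 0) interior <- c(m, 1)   # m = 2: no interior
  for (i in seq_len(degree - 1)) {
    anchors[i + 1] <- interior[((i - 1) %% length(interior)) + 1]
  }
  purrr::map(anchors, concentrated)
}

#' Random smooth support matrices for recovery studies
#'
#' Draws `degree + 1` row-stochastic matrices as softmax transforms of
#' i.i.d. Gaussian logits with modest spread, so the Lagrange interpolant
#' stays (essentially) inside [0, 1] between the nodes. Support matrices are
#' only identifiable from data when the drifting transition probabilities
#' are not clipped, so parameter-recovery tests use this generator rather
#' than the strongly concentrated strategy presets.
#'
#' @param m Alphabet size.
#' @param degree Drift degree.
#' @param scale SD of the logits (default 0.8; larger = stronger drift).
#' @param seed Integer seed.
#' @return List of `degree + 1` row-stochastic m x m matrices.
#' @export
random_smooth_supports <- function(m, degree, scale = 0.8, seed = 1) {
  with_seed(seed, {
    purrr::map(seq_len(degree + 1), function(i) {
      E <- exp(matrix(rnorm(m * m, 0, scale), m, m))
      E / rowSums(E)
    })
  })
}

#' Default CRP templates for m coordination patterns
#'
#' `m - 1` constant-level CRP curves evenly spaced well inside (-180, 180)
#' plus one expert-like curve sweeping from near anti-phase through in-phase
#' back to near anti-phase (the hallmark of effective breaststroke
#' coordination). Template values keep a margin from +/-180 so that additive
#' phase noise cannot wrap around the circle, which would turn a few degrees
#' of noise into ~360-degree outliers in the Euclidean curve features.
#'
#' @param m Number of patterns.
#' @param L Points per template curve (default 100).
#' @return List of `m` length-`L` numeric vectors (degrees). The expert-like
#'   template is last (pattern `m`).
#' @export
make_crp_templates <- function(m, L = 100) {
  stopifnot(m >= 2)
  levels <- seq(-140, 140, length.out = m - 1)
  flats <- purrr::map(levels, ~rep(.x, L))
  s <- seq(0, 1, length.out = L)
  expert <- -160 + 160 * (1 - abs(2 * s - 1))   # -160 -> 0 -> -160
  c(flats, list(expert))
}

#' Render a label sequence into a 100 Hz joint-angle trace
#'
#' The knee is a fixed-period sinusoid (maximal flexion at every cycle
#' boundary); the elbow is a sinusoid carrying a time-varying phase offset
#' equal to the labelled cycle's CRP template plus i.i.d. Gaussian noise on
#' the phase, so the downstream CRP chain recovers the template. Half a
#' period of padding is added at both ends so all `length(labels)` cycles
#' lie between strictly interior knee maxima; after the standard first/last
#' cycle drop, `length(labels) - 2` cycles survive.
#'
#' @param labels Integer vector of pattern labels (chronological cycles).
#' @param templates List of per-pattern CRP template curves (degrees), as
#'   from [make_crp_templates()]; must cover every label.
#' @param cycle_period Cycle duration in seconds (default 1.25).
#' @param noise_sd SD of Gaussian phase noise in degrees (default 5), split
#'   between a cycle-to-cycle offset and band-limited within-cycle wander.
#' @param sensor_noise_sd SD of broadband white noise added to both angle
#'   channels in degrees (default 0.5); its sub-cutoff part survives the
#'   low-pass filter as a measurement-noise floor.
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz (default 100).
#' @param meta Named list of trial keys (learner, session, trial, speed).
#' @return List with `trace` (a trace tibble), `boundaries` (times of the
#'   knee maxima bounding each cycle) and `labels`.
#' @export
gen_angle_traces <- function(labels, templates, cycle_period = 1.25,
                             noise_sd = 5, sensor_noise_sd = 0.5,
                             seed = 1, fs = 100,
                             meta = list(learner = 1L, session = 1L,
                                         trial = 1L, speed = "low")) {
  stopifnot(cycle_period > 0, noise_sd >= 0)
  if (max(labels) > length(templates) || min(labels) < 1) {
    abort("missing template for a label")
  }
  n_cyc <- length(labels)
  dt <- 1 / fs
  t <- seq(-cycle_period / 2, n_cyc * cycle_period + cycle_period / 2, by = dt)
  omega <- 2 * pi / cycle_period
  # per-sample CRP offset from the labelled cycle's template
  cyc_idx <- pmin(pmax(floor(t / cycle_period) + 1, 1), n_cyc)
  within <- (t - (cyc_idx - 1) * cycle_period) / cycle_period
  within <- pmin(pmax(within, 0), 1)
  L <- length(templates[[1]])
  tem_mat <- do.call(rbind, templates)
  grid_j <- pmin(floor(within * (L - 1)) + 1L, L)
  offset_deg <- tem_mat[cbind(labels[cyc_idx], grid_j)]
  # Motor phase noise with the two time scales real coordination shows:
  # a cycle-to-cycle offset (one draw per cycle) and a band-limited
  # within-cycle wander (white noise smoothed over ~0.3 s). Per-sample
  # white phase noise alone would be annihilated by the 8 Hz low-pass and
  # leave unrealistically clean cycles; offset-only noise would be rank-1
  # across the cycle grid. noise_sd is the total phase SD, split evenly
  # between the two components.
  seeds <- split_seed(seed, 3)
  comp_sd <- noise_sd / sqrt(2)
  cyc_noise <- with_seed(seeds[1], rnorm(n_cyc, 0, comp_sd))
  wander <- with_seed(seeds[2], rnorm(length(t)))
  wwin <- max(1L, round(0.3 * fs))
  wander <- as.numeric(stats::filter(wander, rep(1, wwin) / wwin, sides = 2))
  wander[is.na(wander)] <- 0
  if (sd(wander) > 0) wander <- wander * comp_sd / sd(wander)
  offset_deg <- offset_deg + cyc_noise[cyc_idx] + wander
  # a learner's relative phase evolves continuously: smooth the template
  # switch across cycle boundaries (~0.2 s moving average) instead of
  # leaving a step discontinuity no physiological signal would show
  win <- max(1L, round(0.2 * fs))
  raw <- offset_deg
  offset_deg <- as.numeric(stats::filter(raw, rep(1 / win, win), sides = 2))
  na <- is.na(offset_deg)
  offset_deg[na] <- raw[na]
  # broadband sensor noise on the angle channels (deg); its sub-cutoff part
  # survives the low-pass filter as a realistic measurement-noise floor
  sens <- with_seed(seeds[3],
                    matrix(rnorm(2 * length(t), 0, sensor_noise_sd), ncol = 2))
  knee <- 90 + 30 * cos(omega * t) + sens[, 1]
  elbow <- 90 + 30 * cos(omega * t + offset_deg * pi / 180) + sens[, 2]
  trace <- tibble(
    learner = meta$learner, session = meta$session,
    trial = meta$trial, speed = meta$speed,
    t_s = t - t[1], elbow_deg = elbow, knee_deg = knee
  )
  list(trace = trace,
       boundaries = (0:n_cyc) * cycle_period - t[1],
       labels = labels)
}

#' Noisy exponential session-performance series
#'
#' `f(t) = a * exp(-b * t) + c + N(0, sigma^2)` for sessions t = 1..n.
#'
#' @param a Initial-performance amplitude (Hz).
#' @param b Learning rate (1/session).
#' @param c Asymptotic performance (Hz).
#' @param sigma Noise SD (Hz, >= 0).
#' @param n_sessions Number of sessions (>= 2).
#' @param seed Integer seed.
#' @return Tibble with columns `session` and `freq_hz`.
#' @export
gen_performance_series <- function(a, b, c, sigma, n_sessions = 16, seed = 1) {
  stopifnot(n_sessions >= 2, sigma >= 0)
  t <- seq_len(n_sessions)
  f <- a * exp(-b * t) + c + with_seed(seed, rnorm(n_sessions, 0, sigma))
  tibble(session = t, freq_hz = f)
}

#' Simulate a full synthetic learner
#'
#' Draws a chronological pattern-label sequence from the drifting Markov
#' model defined by a strategy preset, renders matching joint-angle traces
#' (one trial per block of cycles) and an exponential performance series.
#' The defaults mirror a two-month learning protocol: 16 sessions, 5 trials
#' per session, 3-17 cycles per trial, two speed conditions handled by
#' calling this once per condition.
#'
#' @param strategy Strategy preset name (see [make_strategy_supports()]).
#' @param m Number of patterns (default 11).
#' @param degree Drift degree of the generating model (default 3).
#' @param n_sessions,trials_per_session Protocol shape (defaults 16 and 5).
#' @param cycles_per_trial Integer vector or range `c(min, max)` from which
#'   per-trial cycle counts are drawn uniformly (default `c(3, 17)`).
#' @param cycle_period,crp_noise_sd Trace rendering parameters.
#' @param perf_params Named list `a`, `b`, `c`, `sigma` for the performance
#'   series (defaults a = 0.3, b = 0.2, c = 0.5, sigma = 0.02 Hz).
#' @param seed Integer master seed; all randomness derives from it.
#' @param meta Trial keys (learner id, speed label).
#' @param render What observable data to render besides the labels:
#'   `"traces"` (default) renders 100 Hz joint-angle traces through the
#'   full kinematic model; `"curves"` renders per-cycle CRP curves directly
#'   as template + white Gaussian noise on the L-point grid (the condition
#'   under which cluster-count selection by the BIC plateau is well-posed;
#'   see the methods vignette); `"none"` renders labels and performance
#'   only (fastest, for DMM-level studies).
#' @param labels_at Resolution of the drifting chain: `"cycle"` (default)
#'   draws a new pattern every cycle; `"trial"` draws one pattern per trial
#'   and holds it for the whole trial. Cycle-resolution switching renders
#'   transition cycles whose edges blend neighbouring templates, which is
#'   realistic but adds genuine extra cluster structure; trial-resolution
#'   dwell keeps every retained cycle a pure template rendering (the
#'   "separated-template" condition for cluster-count recovery studies).
#' @return List with `labels` (tibble: session, trial, cycle, pattern),
#'   `truth` (supports, templates, perf parameters), `traces` (trace tibble
#'   or NULL) and `performance`.
#' @export
simulate_learner <- function(strategy = "anchored_local", m = 11, degree = 3,
                             n_sessions = 16, trials_per_session = 5,
                             cycles_per_trial = c(3, 17),
                             cycle_period = 1.25, crp_noise_sd = 5,
                             perf_params = list(a = 0.3, b = 0.2,
                                                c = 0.5, sigma = 0.02),
                             seed = 1,
                             meta = list(learner = 1L, speed = "low"),
                             render = c("traces", "curves", "none"),
                             labels_at = c("cycle", "trial")) {
  render <- match.arg(render)
  labels_at <- match.arg(labels_at)
  seeds <- split_seed(seed, 4)
  n_trials <- n_sessions * trials_per_session
  n_per_trial <- with_seed(seeds[1], {
    if (length(cycles_per_trial) == 2) {
      sample(cycles_per_trial[1]:cycles_per_trial[2], n_trials, replace = TRUE)
    } else {
      rep_len(cycles_per_trial, n_trials)
    }
  })
  n_cycles <- sum(n_per_trial)
  supports <- make_strategy_supports(strategy, m, degree)
  if (labels_at == "cycle") {
    model <- new_dmm(supports, n = n_cycles - 1)
    lab_seq <- simulate_dmm(model, n = n_cycles - 1, initial = 1L,
                            seed = seeds[2])
  } else {
    model <- new_dmm(supports, n = n_trials - 1)
    per_trial <- simulate_dmm(model, n = n_trials - 1, initial = 1L,
                              seed = seeds[2])
    lab_seq <- rep(per_trial, times = n_per_trial)
  }
  templates <- make_crp_templates(m)
  sched <- tibble(
    session = rep(rep(seq_len(n_sessions), each = trials_per_session),
                  times = n_per_trial),
    trial = rep(rep(seq_len(trials_per_session), times = n_sessions),
                times = n_per_trial),
    pattern = lab_seq
  ) %>%
    group_by(.data$session, .data$trial) %>%
    mutate(cycle = dplyr::row_number()) %>%
    ungroup()
  traces <- NULL
  curves <- NULL
  if (render == "curves") {
    L <- length(templates[[1]])
    tem_mat <- do.call(rbind, templates)
    noise <- with_seed(seeds[3],
                       matrix(rnorm(n_cycles * L, 0, crp_noise_sd),
                              n_cycles, L))
    curves <- sched %>%
      mutate(learner = meta$learner, speed = meta$speed,
             crp = purrr::map(dplyr::row_number(), function(i) {
               tem_mat[sched$pattern[i], ] + noise[i, ]
             }))
  }
  if (render == "traces") {
    tr_seeds <- split_seed(seeds[3], n_trials)
    idx <- 0
    traces <- sched %>%
      group_by(.data$session, .data$trial) %>%
      tidyr::nest(.key = "cyc") %>%
      ungroup() %>%
      mutate(trace = purrr::pmap(
        list(.data$session, .data$trial, .data$cyc),
        function(se, tr, cyc) {
          idx <<- idx + 1
          gen_angle_traces(cyc$pattern, templates,
                           cycle_period = cycle_period,
                           noise_sd = crp_noise_sd, seed = tr_seeds[idx],
                           meta = list(learner = meta$learner, session = se,
                                       trial = tr, speed = meta$speed))$trace
        })) %>%
      pull("trace") %>%
      bind_rows()
  }
  perf <- gen_performance_series(perf_params$a, perf_params$b, perf_params$c,
                                 perf_params$sigma, n_sessions,
                                 seed = seeds[4])
  list(
    labels = mutate(sched, learner = meta$learner, speed = meta$speed),
    truth = list(supports = supports, templates = templates,
                 perf_params = perf_params, strategy = strategy,
                 m = m, degree = degree),
    traces = traces,
    curves = curves,
    performance = perf
  )
}
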