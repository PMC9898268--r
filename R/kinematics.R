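# From joint-angle time series to per-cycle normalized curves and continuous
# relative phase (CRP). A trace is a tidy tibble with one row per sample:
#   learner, session, trial, speed, t_s, elbow_deg, knee_deg
# and one trial stored contiguously. All operations are grouped per trial.

trace_cols <- c("learner", "session", "trial", "speed", "t_s",
                "elbow_deg", "knee_deg")
trial_keys <- c("learner", "session", "trial", "speed")

validate_trace <- function(data, tol = 0.01) {
  missing <- setdiff(trace_cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("trace is missing columns: ", paste(missing, collapse = ", ")))
  }
  for (g in split(data$t_s, interaction(data[trial_keys], drop = TRUE))) {
    dt <- diff(g)
    if (any(dt <= 0)) abort("time must be strictly increasing within a trial")
    if (length(dt) > 1 && (max(dt) - min(dt)) > tol * median(dt)) {
      abort("non-uniform sampling within a trial")
    }
  }
  invisible(data)
}

# FFT-based analytic signal (positive-frequency doubling); phase in radians.
analytic_phase <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(X * h, inverse = TRUE) / n
  atan2(Im(z), Re(z))
}

lowpass_fourier_vec <- function(x, fs, cutoff) {
  n <- length(x)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  X <- fft(x)
  X[freq > cutoff] <- 0
  Re(fft(X, inverse = TRUE) / n)
}

#' Low-pass Fourier filter for joint-angle traces
#'
#' Hard brick-wall filter in the frequency domain: the signal is Fourier
#' transformed, every bin above the cut-off frequency is zeroed, and the
#' result is transformed back. Applied independently to the elbow and knee
#' channels of every trial. The filter is idempotent and exactly preserves
#' pass-band sinusoids.
#'
#' @param data A trace tibble (see [read_angle_csv()] for the dialect).
#' @param cutoff Cut-off frequency in Hz. Default 8 Hz, appropriate for
#'   gross inter-limb movement at cycle rates of roughly 0.5-1 Hz.
#' @return The trace tibble with filtered `elbow_deg` and `knee_deg`.
#' @examples
#' tr <- tibble::tibble(learner = 1, session = 1, trial = 1, speed = "low",
#'                      t_s = seq(0, 10, by = 0.01))
#' tr$knee_deg <- cos(2 * pi * tr$t_s)
#' tr$elbow_deg <- cos(2 * pi * tr$t_s) + 0.5 * sin(2 * pi * 20 * tr$t_s)
#' filt <- lowpass_fourier(tr, cutoff = 8)
#' max(abs(filt$elbow_deg - cos(2 * pi * tr$t_s)))  # 20 Hz component gone
#' @export
lowpass_fourier <- function(data, cutoff = 8) {
  validate_trace(data)
  data %>%
    group_by(across(all_of(trial_keys))) %>%
    mutate(
      elbow_deg = lowpass_fourier_vec(
        .data$elbow_deg, fs = 1 / median(diff(.data$t_s)), cutoff = cutoff),
      knee_deg = lowpass_fourier_vec(
        .data$knee_deg, fs = 1 / median(diff(.data$t_s)), cutoff = cutoff)
    ) %>%
    ungroup()
}

# Strictly interior local maxima, ties to the earliest index of a plateau,
# then greedy enforcement of a minimum separation keeping the higher peak.
find_interior_maxima <- function(x, t, min_period) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  peaks <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  if (length(peaks) == 0) return(integer(0))
  kept <- peaks[1]
  for (p in peaks[-1]) {
    last <- kept[length(kept)]
    if (t[p] - t[last] >= min_period) {
      kept <- c(kept, p)
    } else if (x[p] > x[last]) {
      kept[length(kept)] <- p
    }
  }
  kept
}

resample_curve <- function(x, L) {
  n <- length(x)
  pos <- 1 + (n - 1) * (0:(L - 1)) / L   # half-open [start, end)
  approx(seq_len(n), x, xout = pos)$y
}

#' Partition a trace into movement cycles
#'
#' A cycle runs from one maximal knee flexion to the next. Boundaries are
#' strictly interior local maxima of the knee angle separated by at least
#' `min_period` seconds; the first and last cycle of every trial are dropped
#' by default (push-off and deceleration artefacts). Each retained cycle's
#' knee and elbow curves are amplitude-normalized to [0, 1] and resampled to
#' `L` points.
#'
#' @param data A (filtered) trace tibble.
#' @param min_period Minimum cycle duration in seconds (default 0.5).
#' @param drop_edges Drop the first and last cycle per trial (default TRUE).
#' @param L Number of resampled points per cycle (default 100).
#' @return A tibble with one row per retained cycle: the trial keys,
#'   `cycle` (1-based chronological index within the trial), `start_idx` /
#'   `end_idx` (half-open sample indices into the trial), `t_start`,
#'   `duration_s`, and list-columns `knee_curve`, `elbow_curve`.
#' @export
segment_cycles <- function(data, min_period = 0.5, drop_edges = TRUE, L = 100) {
  validate_trace(data)
  out <- data %>%
    group_by(across(all_of(trial_keys))) %>%
    tidyr::nest(.key = "samples") %>%
    ungroup() %>%
    mutate(cycles = purrr::map(.data$samples, segment_one_trial,
                               min_period = min_period,
                               drop_edges = drop_edges, L = L)) %>%
    select(-"samples") %>%
    tidyr::unnest("cycles")
  out
}

segment_one_trial <- function(tr, min_period, drop_edges, L) {
  pk <- find_interior_maxima(tr$knee_deg, tr$t_s, min_period)
  n_cyc <- length(pk) - 1
  if (drop_edges) {
    keep <- if (n_cyc > 2) 2:(n_cyc - 1) else integer(0)
  } else {
    keep <- seq_len(max(n_cyc, 0))
  }
  if (length(keep) == 0) abort("no cycles: too few interior knee maxima")
  rows <- purrr::map(keep, function(j) {
    s <- pk[j]; e <- pk[j + 1]
    knee <- resample_curve(tr$knee_deg[s:e], L)
    elbow <- resample_curve(tr$elbow_deg[s:e], L)
    rng_k <- range(knee); rng_e <- range(elbow)
    if (diff(rng_k) < 1e-9 || diff(rng_e) < 1e-9) {
      warn(sprintf("degenerate flat cycle at t = %.2f s excluded", tr$t_s[s]))
      return(NULL)
    }
    tibble(
      cycle = j, start_idx = s, end_idx = e,
      t_start = tr$t_s[s], duration_s = tr$t_s[e] - tr$t_s[s],
      knee_curve = list((knee - rng_k[1]) / diff(rng_k)),
      elbow_curve = list((elbow - rng_e[1]) / diff(rng_e))
    )
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) abort("no cycles: all cycles degenerate")
  bind_rows(rows)
}

#' Continuous relative phase between two joint-angle signals
#'
#' Each signal is mean-centered and max-abs normalized, its instantaneous
#' phase obtained from the FFT analytic signal, and the CRP is the wrapped
#' phase difference `first - second` in degrees, in (-180, 180]. Computing
#' the phase on the whole signal (rather than per cycle) avoids Hilbert edge
#' artefacts at interior cycle boundaries.
#'
#' @param first,second Numeric vectors of equal length (e.g. elbow and knee
#'   angles of one trial).
#' @return Numeric vector of CRP values in degrees.
#' @export
crp_signal <- function(first, second) {
  stopifnot(length(first) == length(second))
  if (sd(first) < 1e-12 || sd(second) < 1e-12) {
    abort("undefined phase: constant channel")
  }
  center <- function(x) { x <- x - mean(x); x / max(abs(x)) }
  ph1 <- analytic_phase(center(first))
  ph2 <- analytic_phase(center(second))
  wrap_deg((ph1 - ph2) * 180 / pi)
}

#' Per-cycle continuous relative phase curves
#'
#' Computes the elbow-minus-knee CRP on each whole trial of `data`, slices
#' it at the cycle boundaries in `cycles` (from [segment_cycles()]), and
#' resamples each slice to `L` points. Resampling interpolates the sine and
#' cosine of the CRP so that wrap-around at +/-180 degrees cannot create
#' spurious intermediate values.
#'
#' @param data The (filtered) trace tibble the cycles were segmented from.
#' @param cycles Cycle tibble from [segment_cycles()].
#' @param L Points per resampled CRP curve (default 100).
#' @return `cycles` with an added list-column `crp` (length-`L` numeric,
#'   degrees in (-180, 180]).
#' @export
compute_crp <- function(data, cycles, L = 100) {
  validate_trace(data)
  nested <- data %>%
    group_by(across(all_of(trial_keys))) %>%
    tidyr::nest(.key = "samples") %>%
    ungroup()
  cyc <- cycles %>%
    group_by(across(all_of(trial_keys))) %>%
    tidyr::nest(.key = "cyc") %>%
    ungroup() %>%
    left_join(nested, by = trial_keys)
  if (any(purrr::map_lgl(cyc$samples, is.null))) {
    abort("cycles reference trials absent from the trace")
  }
  out <- cyc %>%
    mutate(cyc = purrr::map2(.data$cyc, .data$samples, function(cc, tr) {
      crp_full <- crp_signal(tr$elbow_deg, tr$knee_deg)
      cc$crp <- purrr::map2(cc$start_idx, cc$end_idx, function(s, e) {
        seg <- crp_full[s:e]
        wrap_deg(atan2(resample_curve(sin(seg * pi / 180), L),
                       resample_curve(cos(seg * pi / 180), L)) * 180 / pi)
      })
      cc
    })) %>%
    select(-"samples") %>%
    tidyr::unnest("cyc")
  out
}

#' Unwrap a CRP curve along its own continuity
#'
#' Chooses the continuous branch of a wrapped phase curve (no +/-360 jumps
#' between neighbouring samples) and recentres it so its mean lies in
#' (-180, 180]. Curves hovering near the +/-180 wrap line otherwise split
#' into spurious far-apart groups under the Euclidean metric.
#'
#' @param x Wrapped CRP values (degrees) of one cycle.
#' @return Unwrapped, recentred curve (may exceed +/-180 pointwise).
#' @export
unwrap_deg <- function(x) {
  u <- cumsum(c(x[1], wrap_deg(diff(x))))
  u - 360 * round(mean(u) / 360)
}

#' Stack per-cycle CRP curves into a feature matrix
#'
#' Each curve is unwrapped along its own continuity ([unwrap_deg()]) before
#' stacking, so the Euclidean metric used by the clustering respects phase
#' circularity.
#'
#' @param crp_cycles Tibble with a `crp` list-column, in chronological
#'   order.
#' @param unwrap Apply [unwrap_deg()] per curve (default TRUE).
#' @return An n-cycles x L numeric matrix.
#' @export
crp_matrix <- function(crp_cycles, unwrap = TRUE) {
  M <- do.call(rbind, crp_cycles$crp)
  if (unwrap) {
    M <- t(apply(M, 1, unwrap_deg))
  }
  M
}
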