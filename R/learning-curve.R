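# Exponential learning curves for session performance. Stroke frequency at
# a fixed swimming speed falls as technique improves; the decay
#   f(t) = a * exp(-b * t) + c
# over session number t captures an early rapid gain (rate b, 1/session)
# toward an asymptote c (Hz), with a + c the pre-practice level.

#' Per-session mean performance
#'
#' @param data Tibble with columns `session` and `freq_hz` (one row per
#'   cycle or trial).
#' @return Tibble with one row per session: `session`, `freq_hz` (mean),
#'   `n_obs`; sessions in increasing order.
#' @export
session_means <- function(data) {
  stopifnot(all(c("session", "freq_hz") %in% names(data)))
  if (any(!is.finite(data$freq_hz))) abort("non-finite frequency values")
  data %>%
    group_by(.data$session) %>%
    summarise(freq_hz = mean(.data$freq_hz), n_obs = dplyr::n(),
              .groups = "drop") %>%
    arrange(.data$session)
}

#' Fit the exponential learning curve f(t) = a exp(-b t) + c
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a log-linear
#' initialization: `c0 = min(f)`, then `log(f - c0 + eps)` regressed on `t`
#' gives `a0` and `b0`. Five jittered starts on `b0` guard against the flat
#' local minimum; bounds `b` in [0, 10], `c` in [0, max(f)]. Goodness of fit
#' is `r2 = 1 - SS_res / SS_tot` and `rmse = sqrt(SS_res / n)`.
#'
#' @param perf Tibble with columns `session` and `freq_hz` (e.g. from
#'   [session_means()]).
#' @param seed Seed for the jittered restarts (default 1).
#' @return A `"learning_curve_fit"`: list with `a`, `b`, `c`, `r2`, `rmse`,
#'   `converged`, `degenerate`, `n_sessions`, `data`, `fitted`.
#' @examples
#' perf <- gen_performance_series(0.3, 0.2, 0.5, sigma = 0, n_sessions = 16)
#' fit_exponential(perf)
#' @export
fit_exponential <- function(perf, seed = 1) {
  stopifnot(all(c("session", "freq_hz") %in% names(perf)))
  t <- as.numeric(perf$session)
  f <- perf$freq_hz
  n <- length(t)
  if (n < 4) abort("need at least 4 sessions to fit 3 parameters")
  if (sd(f) < 1e-12) {
    return(new_lc_fit(a = 0, b = 0, c = mean(f), t = t, f = f,
                      converged = TRUE, degenerate = TRUE))
  }
  c0 <- min(f)
  eps <- max(1e-4, 1e-3 * diff(range(f)))
  lf <- log(f - c0 + eps)
  sl <- coef(stats::lm(lf ~ t))
  b0 <- max(min(-sl[2], 10), 1e-3)
  a0 <- max(exp(sl[1]), eps)
  jit <- with_seed(seed, runif(4, 0.5, 1.5))
  starts <- c(1, jit)
  fits <- purrr::map(starts, function(j) {
    tryCatch(
      minpack.lm::nlsLM(
        f ~ a * exp(-b * t) + c,
        start = list(a = a0, b = b0 * j, c = c0),
        lower = c(a = -Inf, b = 0, c = 0),
        upper = c(a = Inf, b = 10, c = max(f)),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) {
    return(new_lc_fit(a = a0, b = b0, c = c0, t = t, f = f,
                      converged = FALSE, degenerate = FALSE))
  }
  ssr <- purrr::map_dbl(fits, function(ft) sum(resid(ft)^2))
  best <- fits[[which.min(ssr)]]
  cf <- coef(best)
  new_lc_fit(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
             t = t, f = f, converged = TRUE, degenerate = FALSE)
}

new_lc_fit <- function(a, b, c, t, f, converged, degenerate) {
  fitted <- a * exp(-b * t) + c
  ss_res <- sum((f - fitted)^2)
  ss_tot <- sum((f - mean(f))^2)
  structure(
    list(a = a, b = b, c = c,
         r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         rmse = sqrt(ss_res / length(f)),
         converged = converged, degenerate = degenerate,
         n_sessions = length(t),
         data = tibble(session = t, freq_hz = f, fitted = fitted)),
    class = "learning_curve_fit"
  )
}

#' @export
print.learning_curve_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential learning curve: f(t) = %.4f * exp(-%.4f t) + %.4f\n",
    x$a, x$b, x$c))
  cat(sprintf("  r2 = %.4f, RMSE = %.4g Hz, %d sessions%s%s\n",
              x$r2, x$rmse, x$n_sessions,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (x$degenerate) " [degenerate flat fit]" else ""))
  invisible(x)
}

#' @export
tidy.learning_curve_fit <- function(x, ...) {
  tibble(term = c("a", "b", "c"),
         estimate = c(x$a, x$b, x$c),
         unit = c("Hz", "1/session", "Hz"))
}

#' @export
glance.learning_curve_fit <- function(x, ...) {
  tibble(a = x$a, b = x$b, c = x$c, r2 = x$r2, rmse = x$rmse,
         n_sessions = x$n_sessions, converged = x$converged,
         degenerate = x$degenerate)
}
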