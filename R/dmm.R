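# Order-1 drifting Markov models (DMM) with polynomial drift. The transition
# matrix at relative position u = t/n is the Lagrange interpolation of d+1
# row-stochastic support matrices anchored at equispaced nodes 0, 1/d, .., 1:
#   Pi_u = sum_i P_i * L_i(u).
# For degree <= 1 the interpolant is a convex combination and automatically
# stochastic; for degree >= 2 entries can leave [0,1] between nodes, so
# evaluated matrices are clipped and row-renormalized, and the fit penalizes
# negative interpolants on the data grid.

PROB_FLOOR <- 1e-12

#' Construct a drifting Markov model from support matrices
#'
#' @param supports List of `degree + 1` row-stochastic m x m matrices.
#' @param n Length (number of transitions) of the sequence the model is
#'   indexed over; positions run t = 0..n.
#' @param alphabet Optional character vector of state names (length m).
#' @return An object of class `"dmm"`.
#' @export
new_dmm <- function(supports, n, alphabet = NULL) {
  stopifnot(is.list(supports), length(supports) >= 1, n >= 1)
  m <- nrow(supports[[1]])
  for (P in supports) {
    stopifnot(nrow(P) == m, ncol(P) == m)
    if (max(abs(rowSums(P) - 1)) > 1e-9 || min(P) < -1e-12) {
      abort("support matrices must be row-stochastic")
    }
  }
  structure(
    list(m = m, degree = length(supports) - 1, order = 1L, n = as.integer(n),
         supports = supports, alphabet = alphabet),
    class = "dmm"
  )
}

#' @export
print.dmm <- function(x, ...) {
  cat(sprintf("Drifting Markov model: m = %d states, degree %d, n = %d\n",
              x$m, x$degree, x$n))
  if (!is.null(x$loglik)) {
    cat(sprintf("  logLik = %.3f, npar = %d, AIC = %.1f, BIC = %.1f\n",
                x$loglik, x$npar, x$aic, x$bic))
  }
  invisible(x)
}

# Coerce labels input (integer vector, character states, or a tibble with a
# `pattern` column) to an integer sequence plus alphabet.
as_label_seq <- function(labels, m = NULL, alphabet = NULL) {
  if (is.data.frame(labels)) labels <- labels$pattern
  if (is.character(labels)) {
    if (length(labels) == 1 && nchar(labels) > 1) {
      labels <- strsplit(labels, "")[[1]]
    }
    alphabet <- alphabet %||% sort(unique(labels))
    x <- match(labels, alphabet)
    if (anyNA(x)) abort("labels outside the declared alphabet")
  } else {
    x <- as.integer(labels)
    if (any(x < 1)) abort("integer labels must be >= 1")
    if (!is.null(alphabet)) {
      if (max(x) > length(alphabet)) abort("labels outside the declared alphabet")
    }
  }
  m <- m %||% (if (!is.null(alphabet)) length(alphabet) else max(x))
  if (max(x) > m) abort("labels outside the declared alphabet")
  list(x = x, m = as.integer(m), alphabet = alphabet)
}

#' Transition matrix of a DMM at a sequence position
#'
#' Lagrange interpolation of the support matrices at relative position
#' `t / n`, clipped to [0, 1] and row-renormalized (a no-op for degree <= 1).
#'
#' @param model A `"dmm"` object.
#' @param t Position in `[0, n]` (may be fractional).
#' @return An m x m row-stochastic matrix.
#' @export
transition_at <- function(model, t) {
  if (t < 0 || t > model$n) abort("t outside [0, n]")
  w <- lagrange_weights(t / model$n, model$degree)[1, ]
  P <- Reduce(`+`, purrr::map2(model$supports, w, `*`))
  normalize_rows(pmin(pmax(P, 0), 1))
}

# Raw interpolated transition rows along the observed transitions:
# returns the n x m matrix whose t-th row is Pi_{t/n}[x_{t-1}, ] (unclipped).
interp_obs_rows <- function(supports, degree, x, n) {
  W <- lagrange_weights(seq_len(n) / n, degree)
  prev <- x[seq_len(n)]
  R <- matrix(0, n, ncol(supports[[1]]))
  for (i in seq_len(degree + 1)) {
    R <- R + W[, i] * supports[[i]][prev, , drop = FALSE]
  }
  R
}

# Exact log-likelihood under clip-and-renormalize evaluation, floored at
# PROB_FLOOR. Attaches a diagnostic tibble of floored transitions.
dmm_loglik <- function(supports, degree, x) {
  n <- length(x) - 1
  R <- interp_obs_rows(supports, degree, x, n)
  Rc <- pmin(pmax(R, 0), 1)
  rs <- rowSums(Rc)
  rs[rs <= 0] <- 1
  p <- Rc[cbind(seq_len(n), x[-1])] / rs
  bad <- which(p <= PROB_FLOOR)
  ll <- sum(log(pmax(p, PROB_FLOOR)))
  attr(ll, "floored") <- if (length(bad) > 0) {
    tibble(t = bad, from = x[bad], to = x[bad + 1])
  } else {
    NULL
  }
  ll
}

# Degree-0 maximum-likelihood estimate: transition-count ratios, with
# `alpha` Laplace pseudo-counts (alpha = 0 gives the exact MLE; source
# states never observed get uniform rows either way).
count_mle <- function(x, m, alpha = 0) {
  counts <- matrix(0, m, m)
  for (t in seq_len(length(x) - 1)) {
    counts[x[t], x[t + 1]] <- counts[x[t], x[t + 1]] + 1
  }
  normalize_rows(counts + alpha)
}

# One source-row maximum-likelihood fit: softmax-parameterized support rows,
# BFGS with analytic gradient. W: |T_u| x (d+1) Lagrange weights at the
# observed times; vt: targets; lambda penalizes negative interpolants.
fit_row_ml <- function(W, vt, m, theta0, lambda = 100, maxit = 500) {
  d1 <- ncol(W)
  nt <- nrow(W)
  softmax_rows <- function(TH) {
    E <- exp(TH - apply(TH, 1, max))
    E / rowSums(E)
  }
  obj <- function(th) {
    P <- softmax_rows(matrix(th, d1, m))
    R <- W %*% P
    pobs <- R[cbind(seq_len(nt), vt)]
    -(sum(log(pmax(pobs, PROB_FLOOR))) - lambda * sum(pmin(R, 0)^2))
  }
  grad <- function(th) {
    P <- softmax_rows(matrix(th, d1, m))
    R <- W %*% P
    pobs <- R[cbind(seq_len(nt), vt)]
    G <- matrix(0, nt, m)
    act <- pobs > PROB_FLOOR
    G[cbind(which(act), vt[act])] <- 1 / pobs[act]
    G <- G - 2 * lambda * pmin(R, 0)
    dP <- crossprod(W, G)
    dTH <- P * (dP - rowSums(dP * P))
    -as.vector(dTH)
  }
  res <- optim(as.vector(theta0), obj, grad, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  softmax_rows(matrix(res$par, d1, m))
}

# Least-squares estimator: regress target indicators on the Lagrange basis
# per source row, then project support rows onto the probability simplex.
fit_ls <- function(x, m, degree) {
  n <- length(x) - 1
  W_all <- lagrange_weights(seq_len(n) / n, degree)
  prev <- x[seq_len(n)]
  supports <- replicate(degree + 1, matrix(1 / m, m, m), simplify = FALSE)
  for (u in seq_len(m)) {
    idx <- which(prev == u)
    if (length(idx) == 0) next
    W <- W_all[idx, , drop = FALSE]
    Y <- matrix(0, length(idx), m)
    Y[cbind(seq_along(idx), x[idx + 1])] <- 1
    B <- tryCatch(solve(crossprod(W) + 1e-8 * diag(degree + 1), crossprod(W, Y)),
                  error = function(e) matrix(1 / m, degree + 1, m))
    for (i in seq_len(degree + 1)) {
      supports[[i]][u, ] <- project_simplex(B[i, ])
    }
  }
  supports
}

#' Fit a drifting Markov model to a label sequence
#'
#' Maximum-likelihood estimation of the `degree + 1` support matrices under
#' row-simplex constraints. Degree 0 reduces exactly to the classic
#' transition-count MLE. For degree >= 1 each source state's rows are
#' optimized jointly by quasi-Newton ascent on the floored log-likelihood of
#' the Lagrange-interpolated transition probabilities (softmax
#' parameterization keeps rows on the simplex; negative interpolants on the
#' data grid are penalized). The final model is chosen by exact evaluated
#' log-likelihood among the optimized fit, the replicated degree-0 MLE, and
#' (for degree >= 2) the embedded degree-1 fit, so nested-degree likelihood
#' ordering holds by construction.
#'
#' @param labels Integer vector, character vector (e.g. nucleotides), single
#'   string, or a tibble with a `pattern` column; chronological order.
#' @param degree Polynomial drift degree (>= 0).
#' @param m Alphabet size; defaults to `max(labels)` so patterns a learner
#'   never visited can still be represented by passing the global K.
#' @param method `"ml"` (default) or `"ls"` (least-squares estimator).
#' @param alpha Laplace pseudo-count for the degree-0 initializer of the
#'   degree >= 1 optimization (default 0.5). The degree-0 fit itself is the
#'   unsmoothed count MLE.
#' @param alphabet Optional state names for character input.
#' @param maxit BFGS iteration cap per source row (default 500).
#' @return A fitted `"dmm"` object with `loglik`, `npar`, `aic`, `bic`.
#' @examples
#' fit_dmm(c(1, 1, 2, 1, 2, 2), degree = 0)$supports[[1]]
#' @export
fit_dmm <- function(labels, degree, m = NULL, method = c("ml", "ls"),
                    alpha = 0.5, alphabet = NULL, maxit = 500) {
  method <- match.arg(method)
  ls0 <- as_label_seq(labels, m = m, alphabet = alphabet)
  x <- ls0$x
  m <- ls0$m
  n <- length(x) - 1
  if (n < degree + 1) abort("sequence shorter than degree + 1 transitions")
  if (degree == 0) {
    supports <- list(count_mle(x, m, alpha = 0))
    return(finish_dmm(supports, x, m, 0, method = "counts",
                      alphabet = ls0$alphabet))
  }
  candidates <- list()
  if (method == "ls") {
    candidates$ls <- fit_ls(x, m, degree)
  } else {
    P0 <- count_mle(x, m, alpha = alpha)
    W_all <- lagrange_weights(seq_len(n) / n, degree)
    prev <- x[seq_len(n)]
    supports <- replicate(degree + 1, P0, simplify = FALSE)
    for (u in unique(prev)) {
      idx <- which(prev == u)
      theta0 <- matrix(rep(log(P0[u, ]), each = degree + 1), degree + 1, m)
      Pu <- fit_row_ml(W_all[idx, , drop = FALSE], x[idx + 1], m, theta0,
                       maxit = maxit)
      for (i in seq_len(degree + 1)) supports[[i]][u, ] <- Pu[i, ]
    }
    candidates$ml <- supports
  }
  # degree-0 embedding (all supports equal) guarantees LL(d) >= LL(0)
  candidates$const <- replicate(degree + 1, count_mle(x, m, alpha = 0),
                                simplify = FALSE)
  if (degree >= 2) {
    # embed the degree-1 fit: a linear drift is reproduced exactly by
    # Lagrange interpolation through any >= 2 nodes
    d1 <- fit_dmm(x, degree = 1, m = m, method = method, alpha = alpha,
                  maxit = maxit)
    nodes <- seq(0, 1, length.out = degree + 1)
    candidates$embed_d1 <- purrr::map(nodes, function(u) {
      (1 - u) * d1$supports[[1]] + u * d1$supports[[2]]
    })
  }
  lls <- purrr::map_dbl(candidates, ~as.numeric(dmm_loglik(.x, degree, x)))
  best <- candidates[[which.max(lls)]]
  finish_dmm(best, x, m, degree, method = method, alphabet = ls0$alphabet)
}

finish_dmm <- function(supports, x, m, degree, method, alphabet = NULL) {
  model <- new_dmm(supports, n = length(x) - 1, alphabet = alphabet)
  ll <- dmm_loglik(supports, degree, x)
  model$loglik <- as.numeric(ll)
  model$floored <- attr(ll, "floored")
  model$npar <- (degree + 1) * m * (m - 1)
  model$aic <- -2 * model$loglik + 2 * model$npar
  model$bic <- -2 * model$loglik + model$npar * log(model$n)
  model$method <- method
  model$x0 <- x[1]
  model
}

#' Information criteria of a DMM on a sequence
#'
#' Exact log-likelihood under the drifting transition matrices (evaluated
#' with clip-and-renormalize and a 1e-12 probability floor), with
#' `npar = (d + 1) * m * (m - 1)`, `AIC = -2 LL + 2 npar`,
#' `BIC = -2 LL + npar log(n)` (smaller is better). Observed transitions
#' whose probability hit the floor are listed in the `floored` attribute.
#'
#' @param model A `"dmm"` object.
#' @param labels Sequence to score (same alphabet conventions as
#'   [fit_dmm()]).
#' @return One-row tibble: `loglik`, `npar`, `aic`, `bic`, `n_floored`.
#' @export
information_criteria <- function(model, labels) {
  ls0 <- as_label_seq(labels, m = model$m, alphabet = model$alphabet)
  ll <- dmm_loglik(model$supports, model$degree, ls0$x)
  n <- length(ls0$x) - 1
  npar <- (model$degree + 1) * model$m * (model$m - 1)
  floored <- attr(ll, "floored")
  out <- tibble(
    loglik = as.numeric(ll), npar = npar,
    aic = -2 * as.numeric(ll) + 2 * npar,
    bic = -2 * as.numeric(ll) + npar * log(n),
    n_floored = if (is.null(floored)) 0L else nrow(floored)
  )
  attr(out, "floored") <- floored
  out
}

#' Probability of appearance of each pattern along the sequence
#'
#' Propagates an initial distribution through the drifting transition
#' matrices: `p_t = p_{t-1} %*% Pi_{t/n}` for t = 1..n.
#'
#' @param model A `"dmm"` object.
#' @param p0 Initial distribution over the m states (sums to 1). Defaults to
#'   the indicator of the fitted sequence's first label when available.
#' @return An `(n + 1) x m` matrix; row t + 1 is the distribution at
#'   position t. Rows sum to 1.
#' @export
appearance_probabilities <- function(model, p0 = NULL) {
  if (is.null(p0)) {
    if (is.null(model$x0)) abort("p0 required for an unfitted model")
    p0 <- replace(numeric(model$m), model$x0, 1)
  }
  if (length(p0) != model$m || abs(sum(p0) - 1) > 1e-8 || min(p0) < 0) {
    abort("p0 must be a distribution over the m states")
  }
  n <- model$n
  out <- matrix(NA_real_, n + 1, model$m)
  out[1, ] <- p0
  for (t in seq_len(n)) {
    out[t + 1, ] <- as.numeric(out[t, ] %*% transition_at(model, t))
  }
  out
}

#' Simulate a label sequence from a DMM
#'
#' @param model A `"dmm"` object.
#' @param n Number of transitions to draw (sequence length `n + 1`).
#' @param initial Initial state in 1..m.
#' @param seed Integer seed.
#' @return Integer vector of length `n + 1`.
#' @export
simulate_dmm <- function(model, n, initial, seed = 1) {
  initial <- as.integer(initial)
  if (initial < 1 || initial > model$m) abort("invalid initial state")
  W <- lagrange_weights(seq_len(n) / n, model$degree)
  with_seed(seed, {
    x <- integer(n + 1)
    x[1] <- initial
    for (t in seq_len(n)) {
      row <- numeric(model$m)
      for (i in seq_len(model$degree + 1)) {
        row <- row + W[t, i] * model$supports[[i]][x[t], ]
      }
      row <- pmin(pmax(row, 0), 1)
      row <- row / sum(row)
      x[t + 1] <- sample.int(model$m, 1, prob = row)
    }
    x
  })
}

#' @export
tidy.dmm <- function(x, ...) {
  purrr::imap_dfr(x$supports, function(P, i) {
    tibble(
      support = i - 1L,
      node = (i - 1) / max(x$degree, 1),
      from = rep(seq_len(x$m), times = x$m),
      to = rep(seq_len(x$m), each = x$m),
      probability = as.vector(P)
    )
  })
}

#' @export
glance.dmm <- function(x, ...) {
  tibble(m = x$m, degree = x$degree, n = x$n,
         loglik = x$loglik %||% NA_real_, npar = x$npar %||% NA_integer_,
         aic = x$aic %||% NA_real_, bic = x$bic %||% NA_real_)
}
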