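# Shared numerical helpers: angle wrapping, circular statistics, seeded RNG
# scoping, Lagrange interpolation basis, simplex projection.

#' Wrap angles into (-180, 180]
#'
#' Relative-phase values are only defined modulo 360 degrees; the package
#' convention maps every angle into the half-open interval (-180, 180], so
#' that anti-phase coordination reads +180 and in-phase reads 0.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector of the same length, all values in (-180, 180].
#' @examples
#' wrap_deg(c(-180, 0, 190, 540))
#' @export
wrap_deg <- function(x) {
  w <- ((x %% 360) + 360) %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Circular mean of angles in degrees
#'
#' @param x Angles in degrees.
#' @return Scalar circular mean in (-180, 180].
#' @export
circ_mean_deg <- function(x) {
  r <- x * pi / 180
  wrap_deg(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

# Evaluate a seeded expression without touching the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive `n` independent child seeds from one master seed. All randomness in
# the package flows through this so a single integer reproduces a whole run.
split_seed <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Lagrange basis weights over equispaced nodes 0, 1/d, ..., 1 evaluated at u.
# Returns a length(u) x (d+1) matrix; rows sum to 1 (partition of unity).
lagrange_weights <- function(u, degree) {
  stopifnot(degree >= 0)
  if (degree == 0) {
    return(matrix(1, nrow = length(u), ncol = 1))
  }
  nodes <- seq(0, 1, length.out = degree + 1)
  W <- matrix(NA_real_, nrow = length(u), ncol = degree + 1)
  for (i in seq_along(nodes)) {
    others <- nodes[-i]
    num <- rep(1, length(u))
    for (o in others) num <- num * (u - o)
    W[, i] <- num / prod(nodes[i] - others)
  }
  W
}

# Euclidean projection of a vector onto the probability simplex
# (Duchi et al.'s sorted-threshold algorithm).
project_simplex <- function(v) {
  m <- length(v)
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_len(m) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

# Row-normalize a non-negative matrix; all-zero rows become uniform.
normalize_rows <- function(P) {
  rs <- rowSums(P)
  zero <- rs <= 0
  if (any(zero)) {
    P[zero, ] <- 1 / ncol(P)
    rs[zero] <- 1
  }
  P / rs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
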