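# The quantity-of-exploration statistic: per coordination pattern, the
# average distance between the degree-1 (linear drift) and degree-3 DMM
# descriptions of the same label sequence, expressed in percent. A large
# distance means the pattern's appearance probability fluctuated non-linearly
# during learning (an anchor point that was deeply explored then abandoned);
# a near-zero distance means linear appearance/disappearance.

#' Per-pattern quantity of exploration between two DMM fits
#'
#' Two readings of the distance are implemented:
#' \describe{
#'   \item{appearance (default)}{`Q_k = 100 / (n + 1) * sum_t |p_t^{(3)}(k) -
#'     p_t^{(1)}(k)|`, the mean absolute gap between the two models'
#'     probability-of-appearance curves (from
#'     [appearance_probabilities()]).}
#'   \item{column}{`Q_k = 100 / n * sum_t sqrt(mean_u (Pi3(u,k) -
#'     Pi1(u,k))^2)`, the mean Euclidean distance between the k-th columns of
#'     the two drifting transition matrices (probability of transiting
#'     toward pattern k).}
#' }
#' Both are symmetric in the two models and bounded by 100.
#'
#' @param model_d1,model_d3 Fitted `"dmm"` objects on the same sequence
#'   (same `m` and `n`); conventionally degrees 1 and 3.
#' @param p0 Initial distribution for appearance mode; defaults to the
#'   indicator of the fitted sequence's first label.
#' @param mode `"appearance"` (default) or `"column"`.
#' @return Tibble with columns `pattern` and `q_percent`.
#' @export
exploration_quantity <- function(model_d1, model_d3, p0 = NULL,
                                 mode = c("appearance", "column")) {
  mode <- match.arg(mode)
  if (model_d1$m != model_d3$m || model_d1$n != model_d3$n) {
    abort("models must share the alphabet size m and sequence length n")
  }
  m <- model_d1$m; n <- model_d1$n
  if (mode == "appearance") {
    if (is.null(p0) && !is.null(model_d1$x0)) {
      p0 <- replace(numeric(m), model_d1$x0, 1)
    }
    p1 <- appearance_probabilities(model_d1, p0)
    p3 <- appearance_probabilities(model_d3, p0)
    q <- 100 * colMeans(abs(p3 - p1))
  } else {
    acc <- numeric(m)
    for (t in seq_len(n)) {
      d <- transition_at(model_d3, t) - transition_at(model_d1, t)
      acc <- acc + sqrt(colMeans(d^2))
    }
    q <- 100 * acc / n
  }
  tibble(pattern = seq_len(m), q_percent = q)
}

#' Summarise an exploration profile for one learner and condition
#'
#' @param q Tibble from [exploration_quantity()] (or a numeric vector of
#'   per-pattern percentages).
#' @param labels The chronological label sequence the models were fitted on
#'   (vector or tibble with a `pattern` column).
#' @return An `"exploration_profile"`: list with `per_pattern` (pattern,
#'   q_percent, visited), `n_visited`, and `sd_q` (sample SD of Q over all
#'   m patterns, never-visited ones included with their computed Q).
#' @export
exploration_summary <- function(q, labels) {
  if (is.data.frame(q)) {
    qv <- q$q_percent
  } else {
    qv <- as.numeric(q)
  }
  if (length(labels) == 0 ||
      (is.data.frame(labels) && nrow(labels) == 0)) {
    abort("empty label sequence")
  }
  x <- as_label_seq(labels, m = length(qv))$x
  visited <- seq_along(qv) %in% unique(x)
  structure(
    list(
      per_pattern = tibble(pattern = seq_along(qv), q_percent = qv,
                           visited = visited),
      n_visited = sum(visited),
      sd_q = sd(qv)
    ),
    class = "exploration_profile"
  )
}

#' @export
print.exploration_profile <- function(x, ...) {
  cat(sprintf("Exploration profile: %d of %d patterns visited, SD(Q) = %.2f%%\n",
              x$n_visited, nrow(x$per_pattern), x$sd_q))
  print(x$per_pattern)
  invisible(x)
}

#' @export
tidy.exploration_profile <- function(x, ...) {
  x$per_pattern
}

#' @export
glance.exploration_profile <- function(x, ...) {
  tibble(n_patterns = nrow(x$per_pattern), n_visited = x$n_visited,
         mean_q = mean(x$per_pattern$q_percent),
         max_q = max(x$per_pattern$q_percent), sd_q = x$sd_q)
}

#' Quantity of exploration for one label sequence
#'
#' Convenience wrapper: fits the degree-1 and degree-3 models to a
#' chronological label sequence and returns the exploration profile.
#'
#' @inheritParams fit_dmm
#' @param mode Distance mode, see [exploration_quantity()].
#' @param ... Passed to [fit_dmm()].
#' @return An `"exploration_profile"` with the two fitted models attached as
#'   attributes `model_d1` and `model_d3`.
#' @export
explore_sequence <- function(labels, m = NULL, mode = "appearance", ...) {
  d1 <- fit_dmm(labels, degree = 1, m = m, ...)
  d3 <- fit_dmm(labels, degree = 3, m = m, ...)
  q <- exploration_quantity(d1, d3, mode = mode)
  out <- exploration_summary(q, labels)
  attr(out, "model_d1") <- d1
  attr(out, "model_d3") <- d3
  out
}
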