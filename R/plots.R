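# Diagnostic plots, ggplot2 throughout.

#' Plot the probability-of-appearance trajectories of a DMM
#'
#' One line per pattern: `p_t(k)` propagated through the drifting
#' transition matrices.
#'
#' @param object A fitted `"dmm"`.
#' @param p0 Initial distribution (default: first-label indicator).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dmm <- function(object, p0 = NULL, ...) {
  P <- appearance_probabilities(object, p0)
  df <- as_tibble(as.data.frame(P), .name_repair = ~paste0("p", seq_len(object$m))) %>%
    mutate(cycle = dplyr::row_number() - 1L) %>%
    tidyr::pivot_longer(-"cycle", names_to = "pattern", values_to = "prob",
                        names_prefix = "p")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$prob,
                                   colour = .data$pattern)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle", y = "probability of appearance",
                  colour = "pattern",
                  title = sprintf("Drifting Markov model (degree %d)",
                                  object$degree)) +
    ggplot2::theme_minimal()
}

#' Plot an exploration profile
#'
#' Bar chart of the per-pattern quantity of exploration; never-visited
#' patterns are hollow, following the convention of flagging rather than
#' zeroing them.
#'
#' @param object An `"exploration_profile"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.exploration_profile <- function(object, ...) {
  df <- object$per_pattern
  ggplot2::ggplot(df, ggplot2::aes(x = base::factor(.data$pattern),
                                   y = .data$q_percent,
                                   alpha = .data$visited)) +
    ggplot2::geom_col(fill = "steelblue", colour = "grey30") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3),
                                guide = "none") +
    ggplot2::labs(x = "coordination pattern", y = "quantity of exploration (%)",
                  title = sprintf("Exploration: %d/%d patterns visited, SD = %.1f%%",
                                  object$n_visited, nrow(df), object$sd_q)) +
    ggplot2::theme_minimal()
}

#' Plot an exponential learning-curve fit
#'
#' @param object A `"learning_curve_fit"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.learning_curve_fit <- function(object, ...) {
  grid <- tibble(
    session = seq(min(object$data$session), max(object$data$session),
                  length.out = 200))
  grid$fitted <- object$a * exp(-object$b * grid$session) + object$c
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$session, y = .data$freq_hz)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::labs(x = "session", y = "stroke frequency (Hz)",
                  title = sprintf("f(t) = %.3f exp(-%.3f t) + %.3f   (r2 = %.3f)",
                                  object$a, object$b, object$c, object$r2)) +
    ggplot2::theme_minimal()
}

#' Plot the mean CRP curve of each coordination pattern
#'
#' @param profiles Profiles tibble from [assign_labels()] (columns
#'   `pattern`, `mean_crp`).
#' @return A ggplot, one facet per pattern.
#' @export
plot_profiles <- function(profiles) {
  df <- profiles %>%
    filter(!purrr::map_lgl(.data$mean_crp, anyNA)) %>%
    mutate(curve = purrr::map(.data$mean_crp, function(v) {
      tibble(pct = seq(0, 100, length.out = length(v)), crp = v)
    })) %>%
    select("pattern", "curve") %>%
    tidyr::unnest("curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$crp)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~pattern) +
    ggplot2::ylim(-180, 180) +
    ggplot2::labs(x = "% of cycle", y = "CRP (deg)",
                  title = "Mean coordination pattern per cluster") +
    ggplot2::theme_minimal()
}

#' Plot a BIC scan with the selected plateau K
#'
#' @param scores Tibble with columns `K` and `bic` (e.g. from [scan_k()]).
#' @param k_star Optional selected K to highlight.
#' @return A ggplot.
#' @export
plot_bic_scan <- function(scores, k_star = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters K", y = "BIC (larger is better)") +
    ggplot2::theme_minimal()
  if (!is.null(k_star)) {
    p <- p + ggplot2::geom_vline(xintercept = k_star, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}
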