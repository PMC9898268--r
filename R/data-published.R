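# Published summary values from a breaststroke motor-learning study of seven
# novice swimmers (16 sessions, two within-subject speed conditions), shipped
# as plain R objects so the package's statistical battery and model-selection
# rule can be exercised on real reported numbers without any external data.

#' Individual learning rates for seven novice breaststroke swimmers
#'
#' Per-participant exponential learning-curve parameters reported in a
#' two-month breaststroke learning study: the learning rate `b` of
#' `f(t) = a * exp(-b * t) + c` fitted to per-session mean stroke frequency,
#' together with the fit-quality indicators, for each of two within-subject
#' speed conditions (swimming at 70% vs 90% of personal maximal speed).
#'
#' @format A tibble with 14 rows (7 participants x 2 conditions):
#' \describe{
#'   \item{participant}{Participant identifier (factor-like integer code).}
#'   \item{speed}{Speed condition, `"low"` (70%) or `"high"` (90%).}
#'   \item{b}{Learning rate, 1/session.}
#'   \item{r2}{Coefficient of determination of the exponential fit.}
#'   \item{rmse}{Root-mean-square error of the fit, Hz.}
#' }
#' @examples
#' with(swim_learning_rates,
#'      paired_t(b[speed == "low"], b[speed == "high"]))
#' @export
swim_learning_rates <- tibble::tibble(
  participant = rep(c(1L, 2L, 4L, 5L, 6L, 7L, 8L), times = 2),
  speed = rep(c("low", "high"), each = 7),
  b = c(0.0006178, 0.1777, 0.1394, 0.1796, 0.2285, 0.1286, 0.2407,
        0.02319, 0.3423, 0.005785, 0.2656, 0.1559, 0.3524, 0.4648),
  r2 = c(0.9374, 0.8805, 0.8935, 0.897, 0.8342, 0.9576, 0.95,
         0.7468, 0.8571, 0.8777, 0.9159, 0.7573, 0.693, 0.6866),
  rmse = c(0.0233, 0.0404, 0.0317, 0.0427, 0.045, 0.0261, 0.0247,
           0.0484, 0.0467, 0.0402, 0.0442, 0.0642, 0.0338, 0.0484)
)

#' Reported BIC values for the coordination-pattern cluster scan
#'
#' The BIC scores reported for candidate numbers of coordination-pattern
#' clusters K = 2..16 when clustering all movement cycles of the study
#' (larger is better). Feeding this vector to [select_k()] reproduces the
#' study's choice of 11 patterns via the first-value-of-the-plateau rule.
#'
#' @format A named numeric vector of length 15; names are the candidate K.
#' @examples
#' select_k(coordination_bic)
#' @export
coordination_bic <- stats::setNames(
  c(-12266770, -12054679, -11835712, -11758107, -11478308,
    -11414261, -11299105, -11096673, -10771125, -10382736,
    -10477354, -10527102, -10513261, -10358955, -10398427),
  2:16
)
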