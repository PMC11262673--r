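#' Plateau stopping rule
#'
#' Default monitored-protocol rule on a history of quality values (one per
#' decision point): stop once the quality signal has stabilised, i.e. the
#' relative change between successive decision points has stayed below
#' `epsilon` for `patience` consecutive points. A decision is never made
#' before three decision points exist - the first provides a baseline, the
#' second a difference, and only the third allows comparing differences;
#' the protocol therefore needs a resolution of more than three
#' reconstructions per acquisition to be useful at all.
#'
#' @param epsilon Threshold on the relative change (> 0).
#' @param patience Consecutive sub-threshold changes required (>= 1).
#' @param min_points Minimum decision points before stopping is allowed.
#' @return A rule function `f(history) -> "continue"|"stop"` for
#'   [mtr_simulate()].
#' @examples
#' rule <- stop_on_plateau(0.01, patience = 2)
#' rule(c(1, 1, 1))       # stabilised -> "stop"
#' rule(c(1, 0.5, 0.25))  # still moving -> "continue"
#' @export
stop_on_plateau <- function(epsilon, patience = 2, min_points = 3) {
  if (epsilon <= 0) stop_invalid("`epsilon` must be positive.")
  if (patience < 1) stop_invalid("`patience` must be >= 1.")
  function(history) {
    stopping_rule_eval(history, epsilon = epsilon, patience = patience,
                       min_points = min_points)
  }
}

#' Evaluate the plateau rule on a quality history
#'
#' @param history Numeric vector of quality values, oldest first; `NA`
#'   values count as above threshold.
#' @inheritParams stop_on_plateau
#' @return `"continue"` or `"stop"`.
#' @export
stopping_rule_eval <- function(history, epsilon, patience = 2,
                               min_points = 3) {
  if (length(history) < 1) stop_invalid("`history` must be non-empty.")
  min_points <- max(min_points, 3)
  if (length(history) < min_points) return("continue")
  prev <- head(history, -1)
  rel <- abs(diff(history)) / pmax(abs(prev), .Machine$double.eps)
  k <- min(patience, length(rel))
  recent <- tail(rel, k)
  if (all(!is.na(recent)) && all(recent < epsilon)) "stop" else "continue"
}
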