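#' Per-projection time and dose decomposition
#'
#' For each acquired projection the model charges exposure
#' `t_exp = t_frame + c_det`, movement
#' `t_move = c_move + dist * time_per_rotation / 360` (with `dist` the
#' angular travel to reach the projection; the first projection's initial
#' positioning is charged zero travel) and gating `t_gate = gate *
#' c_gate_move`. Dose is measured in object-exposition seconds:
#' `d_exp = t_exp` always; movement contributes dose only when the beam is
#' not gated (`d_move = (1 - gate) * t_move`); gating itself costs
#' `d_gate = gate * c_gate_dose`.
#'
#' @param setup An [setup_parameters()] object.
#' @param order An `mtr_order` whose grid length matches `setup$n_proj`.
#' @param rotation Stage rotation mode for travel distances, see
#'   [step_distances()].
#' @return Tibble with one row per acquisition step: `i`, `index`, `angle`,
#'   `dist` (deg) and the six cost terms (seconds).
#' @export
projection_costs <- function(setup, order,
                             rotation = c("bidirectional",
                                          "unidirectional")) {
  stopifnot(inherits(setup, "mtr_setup"))
  stopifnot(inherits(order, "mtr_order"))
  rotation <- match.arg(rotation)
  if (order$grid$n_proj != setup$n_proj) {
    stop_invalid(sprintf(
      "Order has %d projections but setup '%s' expects %d.",
      order$grid$n_proj, setup$name, setup$n_proj))
  }
  steps <- step_distances(order, rotation)
  t_exp <- setup$t_frame + setup$c_det
  t_move <- setup$c_move + steps$distance * setup$time_per_rotation / 360
  t_gate <- setup$gate * setup$c_gate_move
  tibble::tibble(
    i = steps$i,
    index = order$order,
    angle = steps$angle,
    dist = steps$distance,
    t_exp = t_exp,
    t_move = t_move,
    t_gate = t_gate,
    d_exp = t_exp,
    d_move = (1 - setup$gate) * t_move,
    d_gate = setup$gate * setup$c_gate_dose
  )
}

# per-projection contributions to total time/dose under the setup's regime
cost_increments <- function(setup, costs) {
  if (setup$continuous) {
    list(time = pmax(costs$t_exp + costs$t_gate, costs$t_move),
         dose = costs$d_exp + costs$d_gate)
  } else {
    list(time = costs$t_exp + costs$t_move + costs$t_gate,
         dose = costs$d_exp + costs$d_move + costs$d_gate)
  }
}

#' Total (or partial) acquisition time and dose
#'
#' Sums the per-projection costs over the first `n` acquired projections.
#' Quasi-stationary setups add exposure, movement and gating per projection;
#' continuous-movement setups (rotating gantry) take the per-projection
#' maximum of exposure+gating and movement, since the two overlap. Dose is
#' in object-exposition seconds.
#'
#' @inheritParams projection_costs
#' @param n Number of acquired projections to sum over (defaults to all).
#' @return One-row tibble: `setup`, `order_kind`, `n`, `t_total`, `d_total`,
#'   `regime`.
#' @examples
#' s <- setup_preset("micro")
#' acquisition_totals(s, acq_order_consecutive(setup_grid(s)))
#' @export
acquisition_totals <- function(setup, order, n = setup$n_proj,
                               rotation = c("bidirectional",
                                            "unidirectional")) {
  rotation <- match.arg(rotation)
  if (n < 1 || n > setup$n_proj) {
    stop_invalid("`n` must lie in [1, n_proj].")
  }
  costs <- projection_costs(setup, order, rotation)
  inc <- cost_increments(setup, costs)
  regime <- if (setup$continuous) "continuous" else "quasi-stationary"
  tibble::tibble(
    setup = setup$name,
    order_kind = order$kind,
    n = as.integer(n),
    t_total = sum(inc$time[seq_len(n)]),
    d_total = sum(inc$dose[seq_len(n)]),
    regime = regime
  )
}

#' Monitored-protocol time/dose curves
#'
#' Cumulative acquisition time and dose after each acquired projection
#' (following each order's acquisition sequence, not sorted angles), for one
#' or several candidate orders. These are the curves a monitored protocol
#' realises when it stops after `n` projections.
#'
#' @param setup An `mtr_setup`.
#' @param orders A single `mtr_order` or a list of them.
#' @inheritParams projection_costs
#' @return Tibble with columns `setup`, `order_kind`, `n`, `t_total`,
#'   `d_total`.
#' @export
acquisition_curves <- function(setup, orders,
                               rotation = c("bidirectional",
                                            "unidirectional")) {
  rotation <- match.arg(rotation)
  if (inherits(orders, "mtr_order")) orders <- list(orders)
  setup_name <- setup$name
  n_proj <- setup$n_proj
  purrr::map_dfr(orders, function(ord) {
    costs <- projection_costs(setup, ord, rotation)
    inc <- cost_increments(setup, costs)
    tibble::tibble(
      setup = setup_name,
      order_kind = ord$kind,
      n = seq_len(n_proj),
      t_total = cumsum(inc$time),
      d_total = cumsum(inc$dose)
    )
  })
}

#' Plot time/dose curves
#'
#' Draws the output of [acquisition_curves()] as two panels (time, dose) vs
#' number of acquired projections, one line per acquisition order.
#'
#' @param curves Tibble from [acquisition_curves()].
#' @return A ggplot object.
#' @export
plot_acquisition_curves <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("t_total", "d_total"),
                              names_to = "quantity", values_to = "seconds")
  long$quantity <- ifelse(long$quantity == "t_total", "time (s)",
                          "dose (object-exposition s)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$seconds,
                                     colour = .data$order_kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "projections acquired", y = NULL,
                  colour = "order",
                  title = paste0("Acquisition cost, setup '",
                                 curves$setup[1], "'"))
}
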