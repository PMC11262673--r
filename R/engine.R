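#' Per-cycle reconstruction cost model
#'
#' The simulator charges each reconstruction cycle a fixed overhead (volume
#' transfers, renormalisation) plus a per-new-projection incremental cost.
#' Validation experience shows cycle time is dominated by the fixed part
#' and only weakly dependent on the batch size, so both terms are exposed.
#'
#' @param overhead Fixed seconds per cycle (>= 0).
#' @param per_projection Seconds per new projection folded in (>= 0).
#' @return A function `f(n_new)` giving the cycle duration in seconds.
#' @export
cycle_cost <- function(overhead = 0, per_projection = 0) {
  if (overhead < 0 || per_projection < 0) {
    stop_invalid("Cycle costs must be non-negative.")
  }
  function(n_new) overhead + per_projection * n_new
}

#' Simulate a monitored acquisition run
#'
#' Discrete-event simulation of the asynchronous monitored protocol:
#' projections become available at the cumulative times of the acquisition
#' model; a single reconstruction worker starts when the first projection
#' is queued, consumes the *whole* queue each cycle (FIFO), and is busy for
#' the cycle-cost-model duration. After each completed cycle a quality
#' value is recorded (if `quality_fn` is given) and the stopping rule is
#' evaluated on the history; on a stop decision acquisition halts, and the
#' realised time and dose are the partial sums at the last acquired
#' projection. Acquisition never waits for reconstruction, so with a
#' never-firing rule the realised time and dose equal the standard-protocol
#' totals.
#'
#' @param setup An `mtr_setup`.
#' @param order An `mtr_order` over the setup's grid.
#' @param cost A [cycle_cost()] function (or any `f(n_new) -> seconds`).
#' @param stopping_rule A rule function `f(history) -> "continue"|"stop"`,
#'   e.g. [stop_on_plateau()]; `NULL` disables stopping.
#' @param quality_fn `f(n_after) -> numeric` quality value after a cycle
#'   that has folded in `n_after` projections (e.g. a reconstruction-change
#'   metric); `NULL` records `NA` and the run never stops.
#' @inheritParams projection_costs
#' @return An `mtr_trace` with acquisition events, reconstruction cycles,
#'   decision points, `n_rec`, `n_stop`, realised time/dose and a
#'   feasibility flag.
#' @examples
#' s <- setup_preset("micro")
#' tr <- mtr_simulate(s, acq_order_consecutive(setup_grid(s)),
#'                    cycle_cost(overhead = 3))
#' glance(tr)
#' @export
mtr_simulate <- function(setup, order, cost = cycle_cost(),
                         stopping_rule = NULL, quality_fn = NULL,
                         rotation = c("bidirectional", "unidirectional")) {
  rotation <- match.arg(rotation)
  if (!is.function(cost)) stop_invalid("`cost` must be a function of n_new.")
  if (cost(1) < 0) stop_invalid("Cycle cost must be non-negative.")
  costs <- projection_costs(setup, order, rotation)
  inc <- cost_increments(setup, costs)
  t_avail <- cumsum(inc$time)
  d_cum <- cumsum(inc$dose)
  n_p <- setup$n_proj

  events <- tibble::tibble(i = costs$i, index = costs$index,
                           angle = costs$angle, t_available = t_avail)

  cycles <- list()
  decisions <- list()
  history <- numeric(0)
  consumed <- 0L     # projections taken off the queue so far
  t_worker <- NA     # time the worker becomes free
  stopped_at <- NA   # time of the stop decision, if any
  n_stop <- NA_integer_

  repeat {
    # projections acquired by a given time (all of them if never stopped)
    acquired_by <- function(t) sum(t_avail <= t + 1e-12)
    if (consumed >= n_p) break
    next_avail <- t_avail[consumed + 1L]
    t_start <- if (is.na(t_worker)) next_avail else max(t_worker, next_avail)
    n_ready <- acquired_by(t_start)
    batch <- (consumed + 1L):n_ready
    dur <- cost(length(batch))
    if (dur < 0) stop_invalid("Cycle cost must be non-negative.")
    t_end <- t_start + dur
    consumed <- n_ready
    cycles[[length(cycles) + 1L]] <- tibble::tibble(
      cycle = length(cycles) + 1L, t_start = t_start, t_end = t_end,
      n_new = length(batch), first_index = batch[1], n_after = consumed)
    t_worker <- t_end

    q <- if (is.null(quality_fn)) NA_real_ else quality_fn(consumed)
    history <- c(history, q)
    decision <- if (is.null(stopping_rule) || is.null(quality_fn)) {
      "continue"
    } else {
      stopping_rule(history)
    }
    decisions[[length(decisions) + 1L]] <- tibble::tibble(
      cycle = length(cycles), t = t_end, quality = q, decision = decision)
    if (decision == "stop") {
      stopped_at <- t_end
      n_stop <- sum(t_avail <= t_end + 1e-12) # acquired before the decision
      break
    }
    if (consumed >= n_p) break
  }

  cycles <- dplyr::bind_rows(cycles)
  decisions <- dplyr::bind_rows(decisions)
  t_acq_end <- if (is.na(n_stop)) t_avail[n_p] else t_avail[n_stop]
  n_real <- if (is.na(n_stop)) n_p else n_stop
  # cycles completed by the time acquisition ends (or stops)
  n_rec <- if (nrow(cycles)) sum(cycles$t_end <= t_acq_end + 1e-12) else 0L
  feasible <- n_rec >= 1L

  structure(
    list(setup = setup$name, order_kind = order$kind,
         events = events, cycles = cycles, decisions = decisions,
         n_rec = as.integer(n_rec), n_stop = n_stop,
         n_realized = as.integer(n_real),
         t_realized = t_avail[n_real], d_realized = d_cum[n_real],
         t_full = t_avail[n_p], d_full = d_cum[n_p],
         feasible = feasible),
    class = "mtr_trace"
  )
}

#' @export
print.mtr_trace <- function(x, ...) {
  cat(sprintf("<monitored run: setup '%s', %s order>\n", x$setup, x$order_kind))
  cat(sprintf("  %d/%d projections acquired in %.4g s (dose %.4g s)\n",
              x$n_realized, nrow(x$events), x$t_realized, x$d_realized))
  cat(sprintf("  %d reconstruction cycles within acquisition (n_rec)%s\n",
              x$n_rec,
              if (!x$feasible) " - real-time reconstruction infeasible" else ""))
  if (!is.na(x$n_stop)) {
    cat(sprintf("  stopped early at n = %d\n", x$n_stop))
  }
  invisible(x)
}

#' @export
tidy.mtr_trace <- function(x, ...) x$cycles

#' @export
glance.mtr_trace <- function(x, ...) resolution_summary(x)

#' Summary of a monitored run
#'
#' Reports the protocol's decision-scale resolution (`n_rec`), the worker's
#' total busy time, realised acquisition time/dose and the savings relative
#' to running the acquisition to completion.
#'
#' @param trace An `mtr_trace` from [mtr_simulate()].
#' @return One-row tibble.
#' @export
resolution_summary <- function(trace) {
  stopifnot(inherits(trace, "mtr_trace"))
  busy <- if (nrow(trace$cycles)) {
    sum(trace$cycles$t_end - trace$cycles$t_start)
  } else 0
  tibble::tibble(
    setup = trace$setup, order_kind = trace$order_kind,
    n_rec = trace$n_rec, n_stop = trace$n_stop,
    n_realized = trace$n_realized,
    recon_busy_s = busy,
    t_realized = trace$t_realized, d_realized = trace$d_realized,
    t_saved = trace$t_full - trace$t_realized,
    d_saved = trace$d_full - trace$d_realized,
    feasible = trace$feasible
  )
}

#' Per-event timing plot of a monitored run
#'
#' Mirrors the validation-stand timing view: per-projection acquisition
#' times and per-cycle reconstruction durations against the index of the
#' first projection involved, showing the queue growing once acquisition
#' outpaces reconstruction.
#'
#' @param trace An `mtr_trace`.
#' @return A ggplot object.
#' @export
plot_trace <- function(trace) {
  stopifnot(inherits(trace, "mtr_trace"))
  acq <- tibble::tibble(
    index = trace$events$i + 1,
    seconds = c(trace$events$t_available[1],
                diff(trace$events$t_available)),
    what = "acquisition (per projection)")
  rec <- tibble::tibble(
    index = trace$cycles$first_index,
    seconds = trace$cycles$t_end - trace$cycles$t_start,
    what = "reconstruction (per cycle)")
  ggplot2::ggplot(dplyr::bind_rows(acq, rec),
                  ggplot2::aes(x = .data$index, y = .data$seconds,
                               colour = .data$what)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "projection index", y = "seconds", colour = NULL,
                  title = sprintf("Monitored run timing ('%s', %s order)",
                                  trace$setup, trace$order_kind))
}
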