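#' Instrument parameter sets for the acquisition time/dose model
#'
#' A setup bundles the per-projection acquisition constants of one CT
#' instrument: frame exposure `t_frame` and detector overhead `c_det`
#' (seconds), motion overhead `c_move` and the time for a full 360-degree
#' rotation `time_per_rotation` (seconds; 0 means angle changes carry no
#' distance-dependent cost, as for an electron-beam scanner), whether the
#' beam is gated (`gate`, 0/1) with gating overheads `c_gate_move` (time)
#' and `c_gate_dose` (dose), and whether exposure and rotation overlap
#' (`continuous`). `n_proj` and `angle_range` define the instrument's angle
#' grid; `n_x`/`n_z` are detector columns/rows used by the
#' reconstruction-cost model.
#'
#' @param name Setup name.
#' @param n_proj Total number of projections.
#' @param angle_range Angular range in degrees, `(0, 360]`.
#' @param n_x,n_z Detector columns and rows.
#' @param t_frame,c_det,c_move,time_per_rotation,c_gate_move,c_gate_dose
#'   Times in seconds (all non-negative).
#' @param gate 0 or 1: beam gating active.
#' @param continuous Logical: exposure and movement run simultaneously
#'   (gantry-type scanners), so the per-projection cost is the maximum of
#'   the two rather than their sum.
#' @return An `mtr_setup` object.
#' @export
setup_parameters <- function(name, n_proj, angle_range, n_x, n_z,
                             t_frame, time_per_rotation, c_det, c_move,
                             gate = 0, c_gate_move = 0, c_gate_dose = 0,
                             continuous = FALSE) {
  times <- c(t_frame = t_frame, time_per_rotation = time_per_rotation,
             c_det = c_det, c_move = c_move, c_gate_move = c_gate_move,
             c_gate_dose = c_gate_dose)
  if (any(!is.finite(times)) || any(times < 0)) {
    stop_invalid("All setup times must be finite and non-negative.")
  }
  if (n_proj < 1 || n_proj != round(n_proj)) {
    stop_invalid("`n_proj` must be a positive integer.")
  }
  if (angle_range <= 0 || angle_range > 360) {
    stop_invalid("`angle_range` must lie in (0, 360].")
  }
  if (!gate %in% c(0, 1)) stop_invalid("`gate` must be 0 or 1.")
  structure(
    list(name = name, n_proj = as.integer(n_proj),
         angle_range = as.numeric(angle_range),
         n_x = as.integer(n_x), n_z = as.integer(n_z),
         t_frame = t_frame, time_per_rotation = time_per_rotation,
         c_det = c_det, c_move = c_move, gate = gate,
         c_gate_move = c_gate_move, c_gate_dose = c_gate_dose,
         continuous = isTRUE(continuous)),
    class = "mtr_setup"
  )
}

# Preset table. Zero entries are literal zeros: data unavailable in the
# source literature and presumed negligible. The nano preset's published
# total time is inconsistent with its published per-projection parameters
# (see the methods vignette); its parameters are shipped as printed.
setup_preset_list <- function() {
  list(
    micro = setup_parameters("micro", 512, 360, 2048, 2048,
                             t_frame = 1, time_per_rotation = 60,
                             c_det = 1, c_move = 0.1,
                             gate = 1, c_gate_dose = 0.1),
    nano = setup_parameters("nano", 800, 180, 2048, 2048,
                            t_frame = 180, time_per_rotation = 60,
                            c_det = 1, c_move = 0.1),
    medical = setup_parameters("medical", 720, 360, 736, 16,
                               t_frame = 0.00138, time_per_rotation = 1,
                               c_det = 0, c_move = 0, continuous = TRUE),
    cargo = setup_parameters("cargo", 720, 256, 1360, 1,
                             t_frame = 0.0833, time_per_rotation = 60,
                             c_det = 0, c_move = 0, continuous = TRUE),
    ebct = setup_parameters("ebct", 400, 360, 720, 2,
                            t_frame = 7e-5, time_per_rotation = 0,
                            c_det = 0, c_move = 1e-5,
                            gate = 1, c_gate_dose = 0)
  )
}

#' Load a CT instrument preset
#'
#' Built-in presets cover five instrument classes: `"micro"` (industrial
#' micro CT, quasi-stationary stage, gated beam), `"nano"` (long-exposure
#' laboratory nano CT), `"medical"` (continuously rotating gantry),
#' `"cargo"` (large-scale MV CT, limited 256-degree range) and `"ebct"`
#' (electron-beam CT: arbitrary angle order with microsecond changeover).
#' A path to a YAML config file (see [read_setup()]) is also accepted.
#'
#' @param name Preset name or config file path.
#' @return An `mtr_setup`.
#' @examples
#' setup_preset("micro")
#' @export
setup_preset <- function(name) {
  presets <- setup_preset_list()
  if (name %in% names(presets)) return(presets[[name]])
  if (file.exists(name)) return(read_setup(name))
  rlang::abort(paste0("Unknown setup preset '", name, "'; available: ",
                      paste(names(presets), collapse = ", "),
                      ", or a config file path."),
               class = "mtrecon_lookup_error")
}

#' All built-in setup presets as a table
#'
#' @return Tibble with one row per preset and one column per parameter.
#' @export
setup_presets <- function() {
  purrr::map_dfr(setup_preset_list(), function(s) {
    tibble::as_tibble(s[setdiff(names(s), character(0))])
  })
}

#' @export
print.mtr_setup <- function(x, ...) {
  cat(sprintf(
    "<CT setup '%s': %d projections over %g deg, detector %d x %d>\n",
    x$name, x$n_proj, x$angle_range, x$n_x, x$n_z))
  cat(sprintf(
    "  t_frame %g s, c_det %g s, c_move %g s, %g s/rotation, gate %d, %s\n",
    x$t_frame, x$c_det, x$c_move, x$time_per_rotation, x$gate,
    if (x$continuous) "continuous movement" else "quasi-stationary"))
  invisible(x)
}

#' Angle grid of a setup
#'
#' @param setup An `mtr_setup`.
#' @return The setup's [angle_grid()] over `[0, angle_range)`.
#' @export
setup_grid <- function(setup) {
  stopifnot(inherits(setup, "mtr_setup"))
  angle_grid(0, setup$angle_range, setup$n_proj)
}

#' Read/write a setup as a flat YAML config
#'
#' @param path File path.
#' @param setup An `mtr_setup`.
#' @return `read_setup()` returns an `mtr_setup`; `write_setup()` returns
#'   `setup` invisibly.
#' @export
read_setup <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(setup_parameters, cfg)
}

#' @rdname read_setup
#' @export
write_setup <- function(setup, path) {
  stopifnot(inherits(setup, "mtr_setup"))
  yaml::write_yaml(unclass(setup), path)
  invisible(setup)
}
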