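#' GPU compute-unit parameters for the reconstruction-cost model
#'
#' @param name Device name.
#' @param s_rec Floating-point operations per second.
#' @param s_load Host-to-device transfer rate, bytes/s.
#' @param s_memory Device memory access rate, bytes/s.
#' @param p_voxel Operations per voxel per projection (backprojection
#'   kernel cost, estimated empirically from production software).
#' @param p_pixel Operations per projection pixel (preprocessing).
#' @param ram_bytes Device memory size in bytes.
#' @return An `mtr_gpu` object.
#' @export
gpu_parameters <- function(name, s_rec, s_load, s_memory, p_voxel, p_pixel,
                           ram_bytes) {
  vals <- c(s_rec, s_load, s_memory, p_voxel, p_pixel, ram_bytes)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_invalid("All GPU parameters must be finite and positive.")
  }
  structure(
    list(name = name, s_rec = s_rec, s_load = s_load, s_memory = s_memory,
         p_voxel = p_voxel, p_pixel = p_pixel, ram_bytes = ram_bytes),
    class = "mtr_gpu"
  )
}

#' Load a GPU preset
#'
#' `"rtx4090"` is a current-generation consumer unit (85.2 TFlops/s,
#' 500 MB/s PCIe load rate, 1 TB/s memory access, 24 GB RAM);
#' `"rtx3080ti"` is the previous-generation unit of the validation stand
#' (34.1 TFlops/s, 0.9 TB/s, 12 GB). Both use the empirical kernel costs
#' p_voxel = 600 and p_pixel = 200. A YAML config path is also accepted.
#'
#' @param name Preset name or config file path.
#' @return An `mtr_gpu`.
#' @export
gpu_preset <- function(name) {
  presets <- list(
    rtx4090 = gpu_parameters("rtx4090", s_rec = 85.2e12, s_load = 500e6,
                             s_memory = 1e12, p_voxel = 600, p_pixel = 200,
                             ram_bytes = 24e9),
    rtx3080ti = gpu_parameters("rtx3080ti", s_rec = 34.1e12, s_load = 500e6,
                               s_memory = 0.9e12, p_voxel = 600,
                               p_pixel = 200, ram_bytes = 12e9)
  )
  if (name %in% names(presets)) return(presets[[name]])
  if (file.exists(name)) {
    return(do.call(gpu_parameters, yaml::read_yaml(name)))
  }
  rlang::abort(paste0("Unknown GPU preset '", name, "'; available: ",
                      paste(names(presets), collapse = ", ")),
               class = "mtrecon_lookup_error")
}

#' @export
print.mtr_gpu <- function(x, ...) {
  cat(sprintf("<GPU '%s': %.3g TFlops/s, load %.3g GB/s, mem %.3g TB/s, %g GB>\n",
              x$name, x$s_rec / 1e12, x$s_load / 1e9, x$s_memory / 1e12,
              x$ram_bytes / 1e9))
  invisible(x)
}

#' GPU reconstruction-time model
#'
#' Decomposes one reconstruction (or incremental update) into host-to-device
#' load, device memory traffic, projection preprocessing and the
#' reconstruction kernel:
#' \deqn{T_{rec} = it\_count \times vol\_size \times N_a \times P_{voxel} / s_{rec}}
#' with `proj_size = n_x * n_z * n_a` pixels and
#' `vol_size = n_x * n_x * n_z` voxels. Data loading is a one-time
#' per-experiment cost and is excluded by default (`include_load = FALSE`)
#' when quoting per-cycle times. For the incremental partial variant
#' (`"fbp_partial"`), `n_a` is the number of *new* projections folded into
#' the running reconstruction (typically 1), which is what makes the cycle
#' cost independent of how many projections were already acquired. SIRT
#' multiplies the kernel term by `it_count` iterations and by
#' `iteration_ops_multiplier` (default 3: forward, back and update passes
#' per iteration).
#'
#' @param gpu An [gpu_parameters()] object.
#' @param n_x,n_z Detector columns/rows.
#' @param n_a Projections processed (new projections for `"fbp_partial"`).
#' @param algorithm `"fbp_fdk"`, `"fbp_partial"` or `"sirt"`.
#' @param it_count Iterations (forced to 1 for the FBP variants).
#' @param bytes_per_pixel Bytes per projection pixel (default 4,
#'   single precision).
#' @param iteration_ops_multiplier Extra per-iteration operation factor for
#'   SIRT.
#' @param include_load Include the one-time host-to-device load in the
#'   total.
#' @return One-row tibble: `algorithm`, `n_x`, `n_z`, `n_a`, `it_count`,
#'   `t_load`, `t_memory`, `t_prep`, `t_rec`, `t_total` (seconds), and
#'   `fits_ram`.
#' @examples
#' recon_time(gpu_preset("rtx4090"), 2048, 2048, 512)
#' @export
recon_time <- function(gpu, n_x, n_z, n_a,
                       algorithm = c("fbp_fdk", "fbp_partial", "sirt"),
                       it_count = 1, bytes_per_pixel = 4,
                       iteration_ops_multiplier = 3,
                       include_load = FALSE) {
  stopifnot(inherits(gpu, "mtr_gpu"))
  algorithm <- match.arg(algorithm)
  if (n_x < 1 || n_z < 1 || n_a < 0) {
    stop_invalid("Detector dimensions must be positive and `n_a` >= 0.")
  }
  if (it_count < 1) stop_invalid("`it_count` must be >= 1.")
  if (algorithm != "sirt") it_count <- 1
  ops_mult <- if (algorithm == "sirt") iteration_ops_multiplier else 1
  n_x <- as.numeric(n_x) # avoid integer overflow in pixel/voxel counts
  n_z <- as.numeric(n_z)
  n_a <- as.numeric(n_a)
  proj_size <- n_x * n_z * n_a
  vol_size <- n_x * n_x * n_z
  t_load <- if (include_load) proj_size * bytes_per_pixel / gpu$s_load else 0
  t_memory <- proj_size * bytes_per_pixel / gpu$s_memory
  t_prep <- proj_size * gpu$p_pixel / gpu$s_rec
  t_rec <- it_count * ops_mult * vol_size * n_a * gpu$p_voxel / gpu$s_rec
  bytes_needed <- (vol_size + proj_size) * bytes_per_pixel
  fits <- bytes_needed <= gpu$ram_bytes
  if (!fits) {
    warning(sprintf(
      "Volume + projections (%.1f GB) exceed GPU RAM (%.1f GB); %s",
      bytes_needed / 1e9, gpu$ram_bytes / 1e9,
      "the model assumes everything stays resident."), call. = FALSE)
  }
  tibble::tibble(
    algorithm = algorithm, n_x = n_x, n_z = n_z, n_a = n_a,
    it_count = it_count,
    t_load = t_load, t_memory = t_memory, t_prep = t_prep, t_rec = t_rec,
    t_total = t_load + t_memory + t_prep + t_rec,
    fits_ram = fits
  )
}

#' Reconstructions per acquisition
#'
#' How many reconstruction cycles of duration `cycle_time` fit inside one
#' acquisition of duration `t_acq`: `floor(t_acq / cycle_time)`. This count
#' is the monitored protocol's resolution on the stopping-decision scale; a
#' count below 1 means real-time reconstruction is infeasible on that
#' instrument/algorithm combination.
#'
#' @param t_acq Total acquisition time, seconds.
#' @param cycle_time Reconstruction cycle time, seconds (> 0).
#' @return One-row tibble: `n_rec` (integer count), `feasible`.
#' @export
recons_per_acquisition <- function(t_acq, cycle_time) {
  if (cycle_time <= 0) stop_invalid("`cycle_time` must be positive.")
  n <- floor(t_acq / cycle_time)
  tibble::tibble(n_rec = n, feasible = n >= 1)
}

#' Reconstruction-cost table across setups and algorithms
#'
#' For each setup and algorithm, the maximum per-cycle reconstruction time
#' (batch FBP/FDK over all `n_proj` projections; SIRT with `sirt_iterations`
#' iterations; incremental partial FBP folding in a single new projection)
#' and the number of such cycles that fit into the setup's modeled
#' consecutive-order acquisition time.
#'
#' @param gpu An `mtr_gpu`.
#' @param setups List of `mtr_setup` objects (or a single one).
#' @param sirt_iterations Iteration count for the SIRT rows.
#' @return Tibble with columns `setup`, `algorithm`, `cycle_s`, `t_acq_s`,
#'   `n_rec`, `feasible`, `per_n_proj` (= n_rec / n_proj).
#' @export
recon_cost_table <- function(gpu, setups, sirt_iterations = 50) {
  if (inherits(setups, "mtr_setup")) setups <- list(setups)
  purrr::map_dfr(setups, function(s) {
    t_acq <- acquisition_totals(s, acq_order_consecutive(setup_grid(s)))$t_total
    algs <- list(
      fbp_fdk = recon_time(gpu, s$n_x, s$n_z, s$n_proj, "fbp_fdk"),
      sirt = recon_time(gpu, s$n_x, s$n_z, s$n_proj, "sirt",
                        it_count = sirt_iterations),
      fbp_partial = recon_time(gpu, s$n_x, s$n_z, 1, "fbp_partial")
    )
    purrr::imap_dfr(algs, function(row, alg) {
      cyc <- row$t_total
      cnt <- recons_per_acquisition(t_acq, cyc)
      tibble::tibble(
        setup = s$name, algorithm = alg, cycle_s = cyc, t_acq_s = t_acq,
        n_rec = cnt$n_rec, feasible = cnt$feasible,
        per_n_proj = cnt$n_rec / s$n_proj
      )
    })
  })
}
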