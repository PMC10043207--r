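#' Fenton-Karma model parameters
#'
#' Returns the parameter set of the three-variable Fenton-Karma (FK) atrial
#' cell model together with tissue diffusivities, as used by the monodomain
#' solver. The defaults start from the original FK fit to the modified
#' Beeler-Reuter kinetics and shorten the action potential (smaller
#' `tau_r`/`tau_si` and recovery constants) to the electrically remodelled,
#' AF-like regime, so that the re-entrant wavelength fits a desk-scale
#' (~3 cm) atrial disk. All values are overridable.
#'
#' Time constants are in ms, thresholds dimensionless, diffusivities in
#' mm^2/ms. Healthy-tissue diffusivity 0.1 mm^2/ms gives a physiological
#' conduction velocity near 0.5 m/s; fibrotic tissue conducts at 0.015
#' mm^2/ms (ratio 0.15), and ablated tissue does not conduct at all.
#'
#' @param ... named overrides of any default parameter.
#' @return An object of class `fk_params` (named list).
#' @export
fk_params <- function(...) {
  p <- list(
    tau_d = 0.25, tau_o = 12.5, tau_r = 15, tau_si = 30,
    tau_v_plus = 3.33, tau_v1_minus = 333, tau_v2_minus = 19.6,
    tau_w_plus = 150, tau_w_minus = 41,
    u_c = 0.13, u_v = 0.04, u_c_si = 0.85, k_si = 10,
    D_healthy = 0.1, D_fibrotic = 0.015, D_ablated = 0
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown FK parameter(s): ", paste(bad, collapse = ", "))
    p[names(dots)] <- dots
  }
  taus <- unlist(p[grep("^tau_", names(p))])
  stopifnot(all(taus > 0), p$u_c > 0, p$u_c < 1,
            p$D_ablated == 0, p$D_fibrotic < p$D_healthy)
  structure(p, class = "fk_params")
}

#' Check the explicit-Euler stability bound
#'
#' The forward-Euler / 5-point-Laplacian scheme requires
#' `dt <= dx^2 / (4 max(D))` and, for the stiff reaction terms, a time step
#' well below the fastest time constant (`dt <= min(tau)/2`). Called before
#' every run; violating either bound is a configuration error.
#'
#' @param params `fk_params` object.
#' @param dt time step (ms).
#' @param dx pixel spacing (mm).
#' @return `dt`, invisibly, if admissible.
#' @export
check_stability <- function(params, dt, dx) {
  d_bound <- dx^2 / (4 * params$D_healthy)
  taus <- unlist(params[grep("^tau_", names(params))])
  if (dt > d_bound)
    stop(sprintf("dt = %g ms violates the diffusion stability bound %g ms",
                 dt, d_bound))
  if (dt > min(taus) / 2)
    stop(sprintf("dt = %g ms exceeds half the fastest time constant (%g ms)",
                 dt, min(taus)))
  invisible(dt)
}

#' Fenton-Karma ionic currents
#'
#' Evaluates the three FK currents on grids of the membrane variable `u` and
#' gates `v`, `w`: the fast inward (sodium-like), slow outward
#' (potassium-like) and slow inward (calcium-like) currents.
#'
#' @param u,v,w numeric matrices of equal dimension.
#' @param params `fk_params` object.
#' @return List with matrices `Ifi`, `Iso`, `Isi`.
#' @export
fk_currents <- function(u, v, w, params) {
  stopifnot(identical(dim(u), dim(v)), identical(dim(u), dim(w)))
  fk_currents_cpp(u, v, w, unclass(params))
}

#' Advance an FK state without stimulation
#'
#' Low-level solver surface used for verification: takes explicit state
#' grids, a per-pixel diffusivity map and an activity mask, and advances
#' `n_steps` forward-Euler steps with zero-flux boundaries.
#'
#' @param u,v,w state grids.
#' @param D per-pixel diffusivity (mm^2/ms); 0 outside tissue.
#' @param active logical/0-1 matrix of conducting pixels.
#' @param params `fk_params`.
#' @param dt time step (ms); checked against the stability bound.
#' @param dx pixel spacing (mm).
#' @param n_steps number of steps.
#' @return List with advanced `u`, `v`, `w`.
#' @export
fk_step <- function(u, v, w, D, active, params, dt, dx, n_steps = 1L) {
  check_stability(params, dt, dx)
  mode(active) <- "integer"
  fk_step_n_cpp(u, v, w, D, active, unclass(params), dt, dx, as.integer(n_steps))
}

#' Simulate AF induction (and optionally ablation) on a tissue disk
#'
#' Runs the monodomain FK model on a [tissue disk][make_disk_geometry] using
#' the standard cross-field (S1-S2) protocol: a planar S1 wave from the left
#' edge at t = 0 and a perpendicular half-plane S2 at `s2_time`, which
#' breaks across the S1 repolarisation tail and initiates re-entry. The
#' default `s2_time` of 65 ms places S2 inside the vulnerable window of the
#' default AF-remodelled cell parameters (the window scales with the
#' model's action-potential duration and conduction velocity, so it must
#' be retuned whenever the cell parameters change). If a lesion mask is supplied its pixels are rendered
#' inexcitable at `lesion_time`, modelling ablation delivered to an ongoing
#' AF episode. Termination is declared when the maximum membrane variable
#' over the tissue stays below `u_act` for `quiescence_window` ms.
#'
#' @param disk a `tissue_disk`.
#' @param lesions optional `lesion_mask` (or plain logical matrix).
#' @param lesion_time time (ms) at which lesions are applied.
#' @param params `fk_params`.
#' @param t_end simulation end time (ms).
#' @param dt time step (ms).
#' @param s2_time S2 stimulus time (ms).
#' @param s1_width width of the S1 stimulus band (pixels).
#' @param record `c(start, end)` window (ms) for membrane snapshots.
#' @param record_stride snapshot stride (ms).
#' @param u_act activity threshold for termination detection.
#' @param quiescence_window quiet period (ms) required for termination.
#' @param stop_on_termination stop integrating once terminated.
#' @param track_activation record first activation times (used by
#'   [measure_cv()]).
#' @return An object of class `sim_result`: snapshots (H x W x T array),
#'   snapshot times, the 1-ms activity trace, `terminated`,
#'   `termination_time` and the final state.
#' @export
run_crossfield <- function(disk, lesions = NULL, lesion_time = 500,
                           params = fk_params(), t_end = 2000, dt = 0.01,
                           s2_time = 65, s1_width = 3,
                           record = c(max(0, lesion_time - 200), lesion_time),
                           record_stride = 2,
                           u_act = 0.1, quiescence_window = 50,
                           stop_on_termination = TRUE,
                           track_activation = FALSE) {
  label <- if (inherits(disk, "tissue_disk")) disk$label_grid else disk
  dx <- if (inherits(disk, "tissue_disk")) disk$geometry$pixel_spacing else 0.3
  check_stability(params, dt, dx)
  les <- NULL
  if (!is.null(lesions)) {
    les <- if (inherits(lesions, "lesion_mask")) lesions$mask else lesions
    stopifnot(identical(dim(les), dim(label)), lesion_time < t_end)
  }
  res <- fk_run_cpp(label, unclass(params), params$D_healthy,
                    params$D_fibrotic, dt, dx, t_end,
                    les, lesion_time, s2_time, as.integer(s1_width),
                    record[1], record[2], record_stride,
                    u_act, quiescence_window, stop_on_termination,
                    0.5, track_activation)
  res$t_end <- t_end
  res$dt <- dt
  class(res) <- "sim_result"
  res
}

#' Termination detection on an activity trace
#'
#' Scans a sampled trace of the tissue-wide maximum membrane variable and
#' reports the first time after which activity stays below `u_act`
#' continuously for `quiescence_window` ms. The returned termination time is
#' the last sample at which activity was present (0 if never).
#'
#' @param times sample times (ms), increasing.
#' @param umax per-sample maximum membrane variable.
#' @param u_act activity threshold in (0,1).
#' @param quiescence_window required quiet duration (ms).
#' @return List with `terminated` and `termination_time` (NA if not
#'   terminated within the trace).
#' @export
is_af_terminated <- function(times, umax, u_act = 0.1,
                             quiescence_window = 50) {
  stopifnot(length(times) == length(umax), u_act > 0, u_act < 1)
  last_active <- 0
  for (k in seq_along(times)) {
    if (umax[k] >= u_act) {
      last_active <- times[k]
    } else if (times[k] - last_active >= quiescence_window) {
      return(list(terminated = TRUE, termination_time = last_active))
    }
  }
  list(terminated = FALSE, termination_time = NA_real_)
}

#' Measure planar conduction velocity
#'
#' Calibration/QA helper: paces a thin homogeneous strip from one end and
#' measures conduction velocity from the activation-time difference between
#' two distal sensing columns. Since mm/ms = m/s, the value is returned in
#' m/s directly.
#'
#' @param params `fk_params`.
#' @param D diffusivity to test (mm^2/ms).
#' @param strip_length strip length in mm (>= 24 mm so that >= 20 mm of
#'   planar propagation is observed).
#' @param dt time step (ms); default respects the stability bound for
#'   D up to 0.1.
#' @param pixel_spacing mm per pixel.
#' @return Conduction velocity in m/s.
#' @export
measure_cv <- function(params = fk_params(), D = params$D_healthy,
                       strip_length = 30, dt = 0.02, pixel_spacing = 0.3) {
  stopifnot(strip_length >= 24, D > 0)
  n <- ceiling(strip_length / pixel_spacing)
  label <- matrix(LBL_HEALTHY, nrow = 7, ncol = n)
  if (dt > pixel_spacing^2 / (4 * D))
    stop("dt violates the diffusion stability bound for this D")
  res <- fk_run_cpp(label, unclass(params), D, D / 2, dt,
                    pixel_spacing, 200, NULL, -1, 1e9, 3L,
                    -1, -1, 1, 0.1, 50, FALSE, 0.5, TRUE)
  at <- res$activation_time
  mid <- 4L
  c1 <- round(n * 0.4); c2 <- round(n * 0.8)
  t1 <- at[mid, c1]; t2 <- at[mid, c2]
  if (t1 < 0 || t2 < 0 || t2 <= t1)
    stop("no-propagation: wave failed to reach both sensing columns")
  (c2 - c1) * pixel_spacing / (t2 - t1)
}
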