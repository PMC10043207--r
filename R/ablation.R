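new_lesion_mask <- function(mask, disk, strategy) {
  tis <- tissue_mask(disk)
  mask <- mask & tis
  structure(list(mask = mask, strategy = strategy,
                 ablated_fraction = sum(mask) / sum(tis)),
            class = "lesion_mask")
}

#' Pulmonary-vein isolation lesions
#'
#' Plans the PVI strategy: an annulus of `ring_width` tissue pixels around
#' the circumference of each PV opening. Rings broken by the disk edge are
#' kept partial with a warning.
#'
#' @param disk a `tissue_disk`.
#' @param ring_width annulus width in pixels (>= 1).
#' @return A `lesion_mask` (fields `mask`, `ablated_fraction`, `strategy`).
#' @export
plan_pvi <- function(disk, ring_width = 2) {
  stopifnot(ring_width >= 1)
  geo <- disk$geometry
  n <- geo$grid_shape[1]
  m <- matrix(FALSE, n, n)
  rr <- row(m); cc <- col(m)
  tis <- tissue_mask(disk)
  for (pv in geo$pv_list) {
    d <- sqrt((rr - pv[1])^2 + (cc - pv[2])^2)
    ring <- d > pv[3] & d <= pv[3] + ring_width
    if (any(ring & !geo$disk_mask))
      warning("PVI ring touches the disk edge; partial ring kept")
    m <- m | ring
  }
  new_lesion_mask(m, disk, "PVI")
}

#' Fibrosis-border ablation lesions
#'
#' Plans the FIBRO strategy: the one-pixel perimeter of every fibrotic
#' connected component with at least `min_region_px` pixels (smaller
#' speckle is ignored). The perimeter is the set of fibrotic pixels with a
#' non-fibrotic 4-neighbour, so lesions never enter the interior of large
#' fibrotic regions.
#'
#' @param disk a `tissue_disk`.
#' @param min_region_px minimum component area in pixels.
#' @return A `lesion_mask`.
#' @export
plan_fibro <- function(disk, min_region_px = 9) {
  fib <- disk$label_grid == LBL_FIBROTIC
  if (!any(fib)) return(new_lesion_mask(fib, disk, "FIBRO"))
  comp <- EBImage::bwlabel(fib)
  sizes <- tabulate(comp[comp > 0])
  keep <- matrix(FALSE, nrow(fib), ncol(fib))
  keep[comp > 0] <- sizes[comp[comp > 0]] >= min_region_px
  per <- keep & !(shift_mat(keep, 1, 0) & shift_mat(keep, -1, 0) &
                    shift_mat(keep, 0, 1) & shift_mat(keep, 0, -1))
  new_lesion_mask(per, disk, "FIBRO")
}

# shift a logical matrix by (dr, dc), padding with FALSE
shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(FALSE, n, p)
  sr <- seq_len(n) - dr; sc <- seq_len(p) - dc
  ok_r <- sr >= 1 & sr <= n; ok_c <- sc >= 1 & sc <= p
  out[ok_r, ok_c] <- m[sr[ok_r], sc[ok_c]]
  out
}

#' Instantaneous phase from a membrane-voltage history
#'
#' Computes a per-pixel activation phase sequence from snapshots of the
#' membrane variable via the analytic-signal construction: each pixel's
#' mean-subtracted time series is extended to its analytic signal (FFT,
#' zeroing negative frequencies) and the phase is its argument in
#' (-pi, pi]. Pixels whose oscillation amplitude is negligible get NA
#' phase (phase undefined at rest).
#'
#' @param u_history H x W x T array of membrane snapshots.
#' @param times snapshot times (ms); the spanned window must be at least
#'   `min_window` (one rotation period or more).
#' @param min_window minimum window length in ms.
#' @param amp_tol amplitude (fraction of the largest pixel amplitude)
#'   below which phase is flagged undefined.
#' @return H x W x T array of phases (radians), NA where undefined.
#' @export
compute_phase <- function(u_history, times = NULL, min_window = 200,
                          amp_tol = 0.05) {
  stopifnot(length(dim(u_history)) == 3)
  nt <- dim(u_history)[3]
  if (!is.null(times) && diff(range(times)) < min_window)
    stop("phase window shorter than one rotation period (", min_window, " ms)")
  h <- dim(u_history)[1]; w <- dim(u_history)[2]
  x <- matrix(aperm(u_history, c(3, 1, 2)), nrow = nt)  # T x (H*W)
  x <- sweep(x, 2, colMeans(x))
  ft <- mvfft(x)
  mult <- numeric(nt)
  if (nt %% 2 == 0) {
    mult[1] <- 1; mult[nt / 2 + 1] <- 1; mult[2:(nt / 2)] <- 2
  } else {
    mult[1] <- 1; mult[2:((nt + 1) / 2)] <- 2
  }
  analytic <- mvfft(ft * mult, inverse = TRUE) / nt
  amp <- apply(Mod(analytic), 2, max)
  undef <- amp < amp_tol * max(amp)
  ph <- atan2(Im(analytic), Re(analytic))
  ph[, undef] <- NA_real_
  aperm(array(ph, dim = c(nt, h, w)), c(2, 3, 1))
}

# wrap angles into (-pi, pi]
wrap_angle <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Detect phase singularities
#'
#' Finds the organising centres of re-entrant waves: 2x2 plaquettes where
#' the wrapped phase differences summed around the loop equal +-2*pi
#' (topological charge +-1). Plaquettes containing undefined (NA) phase
#' are skipped.
#'
#' @param phase H x W phase matrix (radians).
#' @return A data frame with columns `row`, `col` (plaquette centres,
#'   half-integer coordinates) and `charge` (+1 or -1); zero rows if none.
#' @export
detect_ps <- function(phase) {
  h <- nrow(phase); w <- ncol(phase)
  p00 <- phase[-h, -w]; p01 <- phase[-h, -1]
  p11 <- phase[-1, -1]; p10 <- phase[-1, -w]
  s <- wrap_angle(p01 - p00) + wrap_angle(p11 - p01) +
    wrap_angle(p10 - p11) + wrap_angle(p00 - p10)
  hit <- which(!is.na(s) & abs(s) > pi, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(row = numeric(0), col = numeric(0), charge = integer(0)))
  data.frame(row = hit[, 1] + 0.5, col = hit[, 2] + 0.5,
             charge = as.integer(sign(s[hit])))
}

#' Rotor-core ablation lesions
#'
#' Plans the ROTOR strategy from a baseline (unablated) AF episode: phase
#' singularities are detected in every snapshot of the mapping window,
#' their positions are clustered by single-linkage with spatial tolerance
#' `lesion_radius`, and a filled disc of radius `lesion_radius` is placed
#' at each cluster centroid. If no singularity is found the mask is empty
#' (the strategy will then fail by non-termination) with a warning.
#'
#' @param baseline a `sim_result` whose snapshots cover the mapping window.
#' @param disk the `tissue_disk` the baseline was run on.
#' @param lesion_radius lesion disc radius in pixels.
#' @param mapping_window length (ms) of the phase-mapping window (taken
#'   from the end of the recorded snapshots).
#' @return A `lesion_mask`.
#' @export
plan_rotor <- function(baseline, disk, lesion_radius = 4,
                       mapping_window = 200) {
  st <- baseline$snap_times
  if (length(st) < 8 || diff(range(st)) < mapping_window)
    stop("baseline run does not cover the mapping window")
  sel <- st >= max(st) - mapping_window
  ph <- compute_phase(baseline$snapshots[, , sel, drop = FALSE],
                      times = st[sel], min_window = mapping_window)
  pts <- do.call(rbind, lapply(seq_len(dim(ph)[3]), function(k) {
    detect_ps(ph[, , k])
  }))
  n <- disk$geometry$grid_shape[1]
  if (is.null(pts) || !nrow(pts)) {
    warning("no phase singularity found in the mapping window; empty mask")
    return(new_lesion_mask(matrix(FALSE, n, n), disk, "ROTOR"))
  }
  xy <- unique(pts[, c("row", "col")])
  if (nrow(xy) == 1) {
    centres <- xy
  } else {
    hc <- stats::hclust(stats::dist(xy), method = "single")
    grp <- stats::cutree(hc, h = lesion_radius)
    centres <- do.call(rbind, lapply(split(xy, grp), colMeans))
  }
  m <- matrix(FALSE, n, n)
  rr <- row(m); cc <- col(m)
  for (k in seq_len(nrow(centres)))
    m <- m | ((rr - centres[k, 1])^2 + (cc - centres[k, 2])^2 <=
                lesion_radius^2)
  new_lesion_mask(m, disk, "ROTOR")
}

#' The ablation success rule
#'
#' A strategy succeeds on a disk when the AF episode terminated within
#' `t_end` (2000 ms) and less than `max_ablated_fraction` (40%) of the
#' tissue was ablated.
#'
#' @param terminated logical.
#' @param termination_time ms (NA if not terminated).
#' @param ablated_fraction fraction of tissue pixels ablated.
#' @param t_end episode length (ms).
#' @param max_ablated_fraction ablation cap.
#' @return logical.
#' @export
success_rule <- function(terminated, termination_time, ablated_fraction,
                         t_end = 2000, max_ablated_fraction = 0.40) {
  isTRUE(terminated) && !is.na(termination_time) &&
    termination_time <= t_end && ablated_fraction < max_ablated_fraction
}

#' Evaluate one ablation strategy on a disk
#'
#' Runs the cross-field AF episode with the given lesions applied at
#' `lesion_time` and applies the success rule: the strategy succeeds if AF
#' terminated within `t_end` (2000 ms) *and* less than 40% of the tissue
#' was ablated.
#'
#' @param disk a `tissue_disk`.
#' @param lesions a `lesion_mask`.
#' @param params `fk_params`.
#' @param ... further simulation settings passed to [run_crossfield()].
#' @param max_ablated_fraction the 40% cap.
#' @return A `strategy_outcome`: strategy, lesions, terminated,
#'   termination_time, success.
#' @export
evaluate_strategy <- function(disk, lesions, params = fk_params(), ...,
                              max_ablated_fraction = 0.40) {
  res <- run_crossfield(disk, lesions = lesions, params = params, ...)
  success <- success_rule(res$terminated, res$termination_time,
                          lesions$ablated_fraction, res$t_end,
                          max_ablated_fraction)
  structure(list(strategy = lesions$strategy, lesions = lesions,
                 terminated = res$terminated,
                 termination_time = res$termination_time,
                 ablated_fraction = lesions$ablated_fraction,
                 success = success),
            class = "strategy_outcome")
}

#' Simulation settings for disk labelling
#'
#' Fixed study conditions for [label_disk()] and the cohort labelling run:
#' time step, episode length, lesion application time, rotor mapping
#' window and the termination detector settings.
#'
#' @param dt time step (ms).
#' @param t_end episode end (ms).
#' @param lesion_time ablation time (ms).
#' @param mapping_window rotor phase-mapping window (ms).
#' @param record_stride snapshot stride for the mapping window (ms).
#' @param lesion_radius,pvi_ring_width,fibro_min_region geometry defaults
#'   for the three planners.
#' @param s2_scan S2 coupling intervals (ms) probed in order during
#'   inducibility testing (programmed-stimulation style scan); the first
#'   interval that yields AF sustained to `t_end` is used.
#' @export
label_config <- function(dt = 0.05, t_end = 2000, lesion_time = 500,
                         mapping_window = 200, record_stride = 2,
                         lesion_radius = 4, pvi_ring_width = 2,
                         fibro_min_region = 9, s2_scan = seq(50, 130, 10)) {
  list(dt = dt, t_end = t_end, lesion_time = lesion_time,
       mapping_window = mapping_window, record_stride = record_stride,
       lesion_radius = lesion_radius, pvi_ring_width = pvi_ring_width,
       fibro_min_region = fibro_min_region, s2_scan = s2_scan)
}

#' Label a disk with the success of all three strategies
#'
#' Probes the S2 coupling intervals in `config$s2_scan` until one induces
#' AF that persists to `t_end` without ablation (the baseline episode,
#' also used for rotor mapping), then evaluates the three strategies with
#' that coupling interval and returns the multi-label ground truth
#' ordered (PVI, FIBRO, ROTOR). A disk for which no probed interval
#' sustains AF is flagged non-inducible (`inducible = FALSE`); such disks
#' are excluded from cohorts, since the success rule presumes ongoing AF.
#'
#' @param disk a `tissue_disk`.
#' @param params `fk_params`.
#' @param config see [label_config()].
#' @return List with `labels` (named logical 3-vector), `outcomes` (list
#'   of `strategy_outcome`), `inducible`, `baseline` (the baseline
#'   `sim_result`, snapshots dropped).
#' @export
label_disk <- function(disk, params = fk_params(), config = label_config()) {
  baseline <- NULL
  s2_used <- NA_real_
  for (s2 in config$s2_scan) {
    probe <- run_crossfield(
      disk, lesions = NULL, params = params, t_end = config$t_end,
      dt = config$dt, s2_time = s2,
      record = c(config$lesion_time - config$mapping_window,
                 config$lesion_time),
      record_stride = config$record_stride, stop_on_termination = TRUE)
    if (!probe$terminated) { baseline <- probe; s2_used <- s2; break }
  }
  inducible <- !is.null(baseline)
  run_args <- list(params = params, t_end = config$t_end, dt = config$dt,
                   s2_time = if (inducible) s2_used else config$s2_scan[1],
                   lesion_time = config$lesion_time,
                   record = c(-1, -1), record_stride = config$t_end)
  plans <- list(
    PVI = plan_pvi(disk, ring_width = config$pvi_ring_width),
    FIBRO = plan_fibro(disk, min_region_px = config$fibro_min_region),
    ROTOR = if (inducible)
      plan_rotor(baseline, disk, lesion_radius = config$lesion_radius,
                 mapping_window = config$mapping_window)
    else new_lesion_mask(matrix(FALSE, nrow(disk$label_grid),
                                ncol(disk$label_grid)), disk, "ROTOR"))
  outcomes <- lapply(plans, function(pl)
    do.call(evaluate_strategy, c(list(disk = disk, lesions = pl), run_args)))
  labels <- vapply(outcomes, function(o) o$success, logical(1))
  if (inducible) baseline$snapshots <- NULL
  list(labels = labels, outcomes = outcomes, inducible = inducible,
       baseline = baseline, s2_time = s2_used)
}

#' Label an entire cohort
#'
#' Applies [label_disk()] to every disk, appends the three label columns
#' and the inducibility flag to the manifest, and (by default) drops
#' non-inducible disks.
#'
#' @param cohort result of [generate_cohort()].
#' @param params `fk_params`.
#' @param config [label_config()].
#' @param keep_noninducible keep rows for non-inducible disks.
#' @param progress print one line per disk.
#' @return The cohort list with `manifest` gaining columns `pvi`, `fibro`,
#'   `rotor`, `inducible`, and `outcomes` (per-disk outcome lists).
#' @export
label_cohort <- function(cohort, params = fk_params(),
                         config = label_config(),
                         keep_noninducible = FALSE, progress = FALSE) {
  res <- lapply(seq_along(cohort$disks), function(i) {
    out <- label_disk(cohort$disks[[i]], params, config)
    if (progress)
      message(sprintf("%s: PVI=%d FIBRO=%d ROTOR=%d inducible=%d",
                      cohort$manifest$id[i], out$labels[1], out$labels[2],
                      out$labels[3], out$inducible))
    out
  })
  man <- cohort$manifest
  man$pvi <- vapply(res, function(r) r$labels[["PVI"]], logical(1))
  man$fibro <- vapply(res, function(r) r$labels[["FIBRO"]], logical(1))
  man$rotor <- vapply(res, function(r) r$labels[["ROTOR"]], logical(1))
  man$inducible <- vapply(res, function(r) r$inducible, logical(1))
  keep <- man$inducible | keep_noninducible
  list(disks = cohort$disks[keep], manifest = man[keep, ],
       outcomes = lapply(res[keep], function(r) r$outcomes),
       n_noninducible = sum(!man$inducible))
}
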