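#' Disk geometry with pulmonary-vein openings
#'
#' Builds the standardised circular left-atrial disk used throughout the
#' package: a centred circular tissue mask with four pulmonary-vein (PV)
#' openings placed in the periphery. Six fixed PV variants are available,
#' combining two PV radii (small/large) with three angular layouts; they
#' are a fixed design artefact of the generator and deterministic in
#' `pv_variant`.
#'
#' @param size grid side length in pixels (>= 64).
#' @param pv_variant integer 1..6.
#' @param pixel_spacing mm per pixel (default 0.3).
#' @return An object of class `disk_geometry` with fields `grid_shape`,
#'   `pixel_spacing`, `disk_mask` (logical matrix), `pv_list` (list of
#'   `c(row, col, radius)`), `pv_variant`.
#' @export
make_disk_geometry <- function(size, pv_variant, pixel_spacing = 0.3) {
  stopifnot(length(size) == 1, pv_variant %in% 1:6)
  if (size < 64) stop("invalid-geometry: size must be >= 64 pixels")
  ctr <- (size + 1) / 2
  r_disk <- size / 2 - 2
  rr <- row(matrix(0, size, size)) - ctr
  cc <- col(matrix(0, size, size)) - ctr
  d2 <- rr^2 + cc^2
  disk_mask <- d2 <= r_disk^2
  pv_radius <- if (pv_variant <= 3) max(2, round(0.045 * size)) else round(0.07 * size)
  offset <- c(0, 30, 60)[(pv_variant - 1) %% 3 + 1]
  angles <- (c(45, 135, 225, 315) + offset) * pi / 180
  r_pv_ctr <- 0.72 * r_disk
  pv_list <- lapply(angles, function(a) {
    c(row = ctr + r_pv_ctr * sin(a), col = ctr + r_pv_ctr * cos(a),
      radius = pv_radius)
  })
  for (pv in pv_list)
    if (sqrt((pv[1] - ctr)^2 + (pv[2] - ctr)^2) + pv[3] >= r_disk)
      stop("invalid-geometry: PV does not fit strictly inside the disk")
  structure(list(grid_shape = c(size, size), pixel_spacing = pixel_spacing,
                 disk_mask = disk_mask, pv_list = pv_list,
                 pv_variant = as.integer(pv_variant)),
            class = "disk_geometry")
}

# logical mask of all PV pixels for a geometry
pv_mask <- function(geometry) {
  size <- geometry$grid_shape[1]
  m <- matrix(FALSE, size, size)
  rr <- row(m); cc <- col(m)
  for (pv in geometry$pv_list)
    m <- m | ((rr - pv[1])^2 + (cc - pv[2])^2 <= pv[3]^2)
  m & geometry$disk_mask
}

#' Sample a spatially correlated base fibrosis field
#'
#' Synthetic surrogate for a patient's normalised LGE-MRI intensity map:
#' Gaussian white noise smoothed with a Gaussian kernel and min-max
#' rescaled to \[0,1\] inside the disk (linear rescaling, so the spatial
#' correlation structure is preserved). The kernel width is chosen so that
#' the field's autocorrelation drops to 1/e at `correlation_length`.
#'
#' @param geometry a `disk_geometry`.
#' @param correlation_length correlation length in mm (> pixel spacing);
#'   default 4 mm reproduces patchy fibrosis at disk scale.
#' @param seed integer seed; the field is reproducible from it.
#' @return An object of class `fibrosis_field`: list with `intensity`
#'   (matrix in \[0,1\], 0 outside the disk), `correlation_length`, `seed`.
#' @export
sample_base_fibrosis <- function(geometry, correlation_length = 4, seed) {
  stopifnot(correlation_length > geometry$pixel_spacing)
  size <- geometry$grid_shape[1]
  sigma_px <- (correlation_length / geometry$pixel_spacing) / 2
  noise <- withr::with_seed(seed, matrix(rnorm(size * size), size, size))
  sm <- smooth_gaussian_periodic(noise, sigma_px)
  sm <- rescale01(sm, geometry$disk_mask)
  structure(list(intensity = sm, correlation_length = correlation_length,
                 seed = seed, geometry = geometry),
            class = "fibrosis_field")
}

# Gaussian smoothing by FFT with periodic wrap-around. Smoothing white
# noise with kernel sd = sigma gives a field whose spatial autocorrelation
# is exp(-r^2 / (4 sigma^2)), i.e. 1/e at r = 2 sigma.
smooth_gaussian_periodic <- function(m, sigma) {
  n1 <- nrow(m); n2 <- ncol(m)
  d1 <- 0:(n1 - 1); d1 <- pmin(d1, n1 - d1)
  d2 <- 0:(n2 - 1); d2 <- pmin(d2, n2 - d2)
  k <- exp(-outer(d1^2, d2^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  Re(fft(fft(m) * fft(k), inverse = TRUE)) / (n1 * n2)
}

# min-max rescale inside a mask, zero outside; constant fields untouched
rescale01 <- function(m, mask) {
  v <- m[mask]
  rng <- range(v)
  if (diff(rng) > 0) m[mask] <- (v - rng[1]) / diff(rng)
  m[!mask] <- 0
  m
}

#' Weighted-average augmentation of fibrosis fields
#'
#' Builds a new fibrosis distribution as a convex combination of existing
#' fields: each input field receives a single scalar weight drawn
#' uniformly from (0,1) (applied to all its pixels) and the weighted
#' average is formed. Values remain in \[0,1\] by convexity.
#'
#' @param fields list of `fibrosis_field`s on identical geometry.
#' @param seed integer seed for the weights.
#' @return A `fibrosis_field` on the same geometry.
#' @export
weighted_average_augment <- function(fields, seed) {
  stopifnot(length(fields) >= 1)
  dims <- vapply(fields, function(f) dim(f$intensity), integer(2))
  if (any(dims != dims[, 1])) stop("shape error: fields on different grids")
  wts <- withr::with_seed(seed, runif(length(fields)))
  acc <- 0
  for (k in seq_along(fields)) acc <- acc + wts[k] * fields[[k]]$intensity
  out <- acc / sum(wts)
  out <- pmin(pmax(out, 0), 1)
  f1 <- fields[[1]]
  structure(list(intensity = out, correlation_length = f1$correlation_length,
                 seed = seed, geometry = f1$geometry),
            class = "fibrosis_field")
}

#' Elementary spatial transforms of a fibrosis field
#'
#' Deterministic building blocks of [affine_augment()]. Flips are exact
#' index reversals (involutions); rotation uses bilinear interpolation
#' about the grid centre (angle 0 is an exact identity); translation
#' shifts by whole pixels, discarding mass shifted outside the disk.
#' All three re-mask the result to the disk and never touch PV geometry.
#'
#' @param field a `fibrosis_field`.
#' @param axis `"horizontal"` or `"vertical"` flip axis.
#' @param angle rotation angle in degrees (counter-clockwise).
#' @param dr,dc translation in pixels (rows, cols).
#' @return A transformed `fibrosis_field`.
#' @name field-transforms
NULL

#' @rdname field-transforms
#' @export
field_flip <- function(field, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  m <- field$intensity
  m <- if (axis == "horizontal") m[, rev(seq_len(ncol(m)))] else m[rev(seq_len(nrow(m))), ]
  field$intensity <- remask(m, field$geometry)
  field
}

#' @rdname field-transforms
#' @export
field_rotate <- function(field, angle) {
  angle <- angle %% 360
  if (angle == 0) return(field)
  m <- field$intensity
  n <- nrow(m)
  ctr <- (n + 1) / 2
  th <- -angle * pi / 180  # inverse map
  rr <- row(m) - ctr; cc <- col(m) - ctr
  src_r <- ctr + cos(th) * rr - sin(th) * cc
  src_c <- ctr + sin(th) * rr + cos(th) * cc
  field$intensity <- remask(bilinear_sample(m, src_r, src_c), field$geometry)
  field
}

#' @rdname field-transforms
#' @export
field_translate <- function(field, dr, dc) {
  m <- field$intensity
  n <- nrow(m)
  out <- matrix(0, n, n)
  sr <- seq_len(n) - round(dr); sc <- seq_len(n) - round(dc)
  ok_r <- sr >= 1 & sr <= n; ok_c <- sc >= 1 & sc <= n
  out[ok_r, ok_c] <- m[sr[ok_r], sc[ok_c]]
  field$intensity <- remask(out, field$geometry)
  field
}

remask <- function(m, geometry) { m[!geometry$disk_mask] <- 0; m }

bilinear_sample <- function(m, src_r, src_c) {
  n <- nrow(m)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  get <- function(ri, ci) {
    ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= n
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok], ci[ok])]
    v
  }
  out <- (1 - fr) * (1 - fc) * get(r0, c0) + (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) + fr * fc * get(r0 + 1, c0 + 1)
  matrix(out, n, n)
}

#' Random affine augmentation of a fibrosis field
#'
#' Applies a randomly selected non-empty subset of {translation, rotation,
#' flip} to the fibrosis intensity inside the disk. Intensity carried
#' outside the disk is clipped; the PV geometry is left untouched.
#'
#' @param field a `fibrosis_field`.
#' @param seed integer seed; the transform selection and magnitudes are
#'   reproducible from it.
#' @param max_shift_frac maximum translation as a fraction of grid size.
#' @return A transformed `fibrosis_field`.
#' @export
affine_augment <- function(field, seed, max_shift_frac = 0.1) {
  n <- nrow(field$intensity)
  withr::with_seed(seed, {
    repeat {
      use <- runif(3) < 0.5
      if (any(use)) break
    }
    if (use[1]) {
      sh <- round(runif(2, -max_shift_frac, max_shift_frac) * n)
      field <- field_translate(field, sh[1], sh[2])
    }
    if (use[2]) field <- field_rotate(field, runif(1, 0, 360))
    if (use[3]) field <- field_flip(field, sample(c("horizontal", "vertical"), 1))
  })
  field
}

#' Threshold a fibrosis field into a labelled tissue disk
#'
#' Pixels with intensity at or above `threshold` (inside the disk,
#' outside the PV openings) become fibrotic; remaining disk pixels are
#' healthy; PV pixels and the exterior keep their own labels. The
#' fibrotic fraction (fibrotic / (fibrotic + healthy)) is stored with the
#' disk and is monotone non-increasing in the threshold.
#'
#' @param field a `fibrosis_field`.
#' @param geometry a `disk_geometry` (defaults to the field's own).
#' @param threshold threshold in (0,1).
#' @param provenance optional named list recorded with the disk.
#' @return An object of class `tissue_disk`: `geometry`, `label_grid`
#'   (integer matrix: 0 outside, 1 healthy, 2 fibrotic, 3 PV),
#'   `fibrotic_fraction`, `intensity`, `provenance`.
#' @export
threshold_fibrosis <- function(field, geometry = field$geometry, threshold,
                               provenance = list()) {
  stopifnot(threshold > 0)
  lab <- matrix(LBL_OUTSIDE, geometry$grid_shape[1], geometry$grid_shape[2])
  pv <- pv_mask(geometry)
  tissue <- geometry$disk_mask & !pv
  lab[tissue] <- ifelse(field$intensity[tissue] >= threshold,
                        LBL_FIBROTIC, LBL_HEALTHY)
  lab[pv] <- LBL_PV
  n_fib <- sum(lab == LBL_FIBROTIC)
  n_tis <- sum(tissue)
  structure(list(geometry = geometry, label_grid = lab,
                 fibrotic_fraction = n_fib / n_tis,
                 intensity = field$intensity,
                 provenance = c(list(threshold = threshold), provenance)),
            class = "tissue_disk")
}

#' Tissue mask of a disk
#'
#' Logical matrix of conducting pixels (healthy or fibrotic).
#' @param disk a `tissue_disk`.
#' @export
tissue_mask <- function(disk) {
  disk$label_grid == LBL_HEALTHY | disk$label_grid == LBL_FIBROTIC
}

#' Cohort generator configuration
#'
#' Fixed study conditions for [generate_cohort()]: disk size (pixels),
#' fibrosis correlation length (mm), the uniform range the per-disk
#' fibrosis threshold is drawn from, and whether synthetic
#' weighted-average fields are contrast-stretched back to \[0,1\] before
#' thresholding (averaging many fields compresses the intensity range).
#'
#' @param size disk side in pixels.
#' @param correlation_length mm.
#' @param threshold_range uniform range for the fibrosis threshold.
#' @param contrast_stretch logical.
#' @export
cohort_config <- function(size = 100, correlation_length = 4,
                          threshold_range = c(0.55, 0.75),
                          contrast_stretch = TRUE) {
  list(size = size, correlation_length = correlation_length,
       threshold_range = threshold_range, contrast_stretch = contrast_stretch)
}

#' Generate a virtual cohort of tissue disks
#'
#' Builds `n_base` independent base disks (fresh correlated-noise fibrosis
#' field, random PV variant, random threshold) plus `n_synthetic`
#' augmented disks. Each synthetic disk is a weighted average of all base
#' fields with fresh uniform weights, followed by a random affine
#' augmentation, a random threshold and a random PV variant. The whole
#' cohort is bitwise reproducible from `seed`.
#'
#' @param n_base number of base disks (>= 1).
#' @param n_synthetic number of augmented disks.
#' @param seed master seed.
#' @param config see [cohort_config()].
#' @return List with `disks` (list of `tissue_disk`) and `manifest`
#'   (tibble: id, kind, pv_variant, threshold, fibrotic_fraction, seed
#'   columns).
#' @export
generate_cohort <- function(n_base, n_synthetic = 0, seed = 1,
                            config = cohort_config()) {
  stopifnot(n_base >= 1, n_synthetic >= 0)
  draws <- withr::with_seed(seed, {
    n <- n_base + n_synthetic
    list(field_seed = sample.int(2^30, n),
         aug_seed = sample.int(2^30, n),
         pv_variant = sample.int(6, n, replace = TRUE),
         threshold = runif(n, config$threshold_range[1],
                           config$threshold_range[2]))
  })
  base_fields <- vector("list", n_base)
  disks <- vector("list", n_base + n_synthetic)
  ids <- character(n_base + n_synthetic)
  for (i in seq_len(n_base)) {
    geo <- make_disk_geometry(config$size, draws$pv_variant[i])
    f <- sample_base_fibrosis(geo, config$correlation_length,
                              draws$field_seed[i])
    base_fields[[i]] <- f
    ids[i] <- sprintf("base_%03d", i)
    disks[[i]] <- threshold_fibrosis(
      f, geo, draws$threshold[i],
      provenance = list(id = ids[i], kind = "base",
                        field_seed = draws$field_seed[i]))
  }
  for (j in seq_len(n_synthetic)) {
    k <- n_base + j
    geo <- make_disk_geometry(config$size, draws$pv_variant[k])
    f <- weighted_average_augment(base_fields, draws$field_seed[k])
    # stretch before the affine step: transforms import structural zeros
    # into the disk, which would otherwise wreck a later min-max rescale
    if (isTRUE(config$contrast_stretch))
      f$intensity <- rescale01(f$intensity, f$geometry$disk_mask)
    f <- affine_augment(f, draws$aug_seed[k])
    f$geometry <- geo  # synthetic disk carries its own PV variant
    ids[k] <- sprintf("synth_%03d", j)
    disks[[k]] <- threshold_fibrosis(
      f, geo, draws$threshold[k],
      provenance = list(id = ids[k], kind = "synthetic",
                        field_seed = draws$field_seed[k],
                        aug_seed = draws$aug_seed[k]))
  }
  manifest <- tibble::tibble(
    id = ids,
    kind = rep(c("base", "synthetic"), c(n_base, n_synthetic)),
    pv_variant = draws$pv_variant,
    threshold = draws$threshold,
    fibrotic_fraction = vapply(disks, function(d) d$fibrotic_fraction, 0),
    field_seed = draws$field_seed,
    aug_seed = draws$aug_seed)
  list(disks = disks, manifest = manifest)
}

#' Serialise a tissue disk to plain-text files
#'
#' Writes the label grid as CSV and the geometry/provenance as a JSON
#' sidecar; [read_disk()] restores the disk (without the continuous
#' intensity field, which is reproducible from the recorded seeds).
#'
#' @param disk a `tissue_disk`.
#' @param path basename (without extension) to write `<path>.csv` and
#'   `<path>.json`.
#' @export
write_disk <- function(disk, path) {
  write.table(disk$label_grid, paste0(path, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  meta <- list(grid_shape = disk$geometry$grid_shape,
               pixel_spacing = disk$geometry$pixel_spacing,
               pv_variant = disk$geometry$pv_variant,
               fibrotic_fraction = disk$fibrotic_fraction,
               provenance = disk$provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_disk
#' @export
read_disk <- function(path) {
  lab <- as.matrix(read.csv(paste0(path, ".csv"), header = FALSE))
  dimnames(lab) <- NULL
  mode(lab) <- "integer"
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  geo <- make_disk_geometry(meta$grid_shape[1], meta$pv_variant,
                            meta$pixel_spacing)
  tissue <- geo$disk_mask & !pv_mask(geo)
  structure(list(geometry = geo, label_grid = lab,
                 fibrotic_fraction = sum(lab == LBL_FIBROTIC) / sum(tissue),
                 intensity = NULL, provenance = as.list(meta$provenance)),
            class = "tissue_disk")
}
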