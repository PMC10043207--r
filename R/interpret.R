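new_fa_map <- function(attribution, method, class_index) {
  structure(list(attribution = attribution, method = method,
                 class_index = as.integer(class_index)),
            class = "fa_map")
}

# resolve a model argument into a scoring closure image -> score vector
score_function <- function(model) {
  if (inherits(model, "af_cnn"))
    function(img) as.numeric(predict(model, img))
  else if (is.function(model)) model
  else stop("model must be an af_cnn or a scoring function")
}

#' GradCAM attribution map
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' layer: each activation channel receives a weight equal to the global
#' average of the gradient of the (pre-sigmoid) class score with respect
#' to that channel, and the map is the rectified weighted sum of the
#' activation channels, upsampled bilinearly to the input resolution.
#' Attributions are therefore non-negative by construction.
#'
#' @param model an `af_cnn`.
#' @param image input image matrix (model input size).
#' @param class_index class of interest, 1..3 (PVI, FIBRO, ROTOR).
#' @return An `fa_map`.
#' @export
gradcam <- function(model, image, class_index) {
  conf <- c(unclass(model$spec), model$config)
  g <- cnn_lastconv_grad_cpp(model$weights, conf, image,
                             as.integer(class_index) - 1L)
  alpha <- apply(g$dA, 3, mean)
  map <- 0
  for (k in seq_along(alpha)) map <- map + alpha[k] * g$A[, , k]
  map <- pmax(map, 0)
  n <- nrow(image)
  if (nrow(map) != n)
    map <- EBImage::resize(map, w = n, h = n)  # bilinear
  map[map < 0] <- 0
  new_fa_map(map, "GRADCAM", class_index)
}

#' Occlusion attribution map
#'
#' Slides a `patch_size` square across the image with the given stride,
#' replaces the patch with `baseline_value`, and records the drop in the
#' class score. Each pixel's attribution is the mean score drop over all
#' patches covering it.
#'
#' @param model an `af_cnn` or a scoring function `image -> scores`.
#' @param image input image matrix.
#' @param class_index class of interest (1-based).
#' @param patch_size occluder side in pixels.
#' @param stride step between patch positions.
#' @param baseline_value replacement value (0 = background).
#' @return An `fa_map`.
#' @export
occlusion_map <- function(model, image, class_index, patch_size = 16,
                          stride = 8, baseline_value = 0) {
  stopifnot(patch_size >= 1, stride >= 1)
  n <- nrow(image)
  if (patch_size > n) stop("patch larger than image")
  f <- score_function(model)
  base_score <- f(image)[class_index]
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  starts <- unique(pmin(seq(1, n, by = stride), n - patch_size + 1))
  for (r0 in starts)
    for (c0 in starts) {
      ri <- r0:(r0 + patch_size - 1); ci <- c0:(c0 + patch_size - 1)
      pert <- image
      pert[ri, ci] <- baseline_value
      d <- base_score - f(pert)[class_index]
      acc[ri, ci] <- acc[ri, ci] + d
      cnt[ri, ci] <- cnt[ri, ci] + 1
    }
  cnt[cnt == 0] <- 1
  new_fa_map(acc / cnt, "OCCLUSION", class_index)
}

#' LIME attribution map
#'
#' Local surrogate explanation: the image is segmented into a regular
#' grid of superpixels, random on/off perturbations are drawn (off
#' superpixels replaced by `baseline_value`), the model is scored on each
#' perturbed image, and a weighted ridge surrogate is fitted with an
#' exponential kernel on the L2 distance between the perturbation and
#' the unperturbed instance. The largest `top_k` coefficients (by
#' absolute value) are kept and broadcast to their superpixels.
#'
#' @param model an `af_cnn` or a scoring function.
#' @param image input image matrix.
#' @param class_index class of interest (1-based).
#' @param n_superpixels approximate number of grid superpixels (>= 2).
#' @param n_samples number of perturbed samples (>= n_superpixels).
#' @param kernel_width kernel width in units of sqrt(#superpixels).
#' @param top_k number of superpixel coefficients kept.
#' @param baseline_value replacement for switched-off superpixels.
#' @param seed RNG seed; the map is reproducible from it.
#' @return An `fa_map`.
#' @export
lime_map <- function(model, image, class_index, n_superpixels = 49,
                     n_samples = 1000, kernel_width = 0.25, top_k = 10,
                     baseline_value = 0, seed = 1) {
  stopifnot(n_samples >= n_superpixels)
  if (n_superpixels < 2) stop("degenerate segmentation: need >= 2 superpixels")
  n <- nrow(image)
  side <- max(2, round(sqrt(n_superpixels)))
  seg <- matrix(0L, n, n)
  cuts_r <- pmin(side, ceiling(seq_len(n) / (n / side)))
  seg[] <- (cuts_r[row(seg)] - 1L) * side + cuts_r[col(seg)]
  m <- side * side
  f <- score_function(model)
  Z <- withr::with_seed(seed,
    matrix(runif(n_samples * m) < 0.5, n_samples, m))
  Z[1, ] <- TRUE  # include the unperturbed instance
  y <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    pert <- image
    off <- which(!Z[s, ])
    if (length(off)) pert[seg %in% off] <- baseline_value
    y[s] <- f(pert)[class_index]
  }
  d <- sqrt(rowSums(!Z))                       # L2 distance in {0,1}^m
  wts <- exp(-(d / (kernel_width * sqrt(m)))^2)
  X <- cbind(1, Z * 1)
  XtW <- t(X * wts)
  pen <- diag(1e-3, m + 1)
  pen[1, 1] <- 0  # intercept unpenalised
  beta <- solve(XtW %*% X + pen, XtW %*% y)
  coefs <- beta[-1]
  keep <- order(abs(coefs), decreasing = TRUE)[seq_len(min(top_k, m))]
  coefs[setdiff(seq_len(m), keep)] <- 0
  map <- matrix(coefs[seg], n, n)
  new_fa_map(map, "LIME", class_index)
}

#' Threshold a feature-attribution map into an informative region
#'
#' The informative region is the set of tissue pixels whose attribution
#' strictly exceeds `factor` times the mean attribution over tissue
#' pixels (background is excluded from the mean, which would otherwise
#' deflate it and inflate the region).
#'
#' @param fa an `fa_map`.
#' @param disk the `tissue_disk` the map belongs to.
#' @param factor threshold factor (1.0 default; 0.75/1.25 for the
#'   sensitivity analysis).
#' @return An `informative_region`: `mask`, `threshold_factor`,
#'   `threshold_value`.
#' @export
threshold_fa <- function(fa, disk, factor = 1.0) {
  stopifnot(factor > 0)
  att <- fa$attribution
  tis <- tissue_mask(disk)
  if (!identical(dim(att), dim(tis))) {
    idx <- pmin(nrow(tis), pmax(1L, round(seq(1, nrow(tis),
                                              length.out = nrow(att)))))
    tis <- tis[idx, idx]
  }
  thr <- factor * mean(att[tis])
  structure(list(mask = (att > thr) & tis, threshold_factor = factor,
                 threshold_value = thr),
            class = "informative_region")
}

#' Interpretability metrics for one map/lesion pair
#'
#' Scores an informative region R against a lesion mask L on the same
#' grid: IoU = |R n L| / |R u L|; lesion percentage = |R n L| / |L|
#' (fraction of the lesions found inside the region); NAT percentage =
#' |R n H| / |R| where H is healthy tissue carrying neither lesion nor
#' fibrosis (fraction of the region wasted on non-arrhythmogenic
#' tissue). Metrics with an empty denominator are NA.
#'
#' @param region an `informative_region` (or logical matrix).
#' @param lesions a `lesion_mask` (or logical matrix).
#' @param disk the `tissue_disk`.
#' @return List with `iou`, `lesion_pct`, `nat_pct`.
#' @export
compute_metrics <- function(region, lesions, disk) {
  R <- if (inherits(region, "informative_region")) region$mask else region
  L <- if (inherits(lesions, "lesion_mask")) lesions$mask else lesions
  lab <- disk$label_grid
  if (!identical(dim(R), dim(L)) || !identical(dim(R), dim(lab)))
    stop("grid mismatch between region, lesions and disk")
  H <- (lab == LBL_HEALTHY) & !L
  inter <- sum(R & L)
  uni <- sum(R | L)
  list(iou = if (uni == 0) NA_real_ else inter / uni,
       lesion_pct = if (sum(L) == 0) NA_real_ else inter / sum(L),
       nat_pct = if (sum(R) == 0) NA_real_ else sum(R & H) / sum(R))
}

#' Population-level average of maps or masks
#'
#' Min-max normalises every item to \[0,1\] and returns the pixel-wise
#' mean (used for cohort-level attribution and lesion-density maps).
#'
#' @param items list of matrices, `fa_map`s or `lesion_mask`s on one grid.
#' @return A matrix with values in \[0,1\].
#' @export
population_average <- function(items) {
  if (!length(items)) stop("empty list")
  grids <- lapply(items, function(it) {
    m <- if (inherits(it, "fa_map")) it$attribution
    else if (inherits(it, "lesion_mask")) it$mask * 1.0
    else it * 1.0
    rng <- range(m)
    if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  })
  Reduce(`+`, grids) / length(grids)
}

#' Full interpretability study on a hold-out set
#'
#' For every disk, attribution method and strategy class: computes the FA
#' map, thresholds it at each factor, scores it against that strategy's
#' lesions and records whether the model classified the disk correctly
#' for that strategy. Returns a long-format table plus population
#' averages per method and strategy.
#'
#' @param model the best-fold `af_cnn`.
#' @param disks hold-out `tissue_disk`s.
#' @param lesions_by_disk list (per disk) of named lists of
#'   `lesion_mask`s (`PVI`, `FIBRO`, `ROTOR`).
#' @param labels hold-out label matrix (rows = disks).
#' @param methods subset of `c("GRADCAM", "LIME", "OCCLUSION")`.
#' @param factors threshold factors.
#' @param seed base seed for the stochastic (LIME) maps.
#' @param occlusion_args,lime_args named lists of extra arguments.
#' @return List: `table` (tibble), `averages` (nested list of matrices).
#' @export
run_interpretability_study <- function(model, disks, lesions_by_disk, labels,
                                       methods = c("GRADCAM", "LIME",
                                                   "OCCLUSION"),
                                       factors = c(0.75, 1.0, 1.25),
                                       seed = 1,
                                       occlusion_args = list(),
                                       lime_args = list()) {
  strategies <- c("PVI", "FIBRO", "ROTOR")
  rows <- list()
  maps <- list()
  input_size <- model$spec$input_size
  for (d in seq_along(disks)) {
    disk <- disks[[d]]
    img <- disk_to_image(disk, input_size)
    scores <- as.numeric(predict(model, img))
    for (ci in seq_along(strategies)) {
      les <- lesions_by_disk[[d]][[strategies[ci]]]
      correct <- (scores[ci] >= 0.5) == as.logical(labels[d, ci])
      for (meth in methods) {
        fa <- switch(meth,
          GRADCAM = gradcam(model, img, ci),
          OCCLUSION = do.call(occlusion_map,
                              c(list(model, img, ci), occlusion_args)),
          LIME = do.call(lime_map,
                         c(list(model, img, ci),
                           lime_args, list(seed = seed + d))))
        att_full <- resample_to(fa$attribution, nrow(disk$label_grid))
        maps[[meth]][[strategies[ci]]][[length(maps[[meth]][[strategies[ci]]]) + 1]] <-
          att_full
        for (fct in factors) {
          reg <- threshold_fa(
            new_fa_map(att_full, meth, ci), disk, fct)
          met <- compute_metrics(reg, les, disk)
          rows[[length(rows) + 1]] <- tibble::tibble(
            disk = d, method = meth, strategy = strategies[ci],
            factor = fct, iou = met$iou, lesion_pct = met$lesion_pct,
            nat_pct = met$nat_pct, correct = correct)
        }
      }
    }
  }
  averages <- lapply(maps, function(by_strat)
    lapply(by_strat, population_average))
  list(table = do.call(rbind, rows), averages = averages)
}

# nearest-neighbour resample of a square matrix to side n
resample_to <- function(m, n) {
  if (nrow(m) == n) return(m)
  idx <- pmin(nrow(m), pmax(1L, round(seq(1, nrow(m), length.out = n))))
  m[idx, idx]
}
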