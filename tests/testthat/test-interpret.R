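test_that("GradCAM reproduces the analytic map of a hand-built conv model", {
  m <- handbuilt_cnn()
  img <- matrix(0, 8, 8)
  img[3, 3] <- 1; img[6, 7] <- 0.5  # two active pixels
  fa <- gradcam(m, img, class_index = 2)
  expect_s3_class(fa, "fa_map")
  expect_true(all(fa$attribution >= 0))
  # analytic construction: A_k = k * img (centre-tap kernels), pooled by
  # 2x2 max; d(logit_2)/dA lands on each pool argmax with the fc weight
  fcW <- m$weights$fcW[[1]]
  A <- list(img, 2 * img)
  dA <- list(matrix(0, 8, 8), matrix(0, 8, 8))
  for (k in 1:2) for (pi_ in 1:4) for (pj in 1:4) {
    blk <- A[[k]][(2 * pi_ - 1):(2 * pi_), (2 * pj - 1):(2 * pj)]
    am <- which(blk == max(blk), arr.ind = TRUE)[1, ]
    unit <- (k - 1) * 16 + (pj - 1) * 4 + pi_
    dA[[k]][2 * pi_ - 2 + am[1], 2 * pj - 2 + am[2]] <- fcW[2, unit]
  }
  alpha <- vapply(dA, mean, 0)
  ref <- pmax(alpha[1] * A[[1]] + alpha[2] * A[[2]], 0)
  expect_equal(fa$attribution, ref, tolerance = 1e-6)
  # invariance to a constant added to the class logit (bias shift)
  m2 <- m; m2$weights$fcb[[1]][2] <- 10
  expect_equal(gradcam(m2, img, 2)$attribution, fa$attribution,
               tolerance = 1e-12)
  # zero gradient to a class -> all-zero map
  expect_true(all(gradcam(m, img, 3)$attribution == 0))
})

test_that("occlusion maps are exact for a linear scorer", {
  n <- 8
  withr::with_seed(5, W <- matrix(runif(n * n, -1, 1), n, n))
  lin <- function(img) c(sum(W * img), 0)
  withr::with_seed(6, img <- matrix(runif(n * n), n, n))
  # non-overlapping patch grid: attribution over a patch is its own
  # weighted mass sum(W * (x - baseline)) exactly
  fa <- occlusion_map(lin, img, 1, patch_size = 4, stride = 4,
                      baseline_value = 0)
  for (r0 in c(1, 5)) for (c0 in c(1, 5)) {
    ri <- r0:(r0 + 3); ci <- c0:(c0 + 3)
    expect_equal(fa$attribution[ri, ci],
                 matrix(sum(W[ri, ci] * img[ri, ci]), 4, 4),
                 tolerance = 1e-10)
  }
  # a model that ignores the image gives a null map
  fa0 <- occlusion_map(function(img) c(1, 2), img, 1,
                       patch_size = 4, stride = 4)
  expect_true(all(fa0$attribution == 0))
  # overlapping patches: pixel value is the mean of its covering patches
  fa2 <- occlusion_map(lin, img, 1, patch_size = 4, stride = 2)
  starts <- unique(pmin(seq(1, n, 2), n - 3))
  deltas <- matrix(NA_real_, length(starts), length(starts))
  for (a in seq_along(starts)) for (b in seq_along(starts)) {
    ri <- starts[a]:(starts[a] + 3); ci <- starts[b]:(starts[b] + 3)
    deltas[a, b] <- sum(W[ri, ci] * img[ri, ci])
  }
  px <- c(4, 4)  # covered by patches starting at rows/cols {1,3} x {1,3}
  cover <- expand.grid(a = which(starts %in% c(1, 3)),
                       b = which(starts %in% c(1, 3)))
  expect_equal(fa2$attribution[4, 4],
               mean(deltas[cbind(cover$a, cover$b)]), tolerance = 1e-10)
  expect_error(occlusion_map(lin, img, 1, patch_size = 20), "patch")
})

test_that("LIME recovers planted superpixel dependence deterministically", {
  n <- 28
  # scorer depends only on superpixel k being fully present
  planted <- 5L
  seg_side <- 4
  seg <- matrix(0L, n, n)
  cuts <- pmin(seg_side, ceiling(seq_len(n) / (n / seg_side)))
  seg[] <- (cuts[row(seg)] - 1L) * seg_side + cuts[col(seg)]
  scorer <- function(img) c(as.numeric(all(img[seg == planted] > 0)), 0)
  img <- matrix(1, n, n)
  fa <- lime_map(scorer, img, 1, n_superpixels = 16, n_samples = 200,
                 seed = 7)
  coefs <- vapply(1:16, function(k) fa$attribution[which(seg == k)[1]], 0)
  expect_equal(which.max(coefs), planted)
  expect_gt(coefs[planted], max(coefs[-planted]) + 1e-6)
  # determinism from the seed
  fa2 <- lime_map(scorer, img, 1, n_superpixels = 16, n_samples = 200,
                  seed = 7)
  expect_identical(fa$attribution, fa2$attribution)
  # constant model: all coefficients vanish within fit tolerance
  fa0 <- lime_map(function(img) c(0.3, 0), img, 1, n_superpixels = 16,
                  n_samples = 100, seed = 1)
  expect_lt(max(abs(fa0$attribution)), 1e-6)
  expect_error(lime_map(scorer, img, 1, n_superpixels = 1, n_samples = 10),
               "degenerate")
})

test_that("informative regions threshold at the tissue-mean attribution", {
  disk <- small_disk()
  tis <- tissue_mask(disk)
  # constant map: strict inequality leaves the region empty
  fa_const <- structure(list(attribution = matrix(1, 64, 64),
                             method = "GRADCAM", class_index = 1L),
                        class = "fa_map")
  expect_equal(sum(threshold_fa(fa_const, disk)$mask), 0)
  # two-level map: the high half alone survives factor 1.0
  att <- matrix(0, 64, 64)
  att[tis] <- 1; att[tis & col(att) > 32] <- 2
  fa2 <- structure(list(attribution = att, method = "GRADCAM",
                        class_index = 1L), class = "fa_map")
  reg <- threshold_fa(fa2, disk, 1.0)
  expect_true(all(att[reg$mask] == 2))
  expect_equal(sum(reg$mask), sum(tis & att == 2))
  # monotone nesting across the sensitivity factors
  f <- sample_base_fibrosis(disk$geometry, 4, seed = 12)
  fa3 <- structure(list(attribution = f$intensity, method = "OCCLUSION",
                        class_index = 1L), class = "fa_map")
  r125 <- threshold_fa(fa3, disk, 1.25)$mask
  r100 <- threshold_fa(fa3, disk, 1.0)$mask
  r075 <- threshold_fa(fa3, disk, 0.75)$mask
  expect_true(all(!r125 | r100))
  expect_true(all(!r100 | r075))
})

test_that("interpretability metrics equal naive set arithmetic", {
  disk <- small_disk()
  tis <- tissue_mask(disk)
  pick <- function(mask, k, seed) {
    idx <- withr::with_seed(seed, sample(which(mask), k))
    m <- matrix(FALSE, 64, 64); m[idx] <- TRUE; m
  }
  R <- pick(tis, 40, 1)
  met <- compute_metrics(R, R, disk)
  expect_equal(met$iou, 1); expect_equal(met$lesion_pct, 1)
  expect_equal(met$nat_pct, 0)
  # disjoint region entirely on lesion-free healthy tissue
  healthy <- disk$label_grid == 1L
  R2 <- pick(healthy, 30, 2)
  L2 <- pick(tis & !R2, 30, 3)
  met2 <- compute_metrics(R2, L2, disk)
  expect_equal(met2$iou, 0); expect_equal(met2$lesion_pct, 0)
  expect_equal(met2$nat_pct, 1)
  # hand-counted overlap: R = 2 px, L = 2 px, 1 shared
  ii <- which(tis)[1:3]
  R3 <- matrix(FALSE, 64, 64); R3[ii[1:2]] <- TRUE
  L3 <- matrix(FALSE, 64, 64); L3[ii[2:3]] <- TRUE
  met3 <- compute_metrics(R3, L3, disk)
  expect_equal(met3$iou, 1 / 3); expect_equal(met3$lesion_pct, 1 / 2)
  # random mask pairs against the set-arithmetic oracle
  for (s in 1:40) {
    R4 <- pick(tis, 25 + s, 100 + s)
    L4 <- pick(tis, 60, 200 + s)
    met4 <- compute_metrics(R4, L4, disk)
    expect_identical(met4$iou, sum(R4 & L4) / sum(R4 | L4))
    expect_identical(met4$lesion_pct, sum(R4 & L4) / sum(L4))
    expect_identical(met4$nat_pct,
                     sum(R4 & healthy & !L4) / sum(R4))
  }
  # empty denominators are reported missing
  none <- matrix(FALSE, 64, 64)
  met5 <- compute_metrics(none, none, disk)
  expect_true(is.na(met5$iou) && is.na(met5$lesion_pct) &&
                is.na(met5$nat_pct))
  expect_error(compute_metrics(matrix(FALSE, 3, 3), none, disk), "mismatch")
})

test_that("population averages are normalised, idempotent means", {
  withr::with_seed(4, m1 <- matrix(runif(64), 8, 8))
  one <- population_average(list(m1))
  expect_equal(min(one), 0); expect_equal(max(one), 1)
  expect_equal(population_average(list(m1, m1)), one)
  withr::with_seed(5, m2 <- matrix(runif(64, 2, 7), 8, 8))
  avg <- population_average(list(m1, m2))
  expect_true(all(avg >= 0 & avg <= 1))
  expect_error(population_average(list()), "empty")
})

test_that("the interpretability study emits one row per cell of the design", {
  toy <- toy_images(24, size = 16, seed = 13)
  m <- train_fold(toy$images, toy$labels, 1:18, 19:24, tiny_spec(),
                  train_config(epochs = 2, lr = 1e-3, batch_size = 8,
                               seed = 4))
  disks <- list(small_disk(seed = 1), small_disk(seed = 2))
  lesions <- lapply(disks, function(d)
    list(PVI = plan_pvi(d), FIBRO = plan_fibro(d),
         ROTOR = plan_pvi(d, ring_width = 1)))
  labels <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3)
  # NOTE: model input 16 != disk grid 64; maps are resampled up
  st <- run_interpretability_study(
    m, disks, lesions, labels, factors = c(0.75, 1.0, 1.25), seed = 9,
    occlusion_args = list(patch_size = 4, stride = 4),
    lime_args = list(n_superpixels = 16, n_samples = 60))
  expect_equal(nrow(st$table), 2 * 3 * 3 * 3)
  gc_rows <- st$table[st$table$method == "GRADCAM", ]
  expect_true(all(gc_rows$iou >= 0 | is.na(gc_rows$iou)))
  st2 <- run_interpretability_study(
    m, disks, lesions, labels, factors = c(0.75, 1.0, 1.25), seed = 9,
    occlusion_args = list(patch_size = 4, stride = 4),
    lime_args = list(n_superpixels = 16, n_samples = 60))
  expect_identical(st$table, st2$table)
  expect_named(st$averages, c("GRADCAM", "LIME", "OCCLUSION"),
               ignore.order = TRUE)
})
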