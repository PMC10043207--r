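test_that("PVI rings encircle each PV inside the tissue", {
  disk <- small_disk()
  les <- plan_pvi(disk, ring_width = 2)
  expect_s3_class(les, "lesion_mask")
  comp <- EBImage::bwlabel(les$mask)
  expect_equal(max(comp), 4)
  expect_error(plan_pvi(disk, ring_width = 0))
  # every lesion pixel lies within ring_width + 1 of a PV boundary
  geo <- disk$geometry
  idx <- which(les$mask, arr.ind = TRUE)
  dmin <- apply(idx, 1, function(px) {
    min(vapply(geo$pv_list, function(pv)
      abs(sqrt((px[1] - pv[1])^2 + (px[2] - pv[2])^2) - pv[3]), 0))
  })
  expect_true(all(dmin <= 3))
  # fraction recomputable
  expect_equal(les$ablated_fraction, sum(les$mask) / sum(tissue_mask(disk)))
})

test_that("FIBRO lesions trace fibrotic perimeters only", {
  # no fibrosis: empty mask
  disk0 <- small_disk(threshold = 1.1)
  expect_equal(plan_fibro(disk0)$ablated_fraction, 0)
  # a hand-built 10x10 fibrotic square: hollow 1-px outline
  disk <- small_disk(threshold = 1.1)
  disk$label_grid[25:34, 25:34] <- 2L
  les <- plan_fibro(disk)
  expect_lte(sum(les$mask), 44)
  expect_equal(sum(les$mask), 36)
  expect_true(all(!les$mask[27:32, 27:32]))  # interior untouched
  # general disk: mask within the morphological boundary zone
  disk2 <- small_disk(threshold = 0.55)
  fib <- disk2$label_grid == 2L
  les2 <- plan_fibro(disk2)
  ker <- matrix(1, 3, 3)
  dil <- EBImage::dilate(fib, ker); ero <- EBImage::erode(fib, ker)
  expect_true(all(!les2$mask | (dil & !ero)))
  # speckle below the minimum region size is ignored
  disk3 <- small_disk(threshold = 1.1)
  disk3$label_grid[40, 40] <- 2L
  expect_equal(sum(plan_fibro(disk3, min_region_px = 9)$mask), 0)
})

test_that("analytic-signal phase recovers sinusoid structure", {
  nt <- 64; ts <- seq(0, 315, length.out = nt)  # ~5 ms sampling
  f <- 1 / 70
  arr <- array(0, dim = c(3, 3, nt))
  for (k in seq_len(nt)) {
    arr[, , k] <- sin(2 * pi * f * ts[k])
    arr[2, 2, k] <- sin(2 * pi * f * ts[k] + pi / 2)
    arr[3, 3, k] <- 0.5  # constant pixel: undefined phase
  }
  ph <- compute_phase(arr, times = ts, min_window = 200)
  # uniform phase advance at rate 2*pi*f
  mid <- 10:50
  slope <- diff(range(unwrap_phase(ph[1, 1, mid]))) /
    diff(range(ts[mid]))
  expect_equal(slope, 2 * pi * f, tolerance = 0.01)
  # 90-degree shifted pixel leads by pi/2
  dphi <- wrap_to_pi(ph[2, 2, mid] - ph[1, 1, mid])
  expect_equal(mean(dphi), pi / 2, tolerance = 0.05)
  # constant pixel flagged undefined
  expect_true(all(is.na(ph[3, 3, ])))
  # window too short
  expect_error(compute_phase(arr[, , 1:5], times = ts[1:5]), "window")
})

test_that("phase-singularity detection matches the loop-sum oracle", {
  # uniform field: nothing detected
  expect_equal(nrow(detect_ps(matrix(0.3, 10, 10))), 0)
  # single planted defect: one PS at the core with charge +1
  n <- 21
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  ph1 <- wrap_to_pi(atan2(rr - 10.5, cc - 10.5))
  ps1 <- detect_ps(ph1)
  expect_equal(nrow(ps1), 1)
  expect_equal(ps1$charge, 1L)
  expect_lt(abs(ps1$row - 10.5) + abs(ps1$col - 10.5), 1.1)
  # defect plus mirror: charges +1 and -1, total zero
  ph2 <- wrap_to_pi(atan2(rr - 10.5, cc - 5.5) - atan2(rr - 10.5, cc - 15.5))
  ps2 <- detect_ps(ph2)
  expect_equal(nrow(ps2), 2)
  expect_equal(sort(ps2$charge), c(-1L, 1L))
  # random smooth fields with planted defects, against the oracle
  for (s in 1:12) {
    nd <- s %% 4
    fld <- planted_phase_field(24, nd, seed = 200 + s)
    got <- detect_ps(fld$phase)
    ref <- detect_ps_oracle(fld$phase)
    expect_equal(got[order(got$row, got$col), , drop = FALSE],
                 ref[order(ref$row, ref$col), , drop = FALSE],
                 ignore_attr = TRUE)
    expect_equal(sum(got$charge), sum(fld$charges))
  }
})

test_that("rotor planning places lesions at singularity cores", {
  # synthetic rotating wave around a known core
  n <- 40; nt <- 80
  ts <- seq(0, 316, length.out = nt)
  rr <- row(matrix(0, n, n)); cc <- col(matrix(0, n, n))
  theta <- atan2(rr - 20.5, cc - 20.5)
  arr <- array(0, dim = c(n, n, nt))
  for (k in seq_len(nt)) arr[, , k] <- 0.5 + 0.4 * cos(theta - 2 * pi * ts[k] / 79)
  disk <- structure(list(
    geometry = list(grid_shape = c(n, n), pixel_spacing = 0.3,
                    disk_mask = matrix(TRUE, n, n), pv_list = list()),
    label_grid = matrix(1L, n, n)), class = "tissue_disk")
  baseline <- list(snapshots = arr, snap_times = ts)
  les <- plan_rotor(baseline, disk, lesion_radius = 4, mapping_window = 300)
  expect_gt(sum(les$mask), 0)
  ctr <- colMeans(which(les$mask, arr.ind = TRUE))
  expect_lt(sqrt(sum((ctr - c(20.5, 20.5))^2)), 4)
  # quiescent baseline: empty mask with a warning
  arr0 <- array(0.2, dim = c(n, n, nt))
  expect_warning(
    les0 <- plan_rotor(list(snapshots = arr0, snap_times = ts), disk,
                       mapping_window = 300),
    "no phase singularity")
  expect_equal(sum(les0$mask), 0)
  # two far-separated rotors give two lesion sites
  arr2 <- array(0, dim = c(n, n, nt))
  th_l <- atan2(rr - 10.5, cc - 10.5); th_r <- atan2(rr - 30.5, cc - 30.5)
  half <- (rr + cc) <= (n + 1)
  for (k in seq_len(nt)) {
    ang <- 2 * pi * ts[k] / 79
    frame <- 0.5 + 0.4 * cos(th_r - ang)
    frame[half] <- (0.5 + 0.4 * cos(th_l - ang))[half]
    arr2[, , k] <- frame
  }
  les2 <- plan_rotor(list(snapshots = arr2, snap_times = ts), disk,
                     lesion_radius = 4, mapping_window = 300)
  comp <- EBImage::bwlabel(les2$mask)
  expect_gte(max(comp), 2)
})

test_that("the success rule combines termination and ablation burden", {
  expect_true(success_rule(TRUE, 1500, 0.30))
  expect_false(success_rule(TRUE, 1500, 0.45))
  expect_false(success_rule(FALSE, NA, 0.10))
  # independent re-derivation across a random outcome sweep
  withr::with_seed(15, {
    for (k in 1:50) {
      term <- runif(1) < 0.5
      tt <- if (term) runif(1, 0, 2500) else NA_real_
      fr <- runif(1)
      expect_equal(success_rule(term, tt, fr),
                   isTRUE(term) && !is.na(tt) && tt <= 2000 && fr < 0.40)
    }
  })
})

test_that("strategy evaluation applies the rule to simulated outcomes", {
  disk <- small_disk()
  # ablating everything terminates the episode -> rule passes on time but
  # fails on burden (fraction 1)
  all_les <- structure(list(mask = tissue_mask(disk), strategy = "FIBRO",
                            ablated_fraction = 1), class = "lesion_mask")
  out <- evaluate_strategy(disk, all_les, t_end = 400, dt = 0.05,
                           lesion_time = 100)
  expect_true(out$terminated)
  expect_false(out$success)
  expect_equal(out$success,
               success_rule(out$terminated, out$termination_time,
                            out$ablated_fraction, t_end = 400))
})
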