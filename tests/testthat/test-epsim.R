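test_that("FK currents take the correct branches and match a scalar oracle", {
  p <- fk_params()
  # rest state: fast and outward currents vanish; Isi equals its closed form
  u <- matrix(0, 4, 4); v <- matrix(1, 4, 4); w <- matrix(1, 4, 4)
  cur <- fk_currents(u, v, w, p)
  expect_true(all(cur$Ifi == 0))
  expect_true(all(cur$Iso == 0))
  isi0 <- -(1 / (2 * p$tau_si)) * (1 + tanh(p$k_si * (0 - p$u_c_si)))
  expect_equal(cur$Isi[1, 1], isi0, tolerance = 1e-14)
  # just above threshold with the fast gate closed
  u2 <- matrix(p$u_c + 1e-3, 2, 2); v2 <- matrix(0, 2, 2)
  cur2 <- fk_currents(u2, v2, matrix(1, 2, 2), p)
  expect_true(all(cur2$Ifi == 0))
  expect_true(all(cur2$Iso == 1 / p$tau_r))
  # random grids against the scalar re-evaluation
  withr::with_seed(33, {
    u3 <- matrix(runif(100), 10); v3 <- matrix(runif(100), 10)
    w3 <- matrix(runif(100), 10)
  })
  cur3 <- fk_currents(u3, v3, w3, p)
  for (i in 1:10) for (j in 1:10) {
    ref <- fk_currents_scalar(u3[i, j], v3[i, j], w3[i, j], p)
    expect_equal(cur3$Ifi[i, j] + cur3$Iso[i, j] + cur3$Isi[i, j],
                 sum(ref), tolerance = 1e-13)
  }
})

test_that("vectorised step equals the scalar reference pixel-for-pixel", {
  p <- fk_params()
  n <- 20; dt <- 0.02; dx <- 0.3
  withr::with_seed(42, {
    u <- matrix(runif(n * n), n); v <- matrix(runif(n * n), n)
    w <- matrix(runif(n * n), n)
    D <- matrix(p$D_healthy, n, n)
    D[matrix(runif(n * n) < 0.3, n, n)] <- p$D_fibrotic
    active <- matrix(TRUE, n, n)
    active[matrix(runif(n * n) < 0.1, n, n)] <- FALSE
  })
  u[!active] <- 0; v[!active] <- 0; w[!active] <- 0; D[!active] <- 0
  got <- fk_step(u, v, w, D, active, p, dt, dx, n_steps = 1L)
  ref <- fk_step_scalar(u, v, w, D, active, p, dt, dx)
  expect_lt(max(abs(got$u - ref$u)), 1e-12)
  expect_lt(max(abs(got$v - ref$v)), 1e-12)
  expect_lt(max(abs(got$w - ref$w)), 1e-12)
})

test_that("rest state is a fixed point and D = 0 decouples pixels", {
  p <- fk_params()
  n <- 16
  u <- matrix(0, n, n); v <- matrix(1, n, n); w <- matrix(1, n, n)
  D <- matrix(p$D_healthy, n, n); act <- matrix(TRUE, n, n)
  out <- fk_step(u, v, w, D, act, p, dt = 0.05, dx = 0.3, n_steps = 1000L)
  # the only drift is the saturated tanh tail of Isi (~1e-8 over 50 ms)
  expect_lt(max(abs(out$u)), 1e-6)
  expect_lt(max(abs(out$v - 1)), 1e-6)
  # zero diffusivity: a single excited pixel never propagates
  u2 <- u; u2[8, 8] <- 1
  out2 <- fk_step(u2, v, w, matrix(0, n, n), act, p, dt = 0.05, dx = 0.3,
                  n_steps = 400L)
  expect_equal(out2$u[-8, ], u[-8, ])
  expect_equal(out2$u[8, -8], u[8, -8])
})

test_that("the discrete Laplacian is exact on a quadratic surface", {
  p <- fk_params()
  n <- 20; dx <- 0.3; dt <- 0.01
  ctr <- (n + 1) / 2
  x <- (col(matrix(0, n, n)) - ctr) * dx
  y <- (row(matrix(0, n, n)) - ctr) * dx
  u <- (x^2 + y^2) / 100  # keep u below threshold branches
  v <- matrix(1, n, n); w <- matrix(1, n, n)
  D <- matrix(p$D_healthy, n, n); act <- matrix(TRUE, n, n)
  stepped <- fk_step(u, v, w, D, act, p, dt, dx, 1L)
  nodiff <- fk_step(u, v, w, matrix(0, n, n), act, p, dt, dx, 1L)
  lap <- (stepped$u - nodiff$u) / dt   # = D * discrete Laplacian
  interior <- 2:(n - 1)
  expect_equal(lap[interior, interior],
               matrix(p$D_healthy * 4 / 100, n - 2, n - 2),
               tolerance = 1e-10)
})

test_that("zero-flux boundaries conserve u up to reaction terms", {
  p <- fk_params()
  n <- 24
  withr::with_seed(8, u <- matrix(runif(n * n, 0, 0.1), n))
  v <- matrix(1, n, n); w <- matrix(1, n, n)
  D <- matrix(p$D_healthy, n, n); act <- matrix(TRUE, n, n)
  stepped <- fk_step(u, v, w, D, act, p, 0.02, 0.3, 1L)
  reaction <- fk_step(u, v, w, matrix(0, n, n), act, p, 0.02, 0.3, 1L)
  # diffusion redistributes but does not create or destroy u
  expect_equal(sum(stepped$u), sum(reaction$u), tolerance = 1e-10)
})

test_that("gates stay in [0,1] during tissue runs", {
  cfg <- cohort_config(size = 64)
  co <- generate_cohort(3, 0, seed = 77, config = cfg)
  for (d in co$disks) {
    res <- run_crossfield(d, t_end = 100, dt = 0.05, record = c(-1, -1),
                          stop_on_termination = FALSE)
    expect_true(all(res$v >= 0 & res$v <= 1))
    expect_true(all(res$w >= 0 & res$w <= 1))
    expect_true(all(is.finite(res$u)))
  }
})

test_that("simulation runs are deterministic", {
  disk <- small_disk()
  r1 <- run_crossfield(disk, t_end = 120, dt = 0.05, record = c(0, 120),
                       record_stride = 10, stop_on_termination = FALSE)
  r2 <- run_crossfield(disk, t_end = 120, dt = 0.05, record = c(0, 120),
                       record_stride = 10, stop_on_termination = FALSE)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$trace_umax, r2$trace_umax)
})

test_that("stability bounds are enforced at configuration time", {
  p <- fk_params()
  expect_error(check_stability(p, dt = 0.5, dx = 0.3), "stability")
  expect_error(run_crossfield(small_disk(), dt = 0.5), "stability")
  expect_silent(check_stability(p, dt = 0.05, dx = 0.3))
})

test_that("termination detection follows the quiescence-window rule", {
  # constructed trace: activity to 700 ms, then silence; window 50 ms
  times <- seq(0, 1000, by = 1)
  umax <- ifelse(times <= 700, 0.9, 0.01)
  out <- is_af_terminated(times, umax, u_act = 0.1, quiescence_window = 50)
  expect_true(out$terminated)
  expect_equal(out$termination_time, 700)
  # all-quiescent run terminates at the start
  out2 <- is_af_terminated(times, rep(0, length(times)))
  expect_true(out2$terminated)
  expect_equal(out2$termination_time, 0)
  # activity throughout: not terminated
  out3 <- is_af_terminated(times, rep(0.5, length(times)))
  expect_false(out3$terminated)
  expect_true(is.na(out3$termination_time))
})

test_that("full-tissue ablation terminates an episode shortly after lesioning", {
  disk <- small_disk()
  les <- tissue_mask(disk)
  res <- run_crossfield(disk, lesions = les, lesion_time = 100,
                        t_end = 600, dt = 0.05)
  expect_true(res$terminated)
  expect_lte(res$termination_time, 110)
})

test_that("conduction velocity scales as sqrt(D)", {
  p <- fk_params()
  # fine strip: the fibrotic wavefront is under-resolved at 0.3 mm
  Ds <- c(0.015, 0.04, 0.07, 0.1)
  cvs <- vapply(Ds, function(D)
    measure_cv(p, D = D, dt = 0.01, pixel_spacing = 0.1), 0)
  expect_gt(cvs[4], 0.3)   # physiological healthy CV
  expect_lt(cvs[4], 1.0)
  fit <- lm(I(cvs^2) ~ Ds)
  expect_gt(summary(fit)$r.squared, 0.99)
  # factor form of the scaling law
  expect_equal(cvs[3] / cvs[2], sqrt(0.07 / 0.04), tolerance = 0.1)
})
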