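# shared fixtures, all generated in code

# small disk with a known fibrosis pattern
small_disk <- function(size = 64, pv_variant = 1, threshold = 0.6,
                       seed = 7, correlation_length = 3) {
  geo <- make_disk_geometry(size, pv_variant)
  f <- sample_base_fibrosis(geo, correlation_length, seed)
  threshold_fibrosis(f, geo, threshold)
}

# constant-intensity fibrosis field on a geometry
const_field <- function(geometry, value) {
  m <- matrix(0, geometry$grid_shape[1], geometry$grid_shape[2])
  m[geometry$disk_mask] <- value
  structure(list(intensity = m, correlation_length = 3, seed = 0,
                 geometry = geometry), class = "fibrosis_field")
}

# scalar (non-vectorised) reference for the FK currents at one pixel
fk_currents_scalar <- function(u, v, w, p) {
  Ifi <- if (u >= p$u_c) -(v / p$tau_d) * (1 - u) * (u - p$u_c) else 0
  Iso <- if (u >= p$u_c) 1 / p$tau_r else u / p$tau_o
  Isi <- -(w / (2 * p$tau_si)) * (1 + tanh(p$k_si * (u - p$u_c_si)))
  c(Ifi = Ifi, Iso = Iso, Isi = Isi)
}

# scalar reference for one forward-Euler FK step on a full grid
fk_step_scalar <- function(u, v, w, D, active, p, dt, dx) {
  H <- nrow(u); W <- ncol(u)
  un <- u; vn <- v; wn <- w
  gface <- function(a, b) if (a > 0 && b > 0) 2 * a * b / (a + b) else 0
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (!active[i, j]) next
    lap <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- i + d[1]; nj <- j + d[2]
      if (ni >= 1 && ni <= H && nj >= 1 && nj <= W && active[ni, nj]) {
        g <- gface(D[i, j], D[ni, nj])
        lap <- lap + g * (u[ni, nj] - u[i, j])
      }
    }
    lap <- lap / dx^2
    cur <- fk_currents_scalar(u[i, j], v[i, j], w[i, j], p)
    un[i, j] <- u[i, j] + dt * (lap - sum(cur))
    if (u[i, j] >= p$u_c) {
      vn[i, j] <- v[i, j] + dt * (-v[i, j] / p$tau_v_plus)
      wn[i, j] <- w[i, j] + dt * (-w[i, j] / p$tau_w_plus)
    } else {
      tvm <- if (u[i, j] >= p$u_v) p$tau_v1_minus else p$tau_v2_minus
      vn[i, j] <- v[i, j] + dt * ((1 - v[i, j]) / tvm)
      wn[i, j] <- w[i, j] + dt * ((1 - w[i, j]) / p$tau_w_minus)
    }
    vn[i, j] <- min(1, max(0, vn[i, j]))
    wn[i, j] <- min(1, max(0, wn[i, j]))
  }
  list(u = un, v = vn, w = wn)
}

# brute-force wrapped-loop-sum phase-singularity oracle
detect_ps_oracle <- function(phase) {
  wrap <- function(a) {
    out <- (a + pi) %% (2 * pi) - pi
    if (length(out) && !is.na(out) && out == -pi) out <- pi
    out
  }
  res <- NULL
  for (i in seq_len(nrow(phase) - 1)) for (j in seq_len(ncol(phase) - 1)) {
    p <- c(phase[i, j], phase[i, j + 1], phase[i + 1, j + 1], phase[i + 1, j])
    if (anyNA(p)) next
    s <- wrap(p[2] - p[1]) + wrap(p[3] - p[2]) + wrap(p[4] - p[3]) +
      wrap(p[1] - p[4])
    if (abs(s) > pi)
      res <- rbind(res, data.frame(row = i + 0.5, col = j + 0.5,
                                   charge = as.integer(sign(s))))
  }
  if (is.null(res))
    data.frame(row = numeric(0), col = numeric(0), charge = integer(0))
  else res
}

# smooth random phase field with planted topological defects
planted_phase_field <- function(n = 24, n_defects = 1, seed = 1) {
  withr::with_seed(seed, {
    base <- matrix(0, n, n)
    rr <- row(base); cc <- col(base)
    # smooth background: low-order harmonics, no winding
    for (k in 1:3)
      base <- base + runif(1, -0.5, 0.5) *
        sin(2 * pi * (runif(1) * rr + runif(1) * cc) / n + runif(1, 0, 2 * pi))
    charges <- integer(0)
    if (n_defects > 0) {
      for (d in seq_len(n_defects)) {
        q <- sample(c(-1L, 1L), 1)
        # keep cores off plaquette corners and away from the border
        y0 <- runif(1, 4, n - 4) + 0.5; x0 <- runif(1, 4, n - 4) + 0.5
        base <- base + q * atan2(rr - y0, cc - x0)
        charges <- c(charges, q)
      }
    }
    list(phase = wrap_to_pi(base), charges = charges)
  })
}

wrap_to_pi <- function(a) {
  out <- (a + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

# separable toy cohort for CNN sanity tests: label = high fibrosis density
toy_images <- function(n, size = 16, seed = 1) {
  withr::with_seed(seed, {
    X <- array(0, dim = c(size, size, n))
    y <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      dens <- runif(1, 0.05, 0.95)
      img <- matrix(0.5, size, size)
      img[matrix(runif(size^2) < dens, size, size)] <- 1
      X[, , i] <- img
      y[i, ] <- rep(as.integer(dens > 0.5), 3)
    }
    list(images = X, labels = y)
  })
}

tiny_spec <- function(size = 16)
  model_spec(input_size = size, n_conv = 2, filters = 4,
             linear_widths = c(16, 3), dropout = 0.2)

unwrap_phase <- function(p) cumsum(c(p[1], wrap_to_pi(diff(p))))

# hand-built single-conv linear model used for the analytic GradCAM case
handbuilt_cnn <- function() {
  spec <- model_spec(input_size = 8, n_conv = 1, filters = 2,
                     linear_widths = c(3), dropout = 0)
  # centre-tap conv kernels: filter 1 = identity, filter 2 = 2x identity
  convW <- matrix(0, 2, 9); convW[1, 5] <- 1; convW[2, 5] <- 2
  flat <- 4 * 4 * 2
  fcW <- matrix(0, 3, flat)
  withr::with_seed(31, fcW[2, ] <- round(runif(flat, -1, 1), 2))
  weights <- list(convW = list(convW), convb = list(rep(0, 2)),
                  fcW = list(fcW), fcb = list(rep(0, 3)))
  structure(list(weights = weights, spec = spec,
                 config = train_config(epochs = 1, seed = 1)),
            class = "af_cnn")
}
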