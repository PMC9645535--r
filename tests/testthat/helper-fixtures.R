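# Shared fixtures (memoised, built in code) and independent brute-force
# oracles used to cross-check the package's implementations.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) assign(name, expr, envir = .fixtures)
  get(name, envir = .fixtures)
}

# straight z-axis tube, radius 10 mm, wall 2 mm, no thrombus, 1 mm voxels
tube_phantom <- function() memo("tube", {
  spec <- phantom_spec(grid_shape = c(48, 48, 60), spacing = c(1, 1, 1),
                       centerline_control_points =
                         cbind(24, 24, seq(0, 60, length.out = 4)),
                       lumen_radius_profile = cbind(c(0, 1), c(10, 10)),
                       wall_thickness = 2, thrombus_fraction = 0, seed = 7)
  list(spec = spec, case = generate_phantom(spec))
})

# curved tube with an aneurysmal bulge and a thrombus crescent
bulge_phantom <- function() memo("bulge", {
  spec <- phantom_spec(grid_shape = c(64, 64, 80), spacing = c(1, 1, 1),
                       centerline_control_points =
                         cbind(32 + 4 * sin(seq(0, pi, length.out = 5)), 32,
                               seq(0, 80, length.out = 5)),
                       lumen_radius_profile =
                         cbind(c(0, 0.3, 0.5, 0.7, 1), c(9, 9, 20, 9, 9)),
                       wall_thickness = 2, thrombus_fraction = 0.5, seed = 3)
  list(spec = spec, case = generate_phantom(spec))
})

# small phantom for warp tests
small_phantom <- function() memo("small", {
  spec <- phantom_spec(grid_shape = c(32, 32, 40), spacing = c(1.5, 1.5, 1.5),
                       centerline_control_points =
                         cbind(24, 24, seq(0, 60, length.out = 4)),
                       lumen_radius_profile = cbind(c(0, 1), c(8, 8)),
                       wall_thickness = 2, thrombus_fraction = 0, seed = 2)
  list(spec = spec, case = generate_phantom(spec))
})

# ---------------------------------------------------------------------------
# brute-force oracles (kept deliberately naive and independent)

bf_dice <- function(a, b, cls) {
  av <- as.vector(a); bv <- as.vector(b)
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_along(av)) {
    ia <- av[i] == cls; ib <- bv[i] == cls
    if (ia) na <- na + 1
    if (ib) nb <- nb + 1
    if (ia && ib) inter <- inter + 1
  }
  if (na + nb == 0) return(1)
  2 * inter / (na + nb)
}

bf_closest_stats <- function(A, B) {
  # directed means and maxima of closest-point distances, via all pairs
  d12 <- numeric(nrow(A)); d21 <- numeric(nrow(B))
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    d12[i] <- best
  }
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    d21[j] <- best
  }
  list(mean_sym = (mean(d12) + mean(d21)) / 2,
       hausdorff = max(max(d12), max(d21)))
}

bf_interp <- function(x, y, x0) {
  # linear interpolation without approx()
  if (x0 <= x[1]) return(y[1])
  if (x0 >= x[length(x)]) return(y[length(y)])
  j <- max(which(x <= x0))
  if (x[j] == x0) return(y[j])
  y[j] + (y[j + 1] - y[j]) * (x0 - x[j]) / (x[j + 1] - x[j])
}

bf_profile_rmse <- function(p1, p2) {
  lo <- max(min(p1$arc_length_mm), min(p2$arc_length_mm))
  hi <- min(max(p1$arc_length_mm), max(p2$arc_length_mm))
  s <- seq(lo, hi, by = min(diff(p1$arc_length_mm)[1], diff(p2$arc_length_mm)[1]))
  se <- 0
  for (q in s) {
    d1 <- bf_interp(p1$arc_length_mm, p1$diameter_mm, q)
    d2 <- bf_interp(p2$arc_length_mm, p2$diameter_mm, q)
    se <- se + (d1 - d2)^2
  }
  sqrt(se / length(s))
}

bf_resample_nearest <- function(v, dims_out, spacing_out, origin_out) {
  out <- array(0, dims_out)
  d <- dim(v$data)
  for (k in seq_len(dims_out[3])) for (j in seq_len(dims_out[2]))
    for (i in seq_len(dims_out[1])) {
      w <- origin_out + (c(i, j, k) - 1) * spacing_out
      f <- round((w - v$origin) / v$spacing) + 1
      if (all(f >= 1) && all(f <= d)) out[i, j, k] <- v$data[f[1], f[2], f[3]]
    }
  out
}

bf_divergence_warp <- function(v, centers_vox, mags, sigmas, nearest) {
  d <- dim(v$data)
  cw <- sweep(matrix(centers_vox, ncol = 3), 2, v$spacing, `*`)
  cw <- sweep(cw, 2, v$origin, `+`)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    w <- v$origin + (c(i, j, k) - 1) * v$spacing
    u <- c(0, 0, 0)
    for (q in seq_len(nrow(cw))) {
      dv <- w - cw[q, ]
      r <- sqrt(sum(dv^2))
      if (r > 1e-9)
        u <- u + mags[q] * dv / r * exp(-r^2 / (2 * sigmas[q]^2))
    }
    f <- (w - u - v$origin) / v$spacing + 1
    if (nearest) {
      f <- round(f)
      if (all(f >= 1) && all(f <= d)) out[i, j, k] <- v$data[f[1], f[2], f[3]]
    } else {
      f0 <- floor(f); t <- f - f0
      acc <- 0
      for (dk in 0:1) for (dj in 0:1) for (di in 0:1) {
        g <- pmin(pmax(f0 + c(di, dj, dk), 1), d)
        if (all(f >= 0.5) && all(f <= d + 0.5))
          acc <- acc + v$data[g[1], g[2], g[3]] *
            (if (di) t[1] else 1 - t[1]) * (if (dj) t[2] else 1 - t[2]) *
            (if (dk) t[3] else 1 - t[3])
      }
      out[i, j, k] <- acc
    }
  }
  out
}

# random blob mask for oracle-equivalence checks
random_blob <- function(dims, n_seeds = 3, r_max = 5) {
  a <- array(0L, dims)
  for (q in seq_len(n_seeds)) {
    c0 <- sapply(dims, function(n) runif(1, 1, n))
    r <- runif(1, 1, r_max)
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
      for (i in seq_len(dims[1]))
        if (sum((c(i, j, k) - c0)^2) <= r^2) a[i, j, k] <- 1L
  }
  a
}
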