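# Shared builders for small test fields and independent brute-force oracles.

# Solid-body rotation u = (-Omega*y, Omega*x, 0) about the grid center on a
# cubic grid; spacing in mm, velocities in m/s.
rotation_field <- function(n = 16L, omega = 3, spacing = c(0.5, 0.5, 0.5)) {
  ax <- lapply(1:3, function(k) (0:(n - 1L)) * spacing[k] / 1000)  # m
  ctr <- vapply(ax, mean, numeric(1))
  vx <- array(0, c(n, n, n, 1L)); vy <- vx; vz <- vx
  for (j in seq_len(n)) vx[, j, , 1L] <- -omega * (ax[[2]][j] - ctr[2])
  for (i in seq_len(n)) vy[i, , , 1L] <- omega * (ax[[1]][i] - ctr[1])
  velocity_field(vx, vy, vz, spacing, times = 0.1, period = 1)
}

full_sac_geom <- function(n = 16L, spacing = c(0.5, 0.5, 0.5)) {
  segmented_geometry(array(LABELS[["sac"]], c(n, n, n)), spacing)
}

# Smooth pseudo-random field: sum of a few sinusoids, deterministic.
smooth_random_field <- function(n = 16L, spacing = c(0.5, 0.5, 0.5), seed = 42L) {
  set.seed(seed)
  ax <- (0:(n - 1L)) / n
  comp <- function() {
    a <- array(0, c(n, n, n))
    for (k in 1:3) {
      kv <- sample(1:3, 3, replace = TRUE)
      ph <- runif(3, 0, 2 * pi)
      amp <- runif(1, 0.01, 0.1)
      for (i in seq_len(n)) for (j in seq_len(n))
        a[i, j, ] <- a[i, j, ] + amp * sin(2 * pi * (kv[1] * ax[i] + kv[2] * ax[j] + kv[3] * ax) + ph[1])
    }
    a
  }
  vx <- comp(); vy <- comp(); vz <- comp()
  dim(vx) <- c(n, n, n, 1L); dim(vy) <- c(n, n, n, 1L); dim(vz) <- c(n, n, n, 1L)
  velocity_field(vx, vy, vz, spacing, times = 0.1, period = 1)
}

# Brute-force curl oracle: per-voxel loops over the same stencil rules
# (central where both neighbours fluid, one-sided otherwise).
curl_oracle <- function(field, mask) {
  v <- frame_velocity(field, 1L)
  h <- field$spacing / 1000
  dm <- dim(mask)
  d1 <- function(a, i, j, k, ax) {
    p <- c(i, j, k); p[ax] <- p[ax] + 1L
    m <- c(i, j, k); m[ax] <- m[ax] - 1L
    hp <- p[ax] <= dm[ax] && mask[p[1], p[2], p[3]]
    hm <- m[ax] >= 1L && mask[m[1], m[2], m[3]]
    if (hp && hm) (a[p[1], p[2], p[3]] - a[m[1], m[2], m[3]]) / (2 * h[ax])
    else if (hp) (a[p[1], p[2], p[3]] - a[i, j, k]) / h[ax]
    else if (hm) (a[i, j, k] - a[m[1], m[2], m[3]]) / h[ax]
    else NA_real_
  }
  wx <- array(NA_real_, dm); wy <- wx; wz <- wx
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (!mask[i, j, k]) next
    wx[i, j, k] <- d1(v$vz, i, j, k, 2L) - d1(v$vy, i, j, k, 3L)
    wy[i, j, k] <- d1(v$vx, i, j, k, 3L) - d1(v$vz, i, j, k, 1L)
    wz[i, j, k] <- d1(v$vy, i, j, k, 1L) - d1(v$vx, i, j, k, 2L)
  }
  list(wx = wx, wy = wy, wz = wz)
}

# UV-sphere triangle mesh used as an STL fixture generator.
sphere_mesh <- function(radius = 5, n_lat = 40L, n_lon = 64L) {
  lat <- seq(-pi / 2, pi / 2, length.out = n_lat + 1L)
  lon <- seq(0, 2 * pi, length.out = n_lon + 1L)[-(n_lon + 1L)]
  verts <- rbind(c(0, 0, -radius))
  for (i in 2:n_lat)
    verts <- rbind(verts, cbind(radius * cos(lat[i]) * cos(lon),
                                radius * cos(lat[i]) * sin(lon),
                                radius * sin(lat[i])))
  verts <- rbind(verts, c(0, 0, radius))
  ring <- function(i) 1L + (i - 2L) * n_lon + seq_len(n_lon)  # i in 2..n_lat
  faces <- list()
  r1 <- ring(2L)
  faces[[1]] <- cbind(1L, r1, r1[c(2:n_lon, 1L)])
  for (i in 2:(n_lat - 1L)) {
    a <- ring(i); b <- ring(i + 1L); an <- a[c(2:n_lon, 1L)]; bn <- b[c(2:n_lon, 1L)]
    faces[[length(faces) + 1L]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  top <- nrow(verts)
  rl <- ring(n_lat)
  faces[[length(faces) + 1L]] <- cbind(top, rl[c(2:n_lon, 1L)], rl)
  triangle_mesh(verts, do.call(rbind, faces))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
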