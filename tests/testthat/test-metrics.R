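# Scalar hemodynamic metrics and the pre/post comparison arithmetic.

make_uniform_field <- function(n, speed, spacing = c(0.5, 0.5, 0.5), frames = 1L) {
  vx <- array(speed, c(n, n, n, frames))
  z <- array(0, c(n, n, n, frames))
  tt <- (seq_len(frames) - 0.5) / frames
  velocity_field(vx, z, z, spacing, times = tt, period = 1)
}

test_that("systolic peak frame maximizes fluid mean speed with earliest-frame ties", {
  n <- 8L
  g <- full_sac_geom(n)
  f1 <- make_uniform_field(n, 0.1)
  expect_identical(systolic_peak_frame(f1, g), 1L)
  # pulsatile: argmax recorded by the generator itself
  sp <- make_sac_phantom(phantom_spec(n_frames = 8L))
  expect_identical(systolic_peak_frame(sp$field, sp$geom), sp$truth$peak_frame)
  fconst <- make_uniform_field(n, 0.1, frames = 5L)
  expect_identical(systolic_peak_frame(fconst, g), 1L)
})

test_that("average sac velocity is the sac-only mean speed", {
  n <- 8L
  lab <- array(LABELS[["outside"]], c(n, n, n))
  lab[1:4, , ] <- LABELS[["sac"]]
  lab[5:8, , ] <- LABELS[["parent_artery"]]
  g <- segmented_geometry(lab, c(0.5, 0.5, 0.5))
  vx <- array(0, c(n, n, n, 1L))
  vx[1:2, , , 1L] <- 0.2            # half the sac at 0.2, half at 0
  vx[5:8, , , 1L] <- 0.9            # parent artery must not contribute
  z <- array(0, c(n, n, n, 1L))
  f <- velocity_field(vx, z, z, c(0.5, 0.5, 0.5), times = 0.1, period = 1)
  expect_equal(average_sac_velocity(f, g, 1L), 0.1)
  # explicit per-voxel loop oracle on a phantom
  sp <- make_sac_phantom(phantom_spec(n_frames = 4L))
  pk <- sp$truth$peak_frame
  mag <- velocity_magnitude(sp$field, pk)
  acc <- 0; cnt <- 0
  idx <- which(sac_mask(sp$geom), arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    acc <- acc + mag[idx[r, 1], idx[r, 2], idx[r, 3]]; cnt <- cnt + 1
  }
  expect_rel_equal(average_sac_velocity(sp$field, sp$geom, pk), acc / cnt, 1e-12)
  g_empty <- segmented_geometry(array(LABELS[["parent_artery"]], c(4, 4, 4)), c(1, 1, 1))
  f4 <- make_uniform_field(4L, 0.1, c(1, 1, 1))
  expect_error(average_sac_velocity(f4, g_empty, 1L), "sac mask is empty")
})

test_that("kinetic energy is the sum of squared sac speeds", {
  n <- 5L  # 125 voxels; restrict sac to 100
  lab <- array(LABELS[["outside"]], c(n, n, n))
  lab[1:4, , ] <- LABELS[["sac"]]
  g <- segmented_geometry(lab, c(0.5, 0.5, 0.5))
  f <- make_uniform_field(n, 0.2)
  expect_equal(kinetic_energy(f, g, 1L), 100 * 0.04)
  f0 <- make_uniform_field(n, 0)
  expect_equal(kinetic_energy(f0, g, 1L), 0)
  fr <- smooth_random_field(10L)
  gs <- full_sac_geom(10L)
  mag <- velocity_magnitude(fr, 1L)
  expect_equal(kinetic_energy(fr, gs, 1L), sum(mag^2))
})

test_that("kinetic energy is invariant under rigid rotation of all velocity vectors", {
  f <- smooth_random_field(10L)
  g <- full_sac_geom(10L)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  fr <- f
  fr$vx <- rot[1, 1] * f$vx + rot[1, 2] * f$vy + rot[1, 3] * f$vz
  fr$vy <- rot[2, 1] * f$vx + rot[2, 2] * f$vy + rot[2, 3] * f$vz
  fr$vz <- rot[3, 1] * f$vx + rot[3, 2] * f$vy + rot[3, 3] * f$vz
  expect_equal(kinetic_energy(fr, g, 1L), kinetic_energy(f, g, 1L), tolerance = 1e-12)
})

test_that("cycle-mean kinetic energy removes a pure sinusoidal modulation", {
  n <- 6L; nt <- 64L
  tt <- (seq_len(nt) - 0.5) / nt
  vx <- array(0, c(n, n, n, nt)); z <- array(0, c(n, n, n, nt))
  E0_speed <- 0.1
  for (fr in seq_len(nt)) vx[, , , fr] <- E0_speed * sqrt(1 + sin(2 * pi * tt[fr]))
  f <- velocity_field(vx, z, z, c(1, 1, 1), times = tt, period = 1)
  g <- full_sac_geom(n, c(1, 1, 1))
  E0 <- n^3 * E0_speed^2
  res <- mean_kinetic_energy(f, g)
  expect_equal(res$E_mean, E0, tolerance = 1e-3)
  # time-constant field: mean equals the single-frame value
  fc <- make_uniform_field(n, 0.2, c(1, 1, 1), frames = 7L)
  gc <- full_sac_geom(n, c(1, 1, 1))
  expect_equal(mean_kinetic_energy(fc, gc)$E_mean, kinetic_energy(fc, gc, 1L))
})

test_that("recirculation of solid-body rotation is 2 Omega A and flips with the normal", {
  f <- rotation_field(n = 24L, omega = 2)
  g <- full_sac_geom(24L)
  ctr <- (24 - 1) / 2 * 0.5
  A <- 50
  pl <- cross_section_plane(c(ctr, ctr, ctr), c(0, 0, 1), radius = sqrt(A / pi))
  R <- recirculation(f, g, pl, 1L)
  expect_rel_equal(R, 2 * 2 * A, 0.02)
  pl_flip <- cross_section_plane(c(ctr, ctr, ctr), c(0, 0, -1), radius = sqrt(A / pi))
  expect_equal(recirculation(f, g, pl_flip, 1L), -R, tolerance = 1e-10)
  # irrotational uniform flow
  fu <- make_uniform_field(24L, 0.3)
  expect_equal(recirculation(fu, g, pl, 1L), 0)
})

test_that("recirculation converges against a fine-resolution quadrature oracle", {
  sp <- make_sac_phantom(phantom_spec(n_frames = 4L))
  pk <- sp$truth$peak_frame
  coarse <- recirculation(sp$field, sp$geom, sp$truth$plane, pk, resolution = 0.25)
  fine <- recirculation(sp$field, sp$geom, sp$truth$plane, pk, resolution = 0.0625)
  expect_rel_equal(coarse, fine, 0.01)
})

test_that("mean recirculation averages |R| over the cycle", {
  tt <- (seq_len(8L) - 0.5) / 8
  expect_equal(time_integrate(abs(rep(-40, 8L)), tt, 1), 40)
  tt64 <- (seq_len(64L) - 0.5) / 64
  R0 <- 123.4
  expect_equal(time_integrate(abs(R0 * sin(2 * pi * tt64)), tt64, 1),
               (2 / pi) * R0, tolerance = 1e-3 * R0)
  # on a field: R_m is invariant to flipping the plane normal
  sp <- make_sac_phantom(phantom_spec(n_frames = 4L))
  plf <- cross_section_plane(sp$truth$plane$origin, -sp$truth$plane$normal,
                             radius = sp$truth$plane$radius)
  m1 <- mean_recirculation(sp$field, sp$geom, sp$truth$plane)
  m2 <- mean_recirculation(sp$field, sp$geom, plf)
  expect_equal(m1$R_mean, m2$R_mean, tolerance = 1e-10)
  expect_equal(m1$R_per_frame, -m2$R_per_frame, tolerance = 1e-10)
})

test_that("Poiseuille wall shear stress recovers eta 2 u_max / a on the lateral wall", {
  spec <- phantom_spec(n_frames = 1L, pulsatility = 0, mean_velocity = 0.1)
  props <- fluid_properties()   # eta = 4.1 mPa s
  tp <- make_tube_phantom(spec, props)
  # u_max = 2 * 0.1 = 0.2 m/s, a = 2 mm -> 0.82 Pa
  expect_equal(tp$truth$WSS_peak, 0.82, tolerance = 1e-12)
  wss <- wall_shear_stress(tp$field, tp$geom, props, 1L)
  lat <- tp$geom$surface$kind == "lateral" & attr(wss, "valid")
  expect_rel_equal(mean(wss[lat]), 0.82, 0.05)
})

test_that("linear shear over a flat wall gives exactly eta gamma, independent of d", {
  n <- 16L; h <- c(0.5, 0.5, 0.5)
  gamma <- 10  # 1/s
  lab <- array(LABELS[["outside"]], c(n, n, n))
  lab[, , 5:16] <- LABELS[["sac"]]
  z0 <- (5 - 1) * h[3] - h[3] / 2  # wall plane: lower face of voxel layer 5
  zco <- ((1:n) - 1) * h[3]
  vx <- array(0, c(n, n, n, 1L))
  for (k in 5:16) vx[, , k, 1L] <- gamma * (zco[k] - z0) / 1000
  zarr <- array(0, c(n, n, n, 1L))
  f <- velocity_field(vx, zarr, zarr, h, times = 0.1, period = 1)
  surf <- mask_surface(lab == LABELS[["sac"]], h)
  fg <- mesh_face_geometry(surf)
  bottom <- abs(fg$normals[, 3] + 1) < 1e-9 & abs(fg$centroids[, 3] - z0) < 1e-9
  # keep only interior bottom faces so samples stay inside the slab
  interior <- fg$centroids[, 1] > 2 & fg$centroids[, 1] < 5.5 &
              fg$centroids[, 2] > 2 & fg$centroids[, 2] < 5.5
  g <- segmented_geometry(lab, h, surface = surf)
  props <- fluid_properties()
  for (d in c(0.6, 0.9)) {
    for (est in c("quadratic", "linear")) {
      wss <- wall_shear_stress(f, g, props, 1L, d = d, estimator = est)
      sel <- bottom & interior & attr(wss, "valid")
      expect_gt(sum(sel), 10)
      expect_equal(unname(unique(round(wss[sel], 12))), props$viscosity * gamma,
                   tolerance = 1e-9)
    }
  }
})

test_that("zero velocity field yields zero wall shear stress everywhere", {
  spec <- phantom_spec(n_frames = 1L, pulsatility = 0, mean_velocity = 0)
  tp <- make_tube_phantom(spec)
  wss <- wall_shear_stress(tp$field, tp$geom, fluid_properties(), 1L)
  expect_true(all(wss[attr(wss, "valid")] == 0))
})

test_that("nWSS normalizes to [0,1] with max exactly 1 and classifies by thresholds", {
  expect_equal(normalized_wss(c(1, 2, 4)), c(0.25, 0.5, 1.0))
  expect_equal(normalized_wss(rep(2.2, 5)), rep(1, 5))
  expect_warning(res <- normalized_wss(c(0, 0, 0)), "zero")
  expect_equal(res, c(0, 0, 0))
  sp <- make_sac_phantom(phantom_spec(n_frames = 2L))
  wss <- wall_shear_stress(sp$field, sp$geom, fluid_properties(), sp$truth$peak_frame)
  sac_el <- sac_adjacent_elements(sp$geom)
  nwss <- normalized_wss(wss, sac_el)
  expect_identical(max(nwss[sac_el], na.rm = TRUE), 1)
  cls <- classify_nwss(c(0.75, 0.25, 0.5, 0.74999, 0.26))
  expect_identical(as.character(cls), c("high", "low", "mid", "mid", "mid"))
})

test_that("relative reduction reproduces the published per-case arithmetic", {
  expect_equal(relative_reduction(0.089, 0.039), 56.17978, tolerance = 1e-5)
  expect_identical(round_half_away(relative_reduction(0.089, 0.039)), 56)
  expect_identical(round_half_away(relative_reduction(806, 395)), 51)
  expect_equal(relative_reduction(3.7, 3.7), 0)
  expect_error(relative_reduction(0, 1), "positive")
  expect_error(relative_reduction(-2, 1), "positive")
  # unit independence
  expect_equal(relative_reduction(0.089, 0.039), relative_reduction(89, 39))
})

test_that("pre/post comparison accepts metric triples and reproduces published rows", {
  b01 <- compare_pre_post(c(0.089, 806, 92), c(0.039, 395, 16.56), "B01", "CFD")
  expect_identical(unname(b01$delta_int), c(56, 51, 82))
  a01 <- compare_pre_post(c(0.443, 18.4, 81), c(0.076, 3.5, 10.53), "A01", "MRI")
  expect_identical(unname(a01$delta_int), c(83, 81, 87))
  same <- compare_pre_post(c(1, 2, 3), c(1, 2, 3))
  expect_identical(unname(same$delta_int), c(0, 0, 0))
  expect_error(compare_pre_post(c(1, 2), c(1, 2, 3)), "triple")
  expect_error(compare_pre_post(c(1, NA, 3), c(1, 2, 3)), "missing metric")
})

test_that("voxel-wise attenuation obeys the delta scaling laws", {
  sp <- make_sac_phantom(phantom_spec(n_frames = 6L))
  cfg <- run_config(plane = sp$truth$plane)
  pre_m <- case_metrics(sp$field, sp$geom, cfg)
  for (k in c(0.8, 0.5, 0.2)) {
    post <- apply_fd_attenuation(sp$field, sp$geom, k)
    rep_ <- compare_cases(pre_m, case_metrics(post, sp$geom, cfg), "phantom", "simulated")
    expect_equal(unname(rep_$delta_int[["delta_U"]]), round_half_away(100 * (1 - k)))
    expect_equal(unname(rep_$delta_int[["delta_E"]]), round_half_away(100 * (1 - k^2)))
    expect_equal(unname(rep_$delta_int[["delta_R"]]), unname(rep_$delta_int[["delta_U"]]))
  }
})
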