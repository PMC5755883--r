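# Analytic phantom generators and their closed-form ground truth.

test_that("tube phantom carries exact Poiseuille ground truth", {
  spec <- phantom_spec(n_frames = 1L, pulsatility = 0, mean_velocity = 0.1)
  tp <- make_tube_phantom(spec)
  expect_equal(tp$truth$WSS_peak, 0.82)  # eta 2 u_max / a with u_max = 0.2, a = 2 mm
  # centerline velocity equals u_max (nearest voxel center sits within half a
  # voxel of the axis, so the parabolic profile is a hair below its apex)
  expect_rel_equal(max(tp$field$vx), 2 * spec$mean_velocity, 0.03)
  expect_true(all(tp$field$vy == 0) && all(tp$field$vz == 0))
  expect_true(all(tp$geom$labels %in% LABELS[c("outside", "parent_artery")]))
})

test_that("tube phantom flux matches pi a^2 u_max / 2 within 3%", {
  spec <- phantom_spec(n_frames = 4L)
  tp <- make_tube_phantom(spec)
  pk <- tp$truth$peak_frame
  h <- tp$field$spacing / 1000
  lum <- fluid_mask(tp$geom)[25, , ]
  flux <- sum(tp$field$vx[25, , , pk][lum]) * h[2] * h[3]
  expect_rel_equal(flux, tp$truth$flow_rate[pk], 0.03)
})

test_that("sac vortex phantom recirculation recovers 2 Omega A within 3%", {
  sp <- make_sac_phantom(phantom_spec(n_frames = 4L))
  pk <- sp$truth$peak_frame
  R <- recirculation(sp$field, sp$geom, sp$truth$plane, pk)
  expect_rel_equal(R, sp$truth$R_per_frame[pk], 0.03)
  Rm <- mean_recirculation(sp$field, sp$geom, sp$truth$plane)$R_mean
  expect_rel_equal(Rm, sp$truth$R_mean, 0.03)
})

test_that("pipeline sac velocity matches ground truth within 1%", {
  sp <- make_sac_phantom(phantom_spec(n_frames = 4L))
  pk <- systolic_peak_frame(sp$field, sp$geom)
  expect_identical(pk, sp$truth$peak_frame)
  expect_rel_equal(average_sac_velocity(sp$field, sp$geom, pk), sp$truth$U_peak, 0.01)
})

test_that("recirculation error shrinks as the voxel grid refines", {
  errs <- vapply(c(1, 2), function(refine) {
    sp <- make_sac_phantom(phantom_spec(n_frames = 1L, pulsatility = 0,
                                        spacing = c(0.53, 0.53, 0.60) / refine))
    R <- recirculation(sp$field, sp$geom, sp$truth$plane, 1L)
    abs(R - sp$truth$R_per_frame[1L]) / abs(sp$truth$R_per_frame[1L])
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.005)
})

test_that("attenuated mode drops sac velocity by exactly k and removes the vortex", {
  k <- 0.37
  pre <- make_sac_phantom(phantom_spec(n_frames = 3L))
  post <- make_sac_phantom(phantom_spec(n_frames = 3L, sac_mode = "attenuated",
                                        attenuation = k))
  for (fr in 1:3) {
    expect_equal(average_sac_velocity(post$field, post$geom, fr),
                 k * average_sac_velocity(pre$field, pre$geom, fr), tolerance = 1e-12)
  }
  R_post <- recirculation(post$field, post$geom, pre$truth$plane, 1L)
  expect_equal(R_post, 0, tolerance = 1e-9)
  expect_true(all(post$truth$R_per_frame == 0))
})

test_that("voxel attenuation is identity at k = 1 and errors outside (0,1]", {
  sp <- make_sac_phantom(phantom_spec(n_frames = 2L))
  same <- apply_fd_attenuation(sp$field, sp$geom, 1)
  expect_identical(same$vx, sp$field$vx)
  expect_error(apply_fd_attenuation(sp$field, sp$geom, 0), "0, 1")
  expect_error(apply_fd_attenuation(sp$field, sp$geom, 1.2), "0, 1")
  sp2 <- apply_fd_attenuation(sp$field, sp$geom, 0.5)
  sm <- sac_mask(sp$geom)
  expect_equal(sp2$vx[, , , 1][sm], 0.5 * sp$field$vx[, , , 1][sm])
  expect_identical(sp2$vx[, , , 1][!sm], sp$field$vx[, , , 1][!sm])
})

test_that("a neck wider than the sac is rejected", {
  expect_error(make_sac_phantom(phantom_spec(neck_width = 9, sac_radius = 4)),
               "neck is wider")
})

test_that("identical spec and seed give bit-identical phantoms", {
  s1 <- make_sac_phantom(phantom_spec(n_frames = 3L, noise_sigma = 0))
  s2 <- make_sac_phantom(phantom_spec(n_frames = 3L, noise_sigma = 0))
  expect_identical(s1$field$vx, s2$field$vx)
  expect_identical(s1$geom$labels, s2$geom$labels)
  n1 <- add_pcmri_noise(s1$field, 1, 0.01, seed = 5L)
  n2 <- add_pcmri_noise(s2$field, 1, 0.01, seed = 5L)
  expect_identical(n1$vx, n2$vx)
})

test_that("velocity-encoding wrap aliases components beyond venc", {
  n <- 4L
  vx <- array(1.1, c(n, n, n, 1L)); z <- array(0, c(n, n, n, 1L))
  f <- velocity_field(vx, z, z, c(1, 1, 1), times = 0.1, period = 1)
  wrapped <- add_pcmri_noise(f, venc = 1.0, sigma = 0)
  expect_equal(unique(as.vector(wrapped$vx)), -0.9)
  # sigma = 0 with sub-venc speeds: bit-identical
  f2 <- velocity_field(z + 0.4, z, z, c(1, 1, 1), times = 0.1, period = 1)
  expect_identical(add_pcmri_noise(f2, 1.0, 0)$vx, f2$vx)
})

test_that("component noise has the nominal standard deviation", {
  n <- 47L  # ~1e5 voxels
  z <- array(0, c(n, n, n, 1L))
  f <- velocity_field(z, z, z, c(1, 1, 1), times = 0.1, period = 1)
  sigma <- 0.02
  noisy <- add_pcmri_noise(f, venc = 1.0, sigma = sigma, seed = 9L)
  for (comp in c("vx", "vy", "vz"))
    expect_rel_equal(stats::sd(noisy[[comp]]), sigma, 0.05)
})

test_that("noise at 5% of the peak sac speed moves delta U by under 5 points", {
  sp <- make_sac_phantom(phantom_spec(n_frames = 4L))
  pk <- sp$truth$peak_frame
  post <- apply_fd_attenuation(sp$field, sp$geom, 0.5)
  d0 <- relative_reduction(average_sac_velocity(sp$field, sp$geom, pk),
                           average_sac_velocity(post, sp$geom, pk))
  sigma <- 0.05 * max(velocity_magnitude(sp$field, pk)[sac_mask(sp$geom)])
  fn <- add_pcmri_noise(sp$field, 1.0, sigma, seed = 21L)
  pn <- add_pcmri_noise(post, 1.0, sigma, seed = 22L)
  dn <- relative_reduction(average_sac_velocity(fn, sp$geom, pk),
                           average_sac_velocity(pn, sp$geom, pk))
  expect_lt(abs(dn - d0), 5)
})
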