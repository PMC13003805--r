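test_that("susceptibility map: values, conventions and trivial cases", {
  g <- voxel_grid(c(16, 16, 16), 1.8)
  empty <- vascular_volume(array(FALSE, g$shape), g)
  full <- vascular_volume(array(TRUE, g$shape), g)
  cfg <- sim_config()
  expect_true(all(susceptibility_map(empty, cfg) == 0))
  expect_true(all(susceptibility_map(full, cfg) == 1e-6))
  cfg4 <- sim_config(chi_convention = "cgs_4pi")
  expect_equal(susceptibility_map(full, cfg4),
               4 * pi * susceptibility_map(full, cfg))
})

test_that("dipole field: constant susceptibility gives zero field", {
  cfg <- sim_config()
  chi <- array(1e-6, c(16, 16, 16))
  fld <- compute_field(chi, cfg, 1.8)
  expect_lt(max(abs(fld$delta_B)), 1e-18)
  expect_error(compute_field(array(NA_real_, c(8, 8, 8)), cfg, 1.8), "NA")
})

test_that("dipole field of a cylinder parallel to B0 is flat outside", {
  cfg <- sim_config()
  n <- 64L
  vol <- cylinder_volume(n = n, voxel_size = 2, radius_vox = 8,
                         center = c(31.5, 31.5))
  chi <- susceptibility_map(vol, cfg)
  fld <- compute_field(chi, cfg, 2)
  ext <- fld$delta_B[!vol$mask]
  scale <- cfg$B0 * cfg$delta_chi
  # spatially constant outside ...
  expect_lt(sd(ext) / scale, 1e-12)
  # ... and equal to the demeaning offset -B0 chi cbv / 3
  expect_equal(mean(ext) / scale, -compute_cbv(vol) / 3, tolerance = 1e-9)
  # which is << the intravascular shift, i.e. 'approximately zero'
  expect_lt(max(abs(ext)) / scale, 0.02)
})

test_that("dipole field of a perpendicular cylinder matches (a/rho)^2 cos 2phi", {
  cfg <- sim_config()
  n <- 96L; vs <- 2; a_vox <- 6 # box >> radius: periodic images negligible
  ctr <- (n - 1) / 2 * vs
  tube <- matrix(c(0, ctr, ctr, (n - 1) * vs, ctr, ctr, a_vox * vs), 1)
  fx <- rasterize_fixture(c(n, n, n), vs, tube)
  chi <- susceptibility_map(fx$volume, cfg)
  fld <- compute_field(chi, cfg, vs)
  yz <- expand.grid(y = (0:(n - 1)) * vs - ctr, z = (0:(n - 1)) * vs - ctr)
  rho2 <- yz$y^2 + yz$z^2
  phi <- atan2(yz$y, yz$z)
  a_um <- a_vox * vs
  analytic <- (cfg$delta_chi / 2) * cfg$B0 * (a_um^2 / rho2) * cos(2 * phi)
  slice <- fld$delta_B[n / 2, , ]
  sel <- rho2 > (2 * a_um)^2 & rho2 < (3.5 * a_um)^2
  err <- slice[cbind(match(yz$y, (0:(n - 1)) * vs - ctr),
                     match(yz$z, (0:(n - 1)) * vs - ctr))] - analytic
  err <- err[sel] - mean(err[sel]) # demeaning offset is physical (k = 0)
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(analytic[sel]^2)), 0.05)
})

test_that("field operator is linear and strictly real", {
  cfg <- sim_config()
  set.seed(8)
  g <- small_sim_grid()
  netA <- generate_network(g, 0.05, seed = 21)
  netB <- generate_network(g, 0.10, seed = 22)
  chiA <- susceptibility_map(netA$volume, cfg)
  chiB <- susceptibility_map(netB$volume, cfg)
  fA <- compute_field(chiA, cfg, g$voxel_size)$delta_B
  fB <- compute_field(chiB, cfg, g$voxel_size)$delta_B
  fAB <- compute_field(chiA + chiB, cfg, g$voxel_size)$delta_B
  expect_equal(fAB, fA + fB, tolerance = 1e-10)
  expect_true(is.double(fA) && !is.complex(fA))
})

test_that("Bloch-Torrey: zero field gives unit signal at all 18 echoes", {
  cfg <- sim_config()
  fld <- structure(list(delta_B = array(0, c(16, 16, 16)), voxel_size = 3.6),
                   class = "field_map")
  s <- evolve_bloch_torrey(fld, NULL, cfg)
  expect_equal(s, rep(1, 18), tolerance = 1e-9)
})

test_that("Bloch-Torrey: static spins refocus perfectly at the spin echo", {
  cfg <- sim_config(D = 0)
  g <- small_sim_grid()
  net <- generate_network(g, 0.2, radius_sampler(min = 4, max = 15), seed = 5)
  curve <- simulate_gesfide(net$volume, cfg)
  # strong dephasing on the FID segment ...
  expect_lt(curve$ratio[4], 0.5)
  # ... fully recovered by the ideal 180-degree pulse at the 120 ms echo
  expect_equal(curve$ratio[12], 1, tolerance = 1e-6)
})

test_that("uniform-gradient free diffusion matches exp(-g^2 G^2 D t^3 / 3)", {
  nz <- 2048L; h <- 0.5
  gam <- GAMMA_PROTON <- 2.675e8
  tes <- c(0.005, 0.01, 0.015, 0.02)
  G <- sqrt(3 / (gam^2 * 1e-9 * max(tes)^3)) # unit exponent at the last echo
  z <- ((0:(nz - 1)) - (nz - 1) / 2) * h * 1e-6
  fld <- structure(list(delta_B = array(G * z, c(1, 1, nz)), voxel_size = h),
                   class = "field_map")
  cfg <- sim_config(D = 1e-3, echo_times = tes, refocus_time = Inf,
                    dt_max = 2.5e-5)
  s <- evolve_bloch_torrey(fld, NULL, cfg, probe_point = c(0, 0, nz / 2))
  # the closed form describes the local magnetization magnitude (the
  # ensemble signal additionally carries the static ramp dephasing)
  expect_equal(attr(s, "probe"), exp(-gam^2 * G^2 * 1e-9 * tes^3 / 3),
               tolerance = 0.02)
})

test_that("stability guard refuses an unstable time step", {
  cfg <- sim_config(dt_max = 0.01, D = 1e-3) # dt = 10 ms >> stability at 3.6 um
  fld <- structure(list(delta_B = array(0, c(8, 8, 8)), voxel_size = 3.6),
                   class = "field_map")
  # choose_dt caps at the stability bound, so force a violation directly
  expect_error(
    vsdmri:::bt_evolve_cpp(rep(0, 512), c(8L, 8L, 8L), rep(1, 512),
                           2.675e8, 1e-9, 3.6e-6, 0.01, 10,
                           10L, -1L) -> dummy, NA)
  # the R-level guard: stability is satisfied by construction
  expect_lte(1e-9 * vsdmri:::choose_dt(cfg, 3.6) / (3.6e-6)^2, 1 / 6 + 1e-12)
})

test_that("empty mask yields unit GESFIDE ratio; higher CBV lowers it", {
  g <- small_sim_grid()
  cfg <- sim_config()
  empty <- vascular_volume(array(FALSE, g$shape), g)
  curve0 <- simulate_gesfide(empty, cfg)
  expect_equal(curve0$ratio, rep(1, 18), tolerance = 1e-9)
  # paired VOIs with the same radius distribution, increasing CBV
  sampler <- radius_sampler(min = 5, max = 12)
  gen_grid <- voxel_grid(c(64, 64, 64), 1.8)
  r60 <- sapply(c(0.05, 0.15, 0.30), function(cbv) {
    net <- generate_network(gen_grid, cbv, sampler, seed = 400)
    frac <- vsdmri:::downsample_mean_cpp(as.numeric(net$volume$mask),
                                         gen_grid$shape, 2L)
    attr(frac, "grid") <- small_sim_grid()
    simulate_gesfide(frac, cfg)$ratio[6]
  })
  expect_true(all(diff(r60) < 0))
})

test_that("spin-echo sampling recovers signal lost to static dephasing", {
  g <- small_sim_grid()
  net <- generate_network(voxel_grid(c(64, 64, 64), 1.8), 0.15,
                          radius_sampler(min = 5, max = 14), seed = 77)
  frac <- vsdmri:::downsample_mean_cpp(as.numeric(net$volume$mask),
                                       c(64L, 64L, 64L), 2L)
  attr(frac, "grid") <- g
  curve <- simulate_gesfide(frac, sim_config())
  # the refocused 120 ms echo exceeds the R2*-extrapolated FID decay
  r2star_fid <- delta_r2_star(curve)
  extrapolated <- curve$ratio[4] * exp(-r2star_fid * (0.120 - 0.040))
  expect_gt(curve$ratio[12], extrapolated)
})

test_that("relaxation-rate estimators match hand-computed values", {
  mk <- function(r10, r40, r120) {
    ratio <- rep(1, 18); ratio[1] <- r10; ratio[4] <- r40; ratio[12] <- r120
    structure(list(echo_times = seq(0.01, 0.18, by = 0.01),
                   s_pre = rep(1, 18), s_post = ratio, ratio = ratio),
              class = "gesfide_curve")
  }
  expect_equal(delta_r2_star(mk(0.90, 0.60, 0.8)), log(1.5) / 0.03,
               tolerance = 1e-12)
  expect_equal(delta_r2_star(mk(0.7, 0.7, 0.8)), 0)
  expect_equal(delta_r2_star(mk(0.6 * exp(0.3), 0.6, 0.8)), 10,
               tolerance = 1e-12)
  expect_equal(delta_r2(mk(1, 1, 0.80)), -log(0.80) / 0.120,
               tolerance = 1e-12)
  expect_equal(delta_r2(mk(1, 1, 1)), 0)
  expect_equal(delta_r2(mk(1, 1, exp(-0.12))), 1, tolerance = 1e-12)
  expect_error(delta_r2(mk(1, 1, -0.1)), "non-positive")
})

test_that("susceptibility-to-iron calibration reproduces the printed values", {
  out <- concentration_from_susceptibility(1)
  expect_equal(out$mg_per_ml, 0.086, tolerance = 0.005)
  expect_equal(out$mM, 1.54, tolerance = 0.005)
  zero <- concentration_from_susceptibility(0)
  expect_equal(zero$mg_per_ml, 0)
  expect_equal(zero$mM, 0)
  expect_error(concentration_from_susceptibility(1, qsm_slope = 0), "slope")
})

test_that("downsampled partial-volume simulation tracks the native grid", {
  gen_grid <- voxel_grid(c(64, 64, 64), 1.8)
  net <- generate_network(gen_grid, 0.12, radius_sampler(min = 5, max = 14),
                          seed = 55)
  cfg <- sim_config()
  native <- simulate_gesfide(net$volume, cfg)
  frac <- vsdmri:::downsample_mean_cpp(as.numeric(net$volume$mask),
                                       gen_grid$shape, 2L)
  attr(frac, "grid") <- small_sim_grid()
  coarse <- simulate_gesfide(frac, cfg)
  expect_lt(max(abs(native$ratio - coarse$ratio)), 0.08)
})
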