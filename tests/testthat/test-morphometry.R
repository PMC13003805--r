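test_that("CLAHE preserves shape, range and flat images", {
  set.seed(1)
  vol <- array(runif(16^3), c(16, 16, 16))
  out <- enhance_contrast(vol)
  expect_identical(dim(out), dim(vol))
  expect_true(all(out >= 0 & out <= 1))
  flat <- array(0.4, c(16, 16, 16))
  expect_identical(enhance_contrast(flat), flat)
})

test_that("CLAHE does not decrease vessel-background contrast", {
  # vessel-like bimodal volume: sparse bright tubes on a dim background
  set.seed(2)
  g <- voxel_grid(c(48, 48, 48), 1.8)
  net <- generate_network(g, 0.06, radius_sampler(min = 4, max = 10),
                          seed = 12)
  vol <- array(rnorm(48^3, 50, 5), g$shape)
  vol[net$volume$mask] <- rnorm(sum(net$volume$mask), 85, 5)
  m <- net$volume$mask
  rng <- range(vol)
  norm <- (vol - rng[1]) / (rng[2] - rng[1])
  # contrast measured at the vessel-background interface (adaptive
  # equalization sharpens boundaries; tile-mean levels may shift)
  shift <- function(a, o, d) {
    n <- dim(a)[d]
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    switch(d, a[idx, , ], a[, idx, ], a[, , idx])
  }
  boundary_gap <- function(x) {
    tot <- 0; cnt <- 0
    for (d in 1:3) for (o in c(-1, 1)) {
      nb <- shift(x, o, d); mb <- shift(m, o, d)
      sel <- m & !mb
      tot <- tot + sum(x[sel] - nb[sel]); cnt <- cnt + sum(sel)
    }
    tot / cnt
  }
  out <- enhance_contrast(vol)
  expect_gte(boundary_gap(out), boundary_gap(norm) * 0.95)
})

test_that("Otsu segmentation recovers a noisy bimodal phantom (Dice >= 0.95)", {
  set.seed(3)
  g <- voxel_grid(c(48, 48, 48), 1.8)
  net <- generate_network(g, 0.10, seed = 11)
  vol <- array(rnorm(48^3, 50, 10), g$shape)
  vol[net$volume$mask] <- rnorm(sum(net$volume$mask), 200, 10)
  seg <- segment(vol, voxel_size = 1.8)
  inter <- sum(seg$mask & net$volume$mask)
  dice <- 2 * inter / (sum(seg$mask) + sum(net$volume$mask))
  expect_gte(dice, 0.95)
  expect_true(is.finite(attr(seg, "threshold")))
  # shift invariance: adding a constant leaves the mask unchanged
  seg2 <- segment(vol + 1000, voxel_size = 1.8)
  expect_identical(seg$mask, seg2$mask)
})

test_that("segmentation of constant volumes warns and returns empty", {
  flat <- array(1, c(16, 16, 16))
  expect_warning(seg <- segment(flat, voxel_size = 1.8), "degenerate")
  expect_false(any(seg$mask))
})

test_that("lumen filling closes a hollow shell into a solid tube", {
  # hollow cylinder: wall of ~1 voxel around a 2-voxel-radius lumen
  n <- 32L
  solid <- cylinder_volume(n = n, voxel_size = 1, radius_vox = 3.4)
  lumen <- cylinder_volume(n = n, voxel_size = 1, radius_vox = 2.2)
  shell <- vascular_volume(solid$mask & !lumen$mask, solid$grid)
  filled <- fill_lumens(shell, kernel_radius_um = 1.5)
  # interior voxels on the axis become foreground
  expect_true(all(filled$mask[16, 16, 5:27]))
  # closing of a solid tube changes at most a thin boundary layer
  refilled <- fill_lumens(solid, kernel_radius_um = 1)
  expect_gte(sum(refilled$mask & solid$mask) / sum(solid$mask), 0.99)
})

test_that("lumen filling keeps only the maximally connected component", {
  g <- voxel_grid(c(32, 32, 32), 1)
  m <- array(FALSE, g$shape)
  m[4:23, 10:14, 10:14] <- TRUE   # 500-voxel block
  m[28:29, 28:29, 28:30] <- TRUE  # 12-voxel crumb
  out <- fill_lumens(vascular_volume(m, g), kernel_radius_um = 1)
  expect_true(all(out$mask[10, 12, 12]))
  expect_false(any(out$mask[28:29, 28:29, 28:30]))
  # empty in, empty out
  empty <- vascular_volume(array(FALSE, g$shape), g)
  expect_false(any(fill_lumens(empty)$mask))
})

test_that("compute_cbv matches the analytic cylinder and is rotation invariant", {
  expect_equal(compute_cbv(array(FALSE, c(8, 8, 8))), 0)
  expect_equal(compute_cbv(array(TRUE, c(8, 8, 8))), 1)
  vol <- cylinder_volume(n = 123L, voxel_size = 1.8, radius_vox = 10)
  expect_equal(compute_cbv(vol), 0.0208, tolerance = 0.02)
  rot <- aperm(vol$mask, c(3, 1, 2))[, , 123:1]
  expect_identical(compute_cbv(vol), compute_cbv(rot))
})

test_that("skeleton of a straight tube is one branch inside the mask", {
  vol <- oblique_cylinder(n = 48L, radius_vox = 4, direction = c(1, 0.6, 0.8))
  gr <- skeletonize_and_label(vol)
  expect_equal(max(gr$branch), 1)
  # point count comparable to the tube length in voxels
  expect_gt(nrow(gr), 30)
  # containment: every skeletal point lies inside the mask
  inside <- mapply(function(x, y, z) vol$mask[x + 1, y + 1, z + 1],
                   gr$x, gr$y, gr$z)
  expect_true(all(inside))
})

test_that("skeleton of a Y-shaped union has three labelled branches", {
  n <- 48L
  cj <- c(24, 24, 24)
  tubes <- rbind(c(24, 24, 2, cj, 2.5),
                 c(cj, 40, 40, 24, 2.5),
                 c(cj, 8, 40, 24, 2.5))
  fx <- rasterize_fixture(c(n, n, n), 1, tubes)
  gr <- skeletonize_and_label(fx$volume)
  expect_equal(max(gr$branch), 3)
})

test_that("empty mask gives an empty skeleton graph", {
  g <- voxel_grid(c(16, 16, 16), 1)
  gr <- skeletonize_and_label(vascular_volume(array(FALSE, g$shape), g))
  expect_equal(nrow(gr), 0)
})

test_that("star-line radius matches the distance-transform oracle on a ball", {
  vol <- ball_volume(n = 24L, radius_vox = 5)
  r <- starline_radius(vol, c(12, 12, 12))
  expect_equal(r, 5, tolerance = 0.5 / 5)
  expect_error(starline_radius(vol, c(0, 0, 0)), "outside")
})

test_that("star-line radius is unbiased (+-0.5 voxel) on digitized cylinders", {
  set.seed(42)
  for (r in c(2, 4, 7, 11)) {
    for (o in 1:3) {
      d <- rnorm(3)
      n <- 48L
      vol <- oblique_cylinder(n = n, radius_vox = r, direction = d)
      gr <- skeletonize_and_label(vol)
      keep <- gr$x > r + 2 & gr$x < n - r - 3 & gr$y > r + 2 &
        gr$y < n - r - 3 & gr$z > r + 2 & gr$z < n - r - 3
      expect_lt(abs(mean(gr$radius_um[keep]) - r), 0.5)
    }
  }
})

test_that("full mask gives a capped, flagged star-line radius", {
  g <- voxel_grid(c(16, 16, 16), 2)
  vol <- vascular_volume(array(TRUE, g$shape), g)
  r <- starline_radius(vol, c(8, 8, 8))
  expect_equal(as.numeric(r), 0.5 * 16 * 2)
  expect_true(isTRUE(attr(r, "capped")))
})

test_that("vessel table: radii, vvf ratios and the partition property", {
  # two disjoint parallel oblique tubes, radii 3 and 8 voxels, equal
  # lengths, widely separated perpendicular to their axis: vvf ratio ~ 9:64
  n <- 96L
  d <- c(1, 0.4, 0.25); d <- d / sqrt(sum(d^2))
  u <- c(-d[2], d[1], 0); u <- u / sqrt(sum(u^2)) # perpendicular offset
  c1 <- c(48, 48, 48) - 20 * u; c2 <- c(48, 48, 48) + 20 * u
  tubes <- rbind(c(c1 - 200 * d, c1 + 200 * d, 3),
                 c(c2 - 200 * d, c2 + 200 * d, 8))
  fx <- rasterize_fixture(c(n, n, n), 1, tubes)
  gr <- skeletonize_and_label(fx$volume)
  tab <- vessel_table(gr, fx$volume)
  expect_equal(nrow(tab), 2)
  tab <- tab[order(tab$mean_radius), ]
  expect_equal(tab$mean_radius[1], 3, tolerance = 0.5 / 3)
  expect_equal(tab$mean_radius[2], 8, tolerance = 0.5 / 8)
  # lengths differ by clipping; compare against the voxel-count truth
  expect_equal(tab$vvf[2] / tab$vvf[1],
               fx$tube_voxels[2] / fx$tube_voxels[1], tolerance = 0.05)
  # partition: vvfs of non-overlapping tubes sum to the CBV
  expect_equal(sum(tab$vvf), compute_cbv(fx$volume), tolerance = 1e-12)
})

test_that("compute_vsd bins vvf by radius and max-normalizes", {
  tab <- vessel_table(id = 1, mean_radius = 5.0, vvf = 0.04)
  v <- compute_vsd(tab)
  expect_equal(v$values[6], 1)            # bin [5, 6)
  expect_equal(sum(v$values), 1)
  tab2 <- vessel_table(id = 1:3, mean_radius = c(3.4, 3.2, 7.5),
                       vvf = c(0.010, 0.020, 0.020))
  v2 <- compute_vsd(tab2)
  expect_equal(v2$raw_vvf_sums[4], 0.030)  # bin [3, 4)
  expect_equal(v2$raw_vvf_sums[8], 0.020)  # bin [7, 8)
  expect_equal(v2$values[4], 1)
  expect_equal(v2$values[8], 2 / 3, tolerance = 1e-12)
  # empty table: all zeros
  v0 <- compute_vsd(vessel_table(id = integer(0), mean_radius = numeric(0),
                                 vvf = numeric(0)))
  expect_equal(v0$values, rep(0, 40))
  # radii beyond the histogram clip into the last bin with a warning
  expect_warning(v41 <- compute_vsd(vessel_table(id = 1, mean_radius = 41,
                                                 vvf = 0.1)), "clipped")
  expect_equal(v41$values[40], 1)
})

test_that("VSD normalization invariant: max bin 1 for random tables", {
  set.seed(5)
  for (i in 1:20) {
    k <- sample(1:12, 1)
    tab <- vessel_table(id = seq_len(k),
                        mean_radius = runif(k, 0.5, 39.5),
                        vvf = runif(k, 0, 0.05))
    v <- compute_vsd(tab)
    expect_equal(max(v$values), 1)
    expect_true(all(v$values >= 0 & v$values <= 1))
  }
})

test_that("true mean radius is the unweighted vessel average", {
  expect_equal(mean_radius_true(vessel_table(id = 1:2,
                                             mean_radius = c(3, 5),
                                             vvf = c(0.1, 0.1))), 4)
  expect_equal(mean_radius_true(vessel_table(id = 1, mean_radius = 7.2,
                                             vvf = 0.2)), 7.2)
  # weights are ignored even when wildly uneven
  expect_equal(mean_radius_true(vessel_table(id = 1:3,
                                             mean_radius = c(2, 2, 8),
                                             vvf = c(0.3, 0.001, 0.001))), 4)
  expect_error(mean_radius_true(vessel_table(id = integer(0),
                                             mean_radius = numeric(0),
                                             vvf = numeric(0))), "empty")
})

test_that("VSD-weighted mean radius uses bin centres", {
  v <- numeric(40); v[6] <- 1
  expect_equal(mean_radius_from_vsd(v), 5.5)
  v2 <- numeric(40); v2[4] <- 1; v2[8] <- 2 / 3
  expect_equal(mean_radius_from_vsd(v2), (3.5 + (2 / 3) * 7.5) / (5 / 3),
               tolerance = 1e-12)
  expect_equal(mean_radius_from_vsd(rep(1, 40)), 20)
  expect_error(mean_radius_from_vsd(numeric(40)), "all-zero")
})

test_that("round trip: morphometry VSD matches generator truth (BC >= 0.9)", {
  for (seed in 1:2) {
    fx <- disjoint_tube_set(seed)
    g <- voxel_grid(c(96, 96, 96), 1.8)
    rast <- rasterize_fixture(g$shape, 1.8, fx$tubes)
    tab_true <- vessel_table(id = seq_along(fx$radii),
                             mean_radius = fx$radii,
                             vvf = rast$tube_voxels / prod(g$shape))
    m <- morphometry(rast$volume, fill = FALSE)
    bc <- bhattacharyya(compute_vsd(tab_true), m$vsd)
    expect_gte(bc, 0.9)
  }
})
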