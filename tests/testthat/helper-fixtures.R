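# Shared fixtures: digitized primitives with analytically known geometry.

# rasterize a set of tubes (n x 7 matrix: endpoints + radius, um) on a grid
rasterize_fixture <- function(shape, voxel_size, tubes) {
  rast <- vsdmri:::rasterize_tubes_cpp(as.integer(shape), voxel_size, tubes)
  list(volume = vascular_volume(array(rast$mask, shape),
                                voxel_grid(shape, voxel_size)),
       tube_voxels = rast$tube_voxels,
       owner = array(rast$owner, shape))
}

# axis-aligned cylinder along the third axis, spanning the full grid
cylinder_volume <- function(n = 64L, voxel_size = 1, radius_vox = 10,
                            center = NULL) {
  if (is.null(center)) center <- rep((n - 1) / 2, 2)
  tube <- matrix(c(center[1] * voxel_size, center[2] * voxel_size, 0,
                   center[1] * voxel_size, center[2] * voxel_size,
                   (n - 1) * voxel_size, radius_vox * voxel_size), 1)
  rasterize_fixture(c(n, n, n), voxel_size, tube)$volume
}

# digitized ball
ball_volume <- function(n = 24L, radius_vox = 5, voxel_size = 1) {
  c0 <- (n - 1) / 2
  co <- expand.grid(x = 0:(n - 1), y = 0:(n - 1), z = 0:(n - 1))
  m <- array((co$x - c0)^2 + (co$y - c0)^2 + (co$z - c0)^2 <= radius_vox^2,
             c(n, n, n))
  vascular_volume(m, voxel_grid(c(n, n, n), voxel_size))
}

# an obliquely oriented cylinder through the grid centre
oblique_cylinder <- function(n = 48L, radius_vox = 4, direction,
                             voxel_size = 1) {
  d <- direction / sqrt(sum(direction^2))
  c0 <- rep((n - 1) / 2, 3) * voxel_size
  tube <- matrix(c(c0 - 100 * d, c0 + 100 * d, radius_vox * voxel_size), 1)
  rasterize_fixture(c(n, n, n), voxel_size, tube)$volume
}

# minimum distance between two segments (used to build disjoint tube sets)
segment_distance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  c1 <- sum(d1 * r); b <- sum(d1 * d2); den <- a * e - b * b
  s <- if (den > 1e-12) max(0, min(1, (b * f - c1 * e) / den)) else 0
  t <- max(0, min(1, (b * s + f) / e))
  s <- max(0, min(1, (b * t - c1) / a))
  sqrt(sum((p1 + s * d1 - p2 - t * d2)^2))
}

# a set of mutually disjoint, randomly oriented tubes with log-normal radii
# (radii rejected outside [r_min, r_max] so no probability atoms sit on a
# histogram bin edge); returns tubes matrix + radii
disjoint_tube_set <- function(seed, n = 96L, voxel_size = 1.8,
                              n_tubes = 16, r_min = 3.6, r_max = 9.6,
                              clearance = 3.6) {
  set.seed(seed)
  ext <- n * voxel_size
  tubes <- NULL; radii <- NULL; tries <- 0
  draw_radius <- function() {
    repeat {
      r <- rlnorm(1, log(6), 0.35)
      if (r >= r_min && r <= r_max) return(r)
    }
  }
  while (length(radii) < n_tubes && tries < 5000) {
    tries <- tries + 1
    r <- draw_radius()
    ctr <- runif(3, 0.25, 0.75) * ext
    dd <- rnorm(3); dd <- dd / sqrt(sum(dd^2))
    p0 <- ctr - 300 * dd; p1 <- ctr + 300 * dd
    ok <- TRUE
    if (!is.null(tubes)) for (j in seq_len(nrow(tubes))) {
      if (segment_distance(p0, p1, tubes[j, 1:3], tubes[j, 4:6]) <
          r + tubes[j, 7] + clearance) { ok <- FALSE; break }
    }
    if (ok) { tubes <- rbind(tubes, c(p0, p1, r)); radii <- c(radii, r) }
  }
  list(tubes = tubes, radii = radii)
}

# fast desk-scale simulation settings shared by signal-level tests
small_sim_grid <- function() voxel_grid(c(32L, 32L, 32L), 3.6)
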