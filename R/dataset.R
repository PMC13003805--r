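# End-to-end dataset synthesis: network generation -> ground-truth labels ->
# partial-volume coarsening -> GESFIDE simulation.

#' Simulate a labelled GESFIDE signal dataset from synthetic vasculature
#'
#' For each VOI a vascular network is generated at the native grid with a
#' target CBV drawn uniformly from `cbv_range`, the ground-truth CBV and the
#' vvf-weighted VSD are taken from the generative truth, the mask is
#' optionally block-averaged into a fractional (partial-volume) mask on a
#' coarser grid, and the pre/post-contrast GESFIDE ratio curve is simulated.
#'
#' @param n_voi number of VOIs.
#' @param grid native generation grid (a [voxel_grid()]).
#' @param downsample integer partial-volume coarsening factor for the
#'   simulation grid (1 = simulate at native resolution).
#' @param cbv_range range the per-VOI target CBV is drawn from.
#' @param sampler a [radius_sampler()].
#' @param cfg a [sim_config()].
#' @param seed master seed; VOI `i` uses `seed + i` for generation.
#' @param n_tubes_max per-VOI tube budget.
#' @param branch_prob Y-branching probability passed to
#'   [generate_network()].
#' @param progress print a progress line every 500 VOIs.
#' @return List with `signals` (N x 18 ratio matrix), `cbv` (N), `vsd`
#'   (N x 40, max-normalized), `mean_radius` (N, unweighted vessel average)
#'   and `provenance`.
#' @export
simulate_dataset <- function(n_voi, grid = voxel_grid(c(64, 64, 64), 1.8),
                             downsample = 2L, cbv_range = c(0.015, 0.38),
                             sampler = radius_sampler(),
                             cfg = sim_config(), seed = 1L,
                             n_tubes_max = 400L, branch_prob = 0.2,
                             progress = FALSE) {
  stopifnot(n_voi >= 1, grid$shape %% downsample == 0)
  n_echo <- length(cfg$echo_times)
  signals <- matrix(NA_real_, n_voi, n_echo)
  cbv <- numeric(n_voi)
  vsd <- matrix(0, n_voi, 40)
  mean_radius <- numeric(n_voi)
  sim_grid <- voxel_grid(grid$shape %/% downsample,
                         grid$voxel_size * downsample)
  targets <- with_seed(seed, runif(n_voi, cbv_range[1], cbv_range[2]))
  for (i in seq_len(n_voi)) {
    net <- generate_network(grid, targets[i], sampler,
                            n_tubes_max = n_tubes_max,
                            seed = seed + i, branch_prob = branch_prob)
    cbv[i] <- net$truth$true_cbv
    vsd[i, ] <- net$truth$true_vsd$values
    mean_radius[i] <- mean_radius_true(net$truth$table)
    frac <- if (downsample > 1) {
      f <- downsample_mean_cpp(as.numeric(net$volume$mask), grid$shape,
                               as.integer(downsample))
      attr(f, "grid") <- sim_grid
      f
    } else net$volume
    curve <- simulate_gesfide(frac, cfg)
    signals[i, ] <- curve$ratio
    if (progress && i %% 500 == 0)
      message(sprintf("  simulated %d / %d VOIs", i, n_voi))
  }
  list(signals = signals, cbv = cbv, vsd = vsd, mean_radius = mean_radius,
       provenance = list(grid = grid, downsample = downsample,
                         cbv_range = cbv_range, seed = seed,
                         n_voi = n_voi, branch_prob = branch_prob,
                         cfg = cfg))
}

#' Write a simulated dataset to CSV files
#'
#' Signals, labels and per-VOI metadata are stored as plain CSV (one file
#' each for signals, CBV + mean radius, and VSD rows).
#'
#' @param dsim result of [simulate_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the written paths.
#' @export
write_dataset_csv <- function(dsim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "signals.csv")
  p2 <- file.path(dir, "labels.csv")
  p3 <- file.path(dir, "vsd.csv")
  write.csv(as.data.frame(dsim$signals), p1, row.names = FALSE)
  write.csv(data.frame(cbv = dsim$cbv, mean_radius = dsim$mean_radius),
            p2, row.names = FALSE)
  write.csv(as.data.frame(dsim$vsd), p3, row.names = FALSE)
  invisible(c(signals = p1, labels = p2, vsd = p3))
}

#' Read a dataset written by [write_dataset_csv()]
#'
#' @param dir dataset directory.
#' @return List with `signals`, `cbv`, `vsd`, `mean_radius`.
#' @export
read_dataset_csv <- function(dir) {
  labels <- read.csv(file.path(dir, "labels.csv"))
  list(signals = as.matrix(read.csv(file.path(dir, "signals.csv"))),
       cbv = labels$cbv,
       vsd = as.matrix(read.csv(file.path(dir, "vsd.csv"))),
       mean_radius = labels$mean_radius)
}
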