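# Morphometry cascade: contrast enhancement -> thresholding -> lumen filling
# -> skeletonization -> branch labelling -> star-line radius estimation ->
# CBV / vvf / VSD.

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE slice-by-slice along the third axis (the in-plane adaptive
#' equalization used on light-sheet stacks), after rescaling intensities to
#' `[0, 1]`.  A constant volume is returned unchanged.
#'
#' @param vol numeric 3D array.
#' @param clip_limit CLAHE clip limit (contrast amplification bound).
#' @param tile_shape number of contextual tiles `(nx, ny)` per slice.
#' @return Numeric array of the same shape with intensities in `[0, 1]`.
#' @export
enhance_contrast <- function(vol, clip_limit = 2, tile_shape = c(8, 8)) {
  g <- attr(vol, "grid")
  stopifnot(length(dim(vol)) == 3, all(is.finite(vol)))
  rng <- range(vol)
  if (rng[2] == rng[1]) return(vol)
  x <- (vol - rng[1]) / (rng[2] - rng[1])
  out <- EBImage::clahe(EBImage::Image(x), nx = tile_shape[1],
                        ny = tile_shape[2], limit = clip_limit)
  out <- array(as.numeric(out), dim(vol))
  out[out < 0] <- 0
  out[out > 1] <- 1
  attr(out, "grid") <- g
  out
}

#' Threshold-based binary segmentation
#'
#' Computes Otsu's global threshold on the (contrast-enhanced) intensity
#' histogram and returns the binary vascular mask.  Intensities are
#' min-max normalized before thresholding, so the segmentation is invariant
#' to affine intensity shifts.  The threshold (on the original intensity
#' scale) is recorded in the `threshold` attribute of the result.
#'
#' @param vol numeric 3D array, optionally carrying a `grid` attribute (else
#'   supply `voxel_size`).
#' @param voxel_size voxel size in um when `vol` has no grid attribute.
#' @return A [vascular_volume()] with attribute `threshold`.
#' @export
segment <- function(vol, voxel_size = NULL) {
  g <- attr(vol, "grid")
  if (is.null(g)) {
    stopifnot(!is.null(voxel_size))
    g <- voxel_grid(dim(vol), voxel_size)
  }
  rng <- range(vol)
  if (rng[2] == rng[1]) {
    warning("constant volume: degenerate threshold, returning empty mask")
    out <- vascular_volume(array(FALSE, dim(vol)), g)
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  x <- (vol - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(matrix(x, nrow = dim(vol)[1])),
                      range = c(0, 1))
  mask <- array(x > th, dim(vol))
  out <- vascular_volume(mask, g)
  attr(out, "threshold") <- rng[1] + th * (rng[2] - rng[1])
  out
}

#' Fill hollow lumens and keep the main vascular network
#'
#' Morphological closing (dilation followed by erosion) with a spherical
#' kernel closes the dark lumens left by wall-only staining of large vessels;
#' the maximally 26-connected component is then retained.  The kernel radius
#' is `max(1 voxel, round(kernel_radius_um / voxel_size))`.
#'
#' @param vol a [vascular_volume()].
#' @param kernel_radius_um spherical kernel radius in um (default 1).
#' @return A [vascular_volume()].
#' @export
fill_lumens <- function(vol, kernel_radius_um = 1.0) {
  stopifnot(inherits(vol, "vascular_volume"))
  if (!any(vol$mask)) return(vol)
  g <- vol$grid
  rv <- max(1, round(kernel_radius_um / g$voxel_size))
  dims <- g$shape
  m <- dilate_ball_cpp(as.logical(vol$mask), dims, rv)
  m <- erode_ball_cpp(m, dims, rv)
  lab <- label_components_cpp(m, dims)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    m <- lab == which.max(sizes)
  }
  vascular_volume(array(m, dims), g)
}

# 13 ray-pair orientations approximately uniform over the hemisphere:
# 3 axes, 6 face diagonals, 4 body diagonals.
starline_directions <- function() {
  d <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
             c(1, 0, -1), c(0, 1, 1), c(0, 1, -1),
             c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  d / sqrt(rowSums(d^2))
}

#' Star-line radius estimate at a point
#'
#' Casts 13 symmetric ray pairs from the query point, measures the chord
#' length through the mask along each pair (the mask boundary is located by
#' linear interpolation of the binary field at the 0.5 level), and returns
#' half the minimum chord, converted to micrometre.
#'
#' @param vol a [vascular_volume()].
#' @param point voxel coordinate (0-based, length 3); must lie inside the
#'   mask.
#' @param n_rays number of ray-pair orientations (only the default 13-pair
#'   star is provided).
#' @return Radius in um.  If the mask fills the whole grid the estimate is
#'   capped at half the grid extent and flagged with attribute
#'   `capped = TRUE`.
#' @export
starline_radius <- function(vol, point, n_rays = 13) {
  stopifnot(inherits(vol, "vascular_volume"), length(point) == 3)
  p <- round(point)
  if (!vol$mask[p[1] + 1, p[2] + 1, p[3] + 1])
    stop("point is outside the mask")
  r <- starline_radius_cpp(as.numeric(vol$mask), vol$grid$shape,
                           matrix(as.numeric(point), 1, 3),
                           starline_directions(), 0.25)
  r_um <- r * vol$grid$voxel_size
  cap <- 0.5 * min(vol$grid$shape) * vol$grid$voxel_size
  if (r_um >= cap) {
    r_um <- cap
    attr(r_um, "capped") <- TRUE
  }
  r_um
}

#' Skeletonize a vascular mask and label branches
#'
#' Thins the mask to a curve skeleton by distance-ordered homotopic thinning
#' (simple-point deletion ordered by a chamfer distance transform, endpoints
#' preserved), splits the skeleton at junction points (voxels with more than
#' two skeletal 26-neighbours), labels each branch as one vessel, merges
#' branches shorter than `min_branch_points` into their longest incident
#' neighbour, assigns junction voxels to the incident branch with the lowest
#' label, and estimates a star-line radius at every skeletal point.
#'
#' @param vol a [vascular_volume()] (after [fill_lumens()]).
#' @param min_branch_points branches with fewer skeletal points are merged
#'   into the longest incident branch (thinning-artifact suppression).
#' @return A `skeleton_graph`: data frame of skeletal points with columns
#'   `x`, `y`, `z` (0-based voxel coordinates), `branch` (label, contiguous
#'   from 1) and `radius_um`, plus the grid as attribute.
#' @export
skeletonize_and_label <- function(vol, min_branch_points = 3) {
  stopifnot(inherits(vol, "vascular_volume"))
  g <- vol$grid
  empty <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                      branch = integer(0), radius_um = numeric(0))
  if (!any(vol$mask))
    return(structure(empty, grid = g, class = c("skeleton_graph",
                                                "data.frame")))
  skel <- skeletonize_cpp(as.logical(vol$mask), g$shape)
  idx <- which(array(skel, g$shape))
  coord <- arrayInd(idx, g$shape) - 1L
  n <- nrow(coord)
  key <- (coord[, 1] + 1) + g$shape[1] * (coord[, 2] +
           as.numeric(g$shape[2]) * coord[, 3])
  pos <- integer(prod(g$shape))
  pos[key] <- seq_len(n)

  # adjacency among skeletal voxels (26-connectivity)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  edges <- NULL
  for (r in seq_len(nrow(off))) {
    nb <- sweep(coord, 2, off[r, ], "+")
    ok <- nb[, 1] >= 0 & nb[, 1] < g$shape[1] &
          nb[, 2] >= 0 & nb[, 2] < g$shape[2] &
          nb[, 3] >= 0 & nb[, 3] < g$shape[3]
    nkey <- (nb[ok, 1] + 1) + g$shape[1] * (nb[ok, 2] +
              as.numeric(g$shape[2]) * nb[ok, 3])
    hit <- pos[nkey] > 0
    from <- which(ok)[hit]
    to <- pos[nkey][hit]
    keep <- from < to
    if (any(keep)) edges <- rbind(edges, cbind(from[keep], to[keep]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  deg <- tabulate(c(edges), nbins = n)
  junction <- deg > 2

  # branches: connected components after junction removal
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0) gr <- igraph::add_edges(gr, t(edges))
  sub <- igraph::delete_vertices(gr, which(junction))
  comp <- igraph::components(sub)
  branch <- integer(n)
  branch[!junction] <- comp$membership

  # star-line radius per skeletal point (needed below for spur pruning)
  rad <- starline_radius_cpp(as.numeric(vol$mask), g$shape,
                             matrix(as.numeric(coord), ncol = 3),
                             starline_directions(), 0.25) * g$voxel_size

  # merge thinning artifacts into the adjacent branch: (a) branches shorter
  # than min_branch_points; (b) terminal spurs shorter (in points) than the
  # radius of the single branch they hang off (in voxels) -- a real vessel
  # shorter than its parent's radius cannot protrude from it
  sizes <- tabulate(branch[branch > 0])
  adj <- igraph::as_adj_list(gr)
  branch_radius_vox <- function(b)
    mean(rad[branch == b]) / g$voxel_size
  repeat {
    merged_any <- FALSE
    for (b in which(sizes > 0)) {
      pts <- which(branch == b)
      nb_lab <- unique(unlist(lapply(pts, function(p) {
        nbs <- as.integer(adj[[p]])
        # direct neighbours and neighbours through one junction voxel
        through <- unlist(lapply(nbs[junction[nbs]],
                                 function(jv) as.integer(adj[[jv]])))
        branch[c(nbs, through)]
      })))
      nb_lab <- setdiff(nb_lab[nb_lab > 0], b)
      if (!length(nb_lab)) next
      is_short <- sizes[b] < min_branch_points
      is_spur <- length(nb_lab) == 1 &&
        sizes[b] < branch_radius_vox(nb_lab[1])
      if (!is_short && !is_spur) next
      target <- nb_lab[which.max(sizes[nb_lab])]
      branch[pts] <- target
      sizes[target] <- sizes[target] + sizes[b]
      sizes[b] <- 0L
      merged_any <- TRUE
    }
    if (!merged_any) break
  }

  # junction voxels: incident branch with the lowest label
  for (jv in which(junction)) {
    labs <- branch[as.integer(adj[[jv]])]
    labs <- labs[labs > 0]
    branch[jv] <- if (length(labs)) min(labs) else max(branch) + 1L
  }
  # contiguous labels from 1, ordered by first occurrence
  branch <- match(branch, unique(branch[branch > 0]))

  out <- data.frame(x = coord[, 1], y = coord[, 2], z = coord[, 3],
                    branch = branch, radius_um = rad)
  structure(out, grid = g, class = c("skeleton_graph", "data.frame"))
}

#' Per-vessel radius and volume-fraction table
#'
#' Builds the vessel table from a labelled skeleton: the radius of a vessel
#' is the mean star-line radius over its skeletal points, and its vessel
#' volume fraction (vvf) is the fraction of all grid voxels assigned to it.
#' Each mask voxel is assigned to the branch of its nearest skeletal point
#' (Euclidean distance, ties to the lower label), so the per-vessel vvfs
#' partition the CBV.
#'
#' @param graph a `skeleton_graph` from [skeletonize_and_label()], or the
#'   first argument of [vessel_table()] called directly with vectors `id`,
#'   `mean_radius`, `vvf`.
#' @param vol the [vascular_volume()] the skeleton was computed on.
#' @param id,mean_radius,vvf direct construction: vessel ids, radii (um) and
#'   volume fractions.
#' @return A data frame of class `vessel_table` with columns `id`,
#'   `mean_radius` (um) and `vvf`.
#' @export
vessel_table <- function(graph = NULL, vol = NULL, id = NULL,
                         mean_radius = NULL, vvf = NULL) {
  if (is.null(graph)) {
    tab <- data.frame(id = as.integer(id), mean_radius = as.numeric(mean_radius),
                      vvf = as.numeric(vvf))
    stopifnot(all(tab$vvf >= 0 & tab$vvf <= 1))
    return(structure(tab, class = c("vessel_table", "data.frame")))
  }
  stopifnot(inherits(graph, "skeleton_graph"), inherits(vol, "vascular_volume"))
  if (nrow(graph) == 0)
    return(vessel_table(id = integer(0), mean_radius = numeric(0),
                        vvf = numeric(0)))
  labs <- sort(unique(graph$branch))
  # edge correction: a skeletal point closer to a volume face than its own
  # radius measures face-clipped chords; exclude such points from the
  # per-vessel average (fall back to all points for branches living
  # entirely in the boundary zone)
  shp <- vol$grid$shape
  border_vox <- pmin(graph$x, shp[1] - 1 - graph$x,
                     graph$y, shp[2] - 1 - graph$y,
                     graph$z, shp[3] - 1 - graph$z)
  interior <- border_vox * vol$grid$voxel_size >= graph$radius_um
  mean_r <- vapply(labs, function(b) {
    sel <- graph$branch == b
    if (any(sel & interior)) mean(graph$radius_um[sel & interior])
    else mean(graph$radius_um[sel])
  }, numeric(1))
  assign <- assign_voxels_cpp(as.logical(vol$mask), vol$grid$shape,
                              matrix(as.numeric(c(graph$x, graph$y, graph$z)),
                                     ncol = 3),
                              as.integer(graph$branch))
  counts <- tabulate(assign[assign > 0], nbins = max(labs))
  vessel_table(id = labs, mean_radius = mean_r,
               vvf = counts[labs] / prod(vol$grid$shape))
}

#' Vessel size distribution histogram
#'
#' The VSD is the vvf-weighted histogram of vessel radii with 1-um bins:
#' bin `i` (radii in `[i, i + 1)` um, `i = 0..39`) accumulates the summed vvf
#' of its vessels, and the histogram is normalized by its maximum bin, so the
#' tallest bin is 1.  Radii of 40 um or more are clipped into the last bin
#' with a warning.  An empty table gives the all-zero histogram.
#'
#' @param table a [vessel_table()].
#' @param n_bins,bin_width histogram geometry (40 bins of 1 um).
#' @return A `vsd_histogram`: list with `values` (max-normalized),
#'   `raw_vvf_sums`, `bin_centers` (um), `bin_width`.
#' @export
compute_vsd <- function(table, n_bins = 40L, bin_width = 1) {
  stopifnot(inherits(table, "vessel_table"))
  raw <- numeric(n_bins)
  if (nrow(table) > 0) {
    bin <- floor(table$mean_radius / bin_width)
    if (any(bin >= n_bins)) {
      warning("vessel radii >= ", n_bins * bin_width,
              " um clipped into the last bin")
      bin[bin >= n_bins] <- n_bins - 1
    }
    bin[bin < 0] <- 0
    for (i in seq_len(nrow(table)))
      raw[bin[i] + 1] <- raw[bin[i] + 1] + table$vvf[i]
  }
  values <- if (max(raw) > 0) raw / max(raw) else raw
  structure(list(values = values, raw_vvf_sums = raw,
                 bin_centers = (seq_len(n_bins) - 0.5) * bin_width,
                 bin_width = bin_width),
            class = "vsd_histogram")
}

#' @export
print.vsd_histogram <- function(x, ...) {
  nz <- which(x$values > 0)
  cat(sprintf("<vsd_histogram> %d bins of %g um, %d non-empty\n",
              length(x$values), x$bin_width, length(nz)))
  invisible(x)
}

#' @export
as.data.frame.vsd_histogram <- function(x, ...) {
  data.frame(bin_center_um = x$bin_centers, value = x$values,
             raw_vvf_sum = x$raw_vvf_sums)
}

#' Mean vessel radius of a VOI (unweighted vessel average)
#'
#' The true mean radius of a VOI is the plain arithmetic mean of the
#' per-vessel radii; vvf weights are deliberately ignored.  See
#' [mean_radius_from_vsd()] for the vvf-weighted companion used on predicted
#' histograms.
#'
#' @param table a non-empty [vessel_table()].
#' @return Mean radius in um.
#' @export
mean_radius_true <- function(table) {
  stopifnot(inherits(table, "vessel_table"))
  if (nrow(table) == 0) stop("mean radius undefined for an empty table")
  mean(table$mean_radius)
}

#' Mean vessel radius from a VSD histogram (vvf-weighted)
#'
#' The predicted mean radius is the histogram-weighted average of the bin
#' centres (`i + 0.5` um): `sum(v_i * c_i) / sum(v_i)`.
#'
#' @param vsd a `vsd_histogram` with at least one positive bin.
#' @return Mean radius in um.
#' @export
mean_radius_from_vsd <- function(vsd) {
  v <- if (inherits(vsd, "vsd_histogram")) vsd$values else as.numeric(vsd)
  centers <- if (inherits(vsd, "vsd_histogram")) vsd$bin_centers else
    seq_along(v) - 0.5
  if (sum(v) <= 0) stop("mean radius undefined for an all-zero histogram")
  sum(v * centers) / sum(v)
}

#' Full morphometry of a binary vascular volume
#'
#' Convenience wrapper running [fill_lumens()], [skeletonize_and_label()],
#' [vessel_table()] and [compute_vsd()] and collecting CBV and mean radii.
#'
#' @param vol a [vascular_volume()].
#' @param fill run the lumen-filling / largest-component step first.
#' @param kernel_radius_um closing kernel radius for [fill_lumens()].
#' @return List with `volume`, `cbv`, `graph`, `table`, `vsd`,
#'   `mean_radius`.
#' @export
morphometry <- function(vol, fill = TRUE, kernel_radius_um = 1.0) {
  if (fill) vol <- fill_lumens(vol, kernel_radius_um)
  graph <- skeletonize_and_label(vol)
  tab <- vessel_table(graph, vol)
  list(volume = vol, cbv = compute_cbv(vol), graph = graph, table = tab,
       vsd = compute_vsd(tab),
       mean_radius = if (nrow(tab)) mean_radius_true(tab) else NA_real_)
}
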