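# Evaluation: histogram similarity, error metrics, agreement analysis,
# SNR-controlled noise injection, and parametric-map stitching.

#' Bhattacharyya coefficient between two histograms
#'
#' `BC = sum(sqrt(p_i * q_i))` after renormalizing both inputs to unit sum
#' (the VSDs handled here are max-normalized, not probability vectors;
#' renormalization keeps BC in `[0, 1]` with `BC(p, p) = 1`).
#'
#' @param p,q non-negative vectors of equal length (or `vsd_histogram`s),
#'   each with a positive sum.
#' @return BC in `[0, 1]`.
#' @export
bhattacharyya <- function(p, q) {
  pv <- if (inherits(p, "vsd_histogram")) p$values else as.numeric(p)
  qv <- if (inherits(q, "vsd_histogram")) q$values else as.numeric(q)
  stopifnot(length(pv) == length(qv), all(pv >= 0), all(qv >= 0))
  if (sum(pv) <= 0 || sum(qv) <= 0)
    stop("Bhattacharyya coefficient undefined for an all-zero histogram")
  sum(sqrt((pv / sum(pv)) * (qv / sum(qv))))
}

#' Mean residual error in percent
#'
#' `MRE = 100 * mean(|pred - true| / true)` (mean absolute relative error).
#'
#' @param true,pred equal-length numeric vectors; all `true` values must be
#'   positive.
#' @return MRE in percent.
#' @export
mre <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  if (any(true == 0)) stop("MRE undefined when a true value is 0")
  100 * mean(abs(pred - true) / abs(true))
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = true - pred`; limits of agreement are
#' `mean(d) +/- 1.96 * SD(d)`.
#'
#' @param true,pred equal-length numeric vectors, `n >= 3`.
#' @return List with `mean_diff`, `lower_limit`, `upper_limit`,
#'   `pct_within_limits` and the differences.  Degenerate limits (zero SD)
#'   are flagged with `degenerate = TRUE`.
#' @export
bland_altman <- function(true, pred) {
  stopifnot(length(true) == length(pred))
  if (length(true) < 3) stop("Bland-Altman analysis needs n >= 3")
  d <- true - pred
  m <- mean(d)
  s <- sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  within <- 100 * mean(d >= lo & d <= hi)
  out <- list(mean_diff = m, lower_limit = lo, upper_limit = hi,
              pct_within_limits = within, differences = d)
  if (s == 0) out$degenerate <- TRUE
  out
}

#' Add white Gaussian noise at a given SNR
#'
#' The SNR is defined on the amplitude scale:
#' `snr_db = 20 * log10(RMS(signal) / sigma)`, so
#' `sigma = RMS(signal) * 10^(-snr_db / 20)`.
#'
#' @param signal numeric vector or matrix (rows = curves; the RMS and draw
#'   are per row for a matrix).
#' @param snr_db target SNR in dB (15, 30, 45 and 60 in the noise study).
#' @param seed integer seed.
#' @return Noisy signal of the same shape.
#' @export
add_noise <- function(signal, snr_db, seed = 1L) {
  stopifnot(is.finite(snr_db))
  with_seed(seed, {
    if (is.matrix(signal)) {
      rms <- sqrt(rowMeans(signal^2))
      sigma <- rms * 10^(-snr_db / 20)
      signal + matrix(rnorm(length(signal)), nrow(signal)) * sigma
    } else {
      sigma <- sqrt(mean(signal^2)) * 10^(-snr_db / 20)
      signal + rnorm(length(signal), 0, sigma)
    }
  })
}

#' Pearson correlation with validity checks
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-zero variance.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("Pearson correlation needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  cor(x, y)
}

#' Stitch per-tile values into a full-resolution parametric map
#'
#' The volume is divided into non-overlapping cubic tiles (VOIs); each voxel
#' of a tile carries the tile's scalar value.  Edge remainders smaller than a
#' full tile are dropped by default (`NA` in the map) or kept with the value
#' of the nearest full-tile grid position when `keep_partial = TRUE`.
#'
#' @param volume_shape integer length-3 shape of the full volume.
#' @param tile_values numeric array (or vector) of per-tile values with one
#'   entry per full tile, in tile-grid order.
#' @param tile_size tile edge length in voxels (123 in the full-scale
#'   setting).
#' @param keep_partial extend edge tiles with the neighbouring tile value.
#' @return A numeric array of shape `volume_shape` (class `parametric_map`),
#'   constant within each tile.
#' @export
stitch_map <- function(volume_shape, tile_values, tile_size = 123L,
                       keep_partial = FALSE) {
  volume_shape <- as.integer(volume_shape)
  nt <- volume_shape %/% tile_size
  if (any(nt < 1)) stop("volume smaller than one tile")
  tv <- array(tile_values, dim = nt)
  if (length(tile_values) != prod(nt))
    stop("tile_values (", length(tile_values), ") do not match the ",
         paste(nt, collapse = "x"), " tile grid")
  out <- array(NA_real_, volume_shape)
  tile_of <- function(n) {
    i <- (seq_len(n) - 1L) %/% tile_size + 1L
    i
  }
  ix <- tile_of(volume_shape[1]); iy <- tile_of(volume_shape[2])
  iz <- tile_of(volume_shape[3])
  if (keep_partial) {
    ix <- pmin(ix, nt[1]); iy <- pmin(iy, nt[2]); iz <- pmin(iz, nt[3])
  }
  ok_x <- ix <= nt[1]; ok_y <- iy <= nt[2]; ok_z <- iz <= nt[3]
  out[ok_x, ok_y, ok_z] <- tv[cbind(
    rep(ix[ok_x], times = sum(ok_y) * sum(ok_z)),
    rep(rep(iy[ok_y], each = sum(ok_x)), times = sum(ok_z)),
    rep(iz[ok_z], each = sum(ok_x) * sum(ok_y)))]
  class(out) <- c("parametric_map", class(out))
  attr(out, "tile_size") <- tile_size
  out
}

#' Summary metrics for predicted CBV and VSD
#'
#' Collects the evaluation battery: Pearson r and MRE between true and
#' predicted CBV, Bland-Altman agreement, and the mean/SD of per-VOI
#' Bhattacharyya coefficients between true and predicted VSDs.
#'
#' @param true_cbv,pred_cbv CBV fractions.
#' @param true_vsd,pred_vsd N x 40 VSD matrices (optional).
#' @return A `metrics_report` list.
#' @export
metrics_report <- function(true_cbv, pred_cbv, true_vsd = NULL,
                           pred_vsd = NULL) {
  rep <- list(pearson_r = pearson(true_cbv, pred_cbv),
              mre_percent = mre(true_cbv, pred_cbv),
              bland_altman = bland_altman(true_cbv, pred_cbv)[
                c("mean_diff", "lower_limit", "upper_limit",
                  "pct_within_limits")])
  if (!is.null(true_vsd)) {
    bc <- vapply(seq_len(nrow(true_vsd)), function(i)
      bhattacharyya(true_vsd[i, ], pred_vsd[i, ]), numeric(1))
    rep$bc_mean <- mean(bc)
    rep$bc_sd <- sd(bc)
    rep$bc <- bc
  }
  structure(rep, class = "metrics_report")
}

#' Save correlation and Bland-Altman plots for predicted CBV
#'
#' Writes a scatter plot of true vs predicted values with the identity line,
#' and a Bland-Altman plot with the mean difference and the 1.96-SD limits
#' of agreement, as PNG files.
#'
#' @param true,pred CBV values (fractions or percent, plotted as given).
#' @param corr_path,ba_path output PNG paths (`NULL` skips either plot).
#' @param label axis label for the quantity.
#' @return Invisibly, the written paths.
#' @export
plot_agreement <- function(true, pred, corr_path = NULL, ba_path = NULL,
                           label = "CBV") {
  if (!is.null(corr_path)) {
    grDevices::png(corr_path, width = 600, height = 600)
    graphics::plot(true, pred, pch = 16, col = "#00000066",
         xlab = paste("true", label), ylab = paste("predicted", label),
         main = sprintf("r = %.3f", pearson(true, pred)))
    graphics::abline(0, 1, col = "red3")
    grDevices::dev.off()
  }
  if (!is.null(ba_path)) {
    ba <- bland_altman(true, pred)
    grDevices::png(ba_path, width = 600, height = 600)
    graphics::plot((true + pred) / 2, true - pred, pch = 16, col = "#00000066",
         xlab = paste("mean", label), ylab = "true - predicted",
         main = sprintf("mean diff %.3g, limits [%.3g, %.3g]",
                        ba$mean_diff, ba$lower_limit, ba$upper_limit))
    graphics::abline(h = c(ba$mean_diff, ba$lower_limit, ba$upper_limit),
           lty = c(1, 2, 2), col = "red3")
    grDevices::dev.off()
  }
  invisible(c(corr_path, ba_path))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> r = %.3f, MRE = %.1f%%", x$pearson_r,
              x$mre_percent))
  if (!is.null(x$bc_mean))
    cat(sprintf(", BC = %.3f +/- %.3f", x$bc_mean, x$bc_sd))
  cat("\n")
  invisible(x)
}
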