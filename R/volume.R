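#' Voxel grid geometry
#'
#' A voxel grid is the common geometric substrate of all volumes handled by
#' the package: an isotropic 3D lattice of given shape and physical voxel
#' size.  Physical coordinates follow the voxel-centre convention: the centre
#' of voxel `(i, j, k)` (0-based) sits at `(i, j, k) * voxel_size` micrometre.
#'
#' @param shape integer vector of length 3, array size in voxels (each >= 8).
#' @param voxel_size isotropic voxel edge length in micrometre (> 0).
#' @return An object of class `voxel_grid` with fields `shape` and
#'   `voxel_size`.
#' @examples
#' voxel_grid(c(123, 123, 123), 1.8)
#' @export
voxel_grid <- function(shape, voxel_size) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 8), is.numeric(voxel_size),
            length(voxel_size) == 1, voxel_size > 0)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels at %.3g um (%.1f um extent)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
              x$shape[1] * x$voxel_size))
  invisible(x)
}

#' Binary vascular volume
#'
#' Wraps a 3D boolean mask together with its grid geometry.  This is the
#' substrate of both morphometry (CBV, skeleton, radii, VSD) and MR signal
#' simulation.
#'
#' @param mask 3D logical (or coercible) array.
#' @param grid a [voxel_grid()] whose shape matches `dim(mask)`.
#' @return An object of class `vascular_volume` with fields `mask` and `grid`.
#' @export
vascular_volume <- function(mask, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(as.integer(dim(mask)), grid$shape))
    stop("mask dimensions do not match grid shape")
  if (anyNA(mask)) stop("mask contains NA")
  structure(list(mask = mask, grid = grid), class = "vascular_volume")
}

#' @export
print.vascular_volume <- function(x, ...) {
  cat(sprintf("<vascular_volume> %d x %d x %d at %.3g um, CBV = %.3f%%\n",
              dim(x$mask)[1], dim(x$mask)[2], dim(x$mask)[3],
              x$grid$voxel_size, 100 * compute_cbv(x)))
  invisible(x)
}

#' Cerebral blood volume of a mask
#'
#' CBV is the ratio of non-zero voxels to the total number of voxels in the
#' binary segmentation, i.e. the volume fraction of the VOI occupied by
#' vessels.
#'
#' @param vol a [vascular_volume()] (or plain logical array).
#' @return CBV as a fraction in `[0, 1]`.
#' @examples
#' g <- voxel_grid(c(16, 16, 16), 1.8)
#' compute_cbv(vascular_volume(array(FALSE, g$shape), g))
#' @export
compute_cbv <- function(vol) {
  m <- if (inherits(vol, "vascular_volume")) vol$mask else vol
  mean(m != 0)
}

#' Read a 3D volume from TIFF or NIfTI
#'
#' Multi-page TIFF stacks are read with \pkg{tiff} (pages become the third
#' axis); `.nii`/`.nii.gz` files are read with \pkg{RNifti}.
#'
#' @param path file path; format chosen by extension.
#' @param voxel_size voxel size in micrometre.  For NIfTI input the default
#'   (`NULL`) takes the pixel dimension from the header.
#' @param binarize if `TRUE`, return a [vascular_volume()] of `value > 0`;
#'   otherwise a numeric array with a `voxel_grid` attribute.
#' @return A `vascular_volume` or numeric array.
#' @export
read_volume <- function(path, voxel_size = NULL, binarize = FALSE) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
    vol <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    if (is.null(voxel_size))
      stop("voxel_size must be given for TIFF input")
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vol <- array(as.numeric(img), dim = dim(img))
    if (is.null(voxel_size)) voxel_size <- RNifti::pixdim(img)[1] * 1000
  } else stop("unsupported volume format: ", path)
  grid <- voxel_grid(dim(vol), voxel_size)
  if (binarize) return(vascular_volume(vol > 0, grid))
  attr(vol, "grid") <- grid
  vol
}

#' Write a 3D volume as multi-page TIFF or NIfTI
#'
#' @param vol a `vascular_volume` or numeric 3D array.
#' @param path output path ending in `.tif`, `.tiff`, `.nii` or `.nii.gz`.
#' @param voxel_size voxel size in micrometre, used for the NIfTI header; for
#'   a `vascular_volume` it is taken from the object.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size = NULL) {
  if (inherits(vol, "vascular_volume")) {
    voxel_size <- vol$grid$voxel_size
    vol <- vol$mask * 1
  }
  vol <- unclass(vol)
  attr(vol, "grid") <- NULL
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(vol)
    sc <- if (rng[2] > 1) vol / rng[2] else vol
    pages <- lapply(seq_len(dim(vol)[3]), function(k) sc[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(vol)
    if (!is.null(voxel_size))
      RNifti::pixdim(img) <- rep(voxel_size / 1000, 3)
    RNifti::writeNifti(img, path)
  } else stop("unsupported volume format: ", path)
  invisible(path)
}
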