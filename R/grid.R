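#' Volumetric brain grid
#'
#' A `brain_grid` describes the voxel lattice every volume in an analysis
#' shares: integer dimensions, voxel size in millimetres, and a 4x4 affine
#' mapping 0-based voxel indices (i, j, k, 1) to millimetre coordinates.
#' Voxel indexing is 0-based throughout; flat (1D) ordering is x-fastest,
#' i.e. R's native column-major array order.
#'
#' @param dims integer vector of length 3, voxel counts per axis (each >= 8).
#' @param voxel_mm numeric vector of length 3, voxel edge lengths in mm.
#' @param origin_mm numeric vector of length 3, mm coordinate of voxel
#'   (0, 0, 0). Defaults to minus half the field of view so the grid is
#'   roughly centred on the coordinate origin.
#' @return an object of class `brain_grid` with elements `dims`, `voxel_mm`
#'   and `affine`.
#' @examples
#' g <- brain_grid(c(24, 28, 24), c(4, 4, 4))
#' g$affine
#' @export
brain_grid <- function(dims, voxel_mm = c(2, 2, 2), origin_mm = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, length(voxel_mm) == 3)
  if (any(dims < 8L)) {
    stop("brain_grid: all dims must be >= 8, got ", paste(dims, collapse = "x"))
  }
  if (any(voxel_mm <= 0)) stop("brain_grid: voxel_mm must be positive")
  if (is.null(origin_mm)) origin_mm <- -(dims - 1) * voxel_mm / 2
  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- origin_mm
  structure(list(dims = dims, voxel_mm = as.numeric(voxel_mm),
                 affine = affine),
            class = "brain_grid")
}

#' Default desk-scale test grid (24 x 28 x 24 voxels at 4 mm)
#' @param full_scale if TRUE, return the full-resolution 91 x 109 x 91 grid at
#'   2 mm matching standard-space resampling; the default is the reduced grid
#'   used for desk-scale simulation and testing.
#' @return a [brain_grid()].
#' @export
default_grid <- function(full_scale = FALSE) {
  if (full_scale) brain_grid(c(91L, 109L, 91L), c(2, 2, 2))
  else brain_grid(c(24L, 28L, 24L), c(4, 4, 4))
}

#' @exportS3Method base::print
print.brain_grid <- function(x, ...) {
  cat(sprintf("<brain_grid %dx%dx%d @ %g/%g/%g mm>\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  invisible(x)
}

n_voxels <- function(grid) prod(grid$dims)

same_grid <- function(a, b) {
  identical(a$dims, b$dims) && isTRUE(all.equal(a$affine, b$affine))
}

#' Convert between 0-based voxel indices and 1-based flat indices
#'
#' Flat ordering is x-fastest (column-major): flat = 1 + i + nx*j + nx*ny*k
#' for 0-based (i, j, k). `voxel_to_flat` and `flat_to_voxel` are exact
#' inverses and are round-trip tested.
#'
#' @param ijk integer matrix (n x 3) of 0-based voxel indices, or a length-3
#'   vector.
#' @param grid a [brain_grid()].
#' @return `voxel_to_flat`: integer vector of 1-based flat indices.
#' @export
voxel_to_flat <- function(ijk, grid) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  nx <- grid$dims[1]; ny <- grid$dims[2]
  as.integer(1L + ijk[, 1] + nx * ijk[, 2] + nx * ny * ijk[, 3])
}

#' @rdname voxel_to_flat
#' @param flat integer vector of 1-based flat indices.
#' @return `flat_to_voxel`: integer matrix (n x 3) of 0-based (i, j, k).
#' @export
flat_to_voxel <- function(flat, grid) {
  nx <- grid$dims[1]; ny <- grid$dims[2]
  f0 <- as.integer(flat) - 1L
  i <- f0 %% nx
  j <- (f0 %/% nx) %% ny
  k <- f0 %/% (nx * ny)
  cbind(i = i, j = j, k = k)
}

#' Millimetre coordinates of voxels
#' @inheritParams voxel_to_flat
#' @return numeric matrix (n x 3) of mm coordinates under the grid affine.
#' @export
voxel_to_mm <- function(ijk, grid) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  xyz1 <- cbind(ijk, 1) %*% t(grid$affine)
  xyz1[, 1:3, drop = FALSE]
}
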