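# Synthetic labeled atlas.
#
# The atlas is a stand-in for an anatomical labeling of standard space: a 3D
# integer volume in which each nonzero value identifies one contiguous
# structure, plus a label table mapping values to (roi_name, subregion_name).
# Structures are placed as spherical blobs at fixed fractional positions that
# roughly respect neuroanatomy (thalamus medial, putamen/insula lateral,
# occipital posterior, cerebellum postero-inferior), mirrored across the
# midline; left and right copies share the roi_name. A deterministic
# seed-driven jitter (<= 1 voxel) keeps placements from being perfectly
# symmetric without moving structures apart.

# (cx, cy, cz) are fractional coordinates of the left-hemisphere centre
# (cx < 0.5), mirrored to the right; base_n is the structure size in voxels
# on the default 24x28x24 test grid, rescaled proportionally on other grids.
ATLAS_STRUCTURES <- data.frame(
  roi = c("insula", "insula",
          "thalamus", "thalamus", "thalamus", "thalamus", "thalamus",
          "putamen", "putamen", "caudate", "pallidum",
          "occipital", "cerebellar grey"),
  subregion = c("anterior", "posterior",
                "pulvinar", "medial dorsal", "ventral lateral", "VPL", "VPM",
                "anterior", "posterior", "", "",
                "", ""),
  cx = c(0.19, 0.19,
         0.37, 0.37, 0.37, 0.37, 0.37,
         0.19, 0.19, 0.32, 0.26,
         0.37, 0.37),
  cy = c(0.64, 0.43,
         0.33, 0.47, 0.61, 0.47, 0.47,
         0.59, 0.37, 0.75, 0.44,
         0.13, 0.24),
  cz = c(0.54, 0.54,
         0.52, 0.69, 0.52, 0.35, 0.52,
         0.30, 0.30, 0.52, 0.27,
         0.52, 0.22),
  base_n = c(28, 28,
             24, 24, 24, 24, 24,
             26, 26, 26, 22,
             60, 60),
  mirror = TRUE,
  stringsAsFactors = FALSE
)

GREY_MATTER_LABEL_NAME <- "grey matter"

#' Build the default synthetic ROI atlas
#'
#' Places every required structure (insula anterior/posterior, five thalamic
#' nuclei, putamen anterior/posterior, caudate, pallidum, occipital cortex --
#' the Carfentanil reference -- and cerebellar grey -- the Raclopride
#' reference) as left/right spherical blobs inside a brain-shaped ellipsoid,
#' then fills the remaining ellipsoid voxels with a generic grey-matter label.
#'
#' @param grid a [brain_grid()]; must be large enough that every structure
#'   receives at least 20 voxels (the default test grid is).
#' @param seed integer; drives the sub-voxel placement jitter. Identical
#'   (grid, seed) gives identical atlases.
#' @return object of class `labeled_atlas`: list with `grid`, `labels`
#'   (3D integer array, 0 = background) and `label_table` (data.frame with
#'   columns label, roi, subregion, hemisphere).
#' @export
build_default_atlas <- function(grid, seed = 1L) {
  dims <- grid$dims
  rng <- local_rng(seed)
  jit <- matrix(rng$runif(nrow(ATLAS_STRUCTURES) * 3, -0.5, 0.5), ncol = 3)

  ax <- seq_len(dims[1]) - 1L
  ay <- seq_len(dims[2]) - 1L
  az <- seq_len(dims[3]) - 1L
  I <- array(rep(ax, times = dims[2] * dims[3]), dim = dims)
  J <- array(rep(rep(ay, each = dims[1]), times = dims[3]), dim = dims)
  K <- array(rep(az, each = dims[1] * dims[2]), dim = dims)

  # brain ellipsoid: semi-axes at 90% of the half-extents
  c0 <- (dims - 1) / 2
  semi <- 0.90 * (dims - 1) / 2
  inside <- ((I - c0[1]) / semi[1])^2 + ((J - c0[2]) / semi[2])^2 +
    ((K - c0[3]) / semi[3])^2 <= 1

  labels <- array(0L, dim = dims)
  rows <- list()
  lbl <- 0L
  # structure sizes scale with the brain volume relative to the default grid
  scale <- sum(inside) / 5450
  for (s in seq_len(nrow(ATLAS_STRUCTURES))) {
    st <- ATLAS_STRUCTURES[s, ]
    target_n <- max(20L, as.integer(round(st$base_n * scale)))
    sides <- if (st$mirror) c("L", "R") else "C"
    for (side in sides) {
      cx <- if (side == "R") 1 - st$cx else st$cx
      ctr <- c(cx, st$cy, st$cz) * (dims - 1) + jit[s, ]
      d2 <- (I - ctr[1])^2 + (J - ctr[2])^2 + (K - ctr[3])^2
      # claim the target_n nearest unclaimed in-brain voxels (nearest-first
      # growth: ball-shaped where space allows, contiguous, never overlapping)
      free <- which(labels == 0L & inside)
      if (length(free) < target_n) {
        stop(sprintf(
          "build_default_atlas: grid too small to place '%s(%s)' [%s]: %d free voxels for %d",
          st$roi, st$subregion, side, length(free), target_n))
      }
      sel <- free[order(d2[free])[seq_len(target_n)]]
      # reject degenerate placements that had to stray far from the centre
      if (max(d2[sel]) > (3 * target_n^(1 / 3))^2) {
        stop(sprintf(
          "build_default_atlas: grid too crowded to place '%s(%s)' [%s] near its centre",
          st$roi, st$subregion, side))
      }
      lbl <- lbl + 1L
      labels[sel] <- lbl
      rows[[lbl]] <- data.frame(label = lbl, roi = st$roi,
                                subregion = st$subregion,
                                hemisphere = side, stringsAsFactors = FALSE)
    }
  }
  # generic grey matter: everything left inside the ellipsoid
  lbl <- lbl + 1L
  sel <- inside & labels == 0L
  labels[sel] <- lbl
  rows[[lbl]] <- data.frame(label = lbl, roi = GREY_MATTER_LABEL_NAME,
                            subregion = "", hemisphere = "C",
                            stringsAsFactors = FALSE)
  structure(list(grid = grid, labels = labels,
                 label_table = do.call(rbind, rows)),
            class = "labeled_atlas")
}

#' @exportS3Method base::print
print.labeled_atlas <- function(x, ...) {
  cat(sprintf("<labeled_atlas: %d labels on %dx%dx%d grid>\n",
              nrow(x$label_table), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3]))
  invisible(x)
}

#' Labels belonging to a named ROI (optionally a subregion)
#' @param atlas a `labeled_atlas`.
#' @param roi character vector of roi names.
#' @param subregion optional character vector of subregion names.
#' @return integer vector of label values.
#' @export
atlas_labels <- function(atlas, roi, subregion = NULL) {
  tab <- atlas$label_table
  sel <- tab$roi %in% roi
  if (!is.null(subregion)) sel <- sel & tab$subregion %in% subregion
  tab$label[sel]
}

# Tracer-specific analysis masks derived from the atlas.
CFN_MASK_ROIS <- c("insula", "thalamus", "putamen", "caudate", "pallidum",
                   "occipital", "cerebellar grey", GREY_MATTER_LABEL_NAME)
BG_MASK_ROIS <- c("putamen", "caudate", "pallidum")

#' Binary analysis mask from the atlas
#'
#' `"grey"` is the grey-matter mask used for Carfentanil whole-brain analysis
#' (all grey labels); `"basal_ganglia"` is the Raclopride mask (putamen,
#' caudate, pallidum).
#'
#' @param atlas a `labeled_atlas`.
#' @param which `"grey"` or `"basal_ganglia"`, or a character vector of roi
#'   names for a custom ROI mask.
#' @return object of class `mask_volume`: list with `grid` and `mask`
#'   (3D 0/1 integer array).
#' @export
atlas_mask <- function(atlas, which = c("grey", "basal_ganglia")) {
  rois <- if (length(which) == 1 && which %in% c("grey", "basal_ganglia")) {
    if (which == "grey") CFN_MASK_ROIS else BG_MASK_ROIS
  } else {
    which
  }
  lbls <- atlas_labels(atlas, rois)
  if (length(lbls) == 0) stop("atlas_mask: no labels match: ",
                              paste(which, collapse = ", "))
  m <- array(0L, dim = atlas$grid$dims)
  m[atlas$labels %in% lbls] <- 1L
  structure(list(grid = atlas$grid, mask = m), class = "mask_volume")
}

#' Default reference-region ROI for a tracer
#' @param tracer `"CFN"` (occipital reference) or `"RCL"` (cerebellar grey).
#' @return roi name.
#' @export
reference_roi <- function(tracer) {
  switch(match.arg(tracer, c("CFN", "RCL")),
         CFN = "occipital", RCL = "cerebellar grey")
}
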