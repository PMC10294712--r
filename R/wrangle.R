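# Volume-to-matrix wrangling: masking, flattening, DVR intensity filtering,
# and the threshold/consistency voxel-retention step that produces the
# design matrix for CBDA.

#' Flatten a BP_ND volume to a 1D DVR array under a mask
#'
#' Out-of-mask voxels are set to exactly 0 and the array length stays the
#' full grid size; in-mask entries carry DVR = BP_ND + 1. Ordering is
#' x-fastest (R column-major), so `unflatten()` is the exact inverse.
#'
#' @param image a `pet_image`.
#' @param mask a `mask_volume` on the same grid.
#' @return numeric vector of length `prod(grid$dims)`.
#' @export
flatten <- function(image, mask) {
  if (!same_grid(image$grid, mask$grid)) {
    stop(sprintf("flatten: image grid %s does not match mask grid %s",
                 paste(image$grid$dims, collapse = "x"),
                 paste(mask$grid$dims, collapse = "x")))
  }
  dvr <- as.vector(image$bpnd) + 1
  dvr[as.vector(mask$mask) == 0] <- 0
  dvr
}

#' Inverse of [flatten()]
#' @param x numeric vector of length `prod(grid$dims)`.
#' @param grid the [brain_grid()].
#' @return 3D array.
#' @export
unflatten <- function(x, grid) {
  stopifnot(length(x) == n_voxels(grid))
  array(x, dim = grid$dims)
}

#' Per-image DVR intensity floor
#'
#' Zeroes entries with DVR below 1.1, the conventional cutoff separating
#' specific binding from reference-level uptake. Zeroing (rather than column
#' removal) keeps array length constant; cohort-level column removal is the
#' job of [apply_threshold()].
#'
#' @param x numeric vector (or matrix) of DVR values.
#' @param floor DVR cutoff, default 1.1; values strictly below it become 0.
#' @return same shape as `x`.
#' @export
dvr_floor <- function(x, floor = 1.1) {
  x[x < floor] <- 0
  x
}

#' Threshold/consistency voxel retention
#'
#' Column (voxel) v is retained iff the fraction of images whose DVR at v is
#' strictly above `intensity_threshold` is at least `consistency`. Retained
#' columns keep their original flat indices; order is preserved.
#'
#' @param X_full images x all-voxels DVR matrix.
#' @param spec a [threshold_spec()].
#' @param y optional binary outcome per row (1 = migraine, 0 = healthy).
#' @param row_meta optional data.frame of per-row metadata.
#' @param grid optional [brain_grid()] for the (i, j, k) columns of the map.
#' @return object of class `voxel_matrix`: list with `X` (retained columns),
#'   `y`, `row_meta`, `col_map` (data.frame: col, flat_index, i, j, k) and
#'   `grid`.
#' @export
apply_threshold <- function(X_full, spec, y = NULL, row_meta = NULL,
                            grid = NULL) {
  stopifnot(is.matrix(X_full), nrow(X_full) >= 1)
  frac <- colMeans(X_full > spec$intensity_threshold)
  keep <- which(frac >= spec$consistency)
  if (length(keep) == 0) {
    stop("apply_threshold: no voxel passes threshold ",
         spec$intensity_threshold, " at consistency ", spec$consistency,
         "; lower the threshold or the consistency")
  }
  if (!is.null(y)) {
    stopifnot(length(y) == nrow(X_full), all(y %in% c(0, 1)))
  }
  if (!is.null(grid)) {
    ijk <- flat_to_voxel(keep, grid)
  } else {
    ijk <- matrix(NA_integer_, length(keep), 3)
  }
  col_map <- data.frame(col = seq_along(keep), flat_index = keep,
                        i = ijk[, 1], j = ijk[, 2], k = ijk[, 3])
  structure(list(X = X_full[, keep, drop = FALSE], y = y,
                 row_meta = row_meta, col_map = col_map, grid = grid),
            class = "voxel_matrix")
}

#' Threshold specification
#' @param intensity_threshold DVR cutoff (strict >). The whole-brain default
#'   is 2.0; ROI-restricted analyses conventionally use the laxer 1.1.
#' @param consistency required fraction of images above the cutoff, in
#'   \[0, 1\]; default 0.8.
#' @return a `threshold_spec` list.
#' @export
threshold_spec <- function(intensity_threshold = 2.0, consistency = 0.8) {
  stopifnot(intensity_threshold > 0, consistency >= 0, consistency <= 1)
  structure(list(intensity_threshold = intensity_threshold,
                 consistency = consistency), class = "threshold_spec")
}

#' @exportS3Method base::print
print.voxel_matrix <- function(x, ...) {
  cat(sprintf("<voxel_matrix: %d images x %d voxels%s>\n", nrow(x$X),
              ncol(x$X),
              if (!is.null(x$y)) sprintf(", %d cases / %d controls",
                                         sum(x$y == 1), sum(x$y == 0))
              else ""))
  invisible(x)
}

#' Assemble the CBDA design matrix from a cohort
#'
#' Runs flatten -> dvr_floor -> apply_threshold over the images of one
#' tracer. The outcome is 1 for migraine groups (EM/CM) and 0 for healthy
#' controls. With `interictal_only = TRUE` the ictal sessions are dropped
#' before thresholding (controls, which carry no attack state, are kept).
#'
#' Accepts either in-memory `pet_image` objects or a manifest directory
#' written by [write_cohort()].
#'
#' @param images list of `pet_image` objects, or a directory containing
#'   `manifest.tsv` plus NIfTI volumes.
#' @param mask a `mask_volume`.
#' @param spec a [threshold_spec()].
#' @param interictal_only drop ictal sessions first.
#' @param apply_floor apply the DVR < 1.1 per-image floor (default TRUE).
#' @return a `voxel_matrix`.
#' @export
assemble_matrix <- function(images, mask, spec = threshold_spec(),
                            interictal_only = FALSE, apply_floor = TRUE) {
  if (is.character(images)) images <- read_cohort(images)
  meta <- do.call(rbind, lapply(images, function(im) {
    data.frame(subject_id = im$subject_id, tracer = im$tracer,
               group = im$group, state = im$state, phase = im$phase,
               sex = im$sex, stringsAsFactors = FALSE)
  }))
  if (length(unique(meta$tracer)) > 1) {
    stop("assemble_matrix: mixed tracers in input (",
         paste(unique(meta$tracer), collapse = ", "),
         "); assemble one tracer at a time")
  }
  if (interictal_only) {
    keep <- meta$state != "ictal"
    images <- images[keep]
    meta <- meta[keep, , drop = FALSE]
    rownames(meta) <- NULL
  }
  X <- do.call(rbind, lapply(images, function(im) {
    v <- flatten(im, mask)
    if (apply_floor) v <- dvr_floor(v)
    v
  }))
  y <- as.integer(meta$group != "HC")
  apply_threshold(X, spec, y = y, row_meta = meta, grid = mask$grid)
}

#' Read a cohort directory written by [write_cohort()]
#' @param directory directory containing `manifest.tsv` and NIfTI volumes.
#' @return list of `pet_image` objects.
#' @export
read_cohort <- function(directory) {
  mpath <- file.path(directory, "manifest.tsv")
  if (!file.exists(mpath)) stop("read_cohort: no manifest.tsv in ", directory)
  manifest <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(r) {
    row <- manifest[r, ]
    nii <- read_nifti(file.path(directory, row$filename))
    out <- as.list(row[c("subject_id", "tracer", "group", "state", "phase",
                         "sex")])
    out$image_id <- sub("\\.nii(\\.gz)?$", "", row$filename)
    out$grid <- nii$grid
    out$bpnd <- nii$data
    structure(out, class = "pet_image")
  })
}
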