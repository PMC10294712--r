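# Synthetic parametric BP_ND volume generation.
#
# The generator emits distribution-volume-ratio (DVR) maps directly: DVR is
# baseline per atlas label, plus an additive group effect in designated
# receptor-rich structures for migraine images of the matching tracer, plus a
# phase effect on late (challenge) images, plus spatially smoothed Gaussian
# noise. Reference-region voxels (occipital for CFN, cerebellar grey for RCL)
# are pinned at DVR = 1 exactly, after noise, as a ratio measure demands.
# BP_ND = DVR - 1 is what gets stored in the volumes.

#' Effect specification for the synthetic generator
#'
#' Defaults state the world the package's recovery tests live in: receptor-
#' rich structures at baseline DVR 2.5 against generic grey matter at 1.3,
#' a migraine effect of +0.5 DVR planted in 20 voxels drawn from the
#' tracer-specific predictive structures (insula anterior, thalamic nuclei
#' and putamen for CFN; anterior putamen for RCL), a +0.1 late-phase shift,
#' and white noise of sd 0.3 smoothed with a 3 mm FWHM Gaussian.
#'
#' @param atlas a `labeled_atlas` the effects refer to.
#' @param delta_bpnd additive group effect (DVR units) applied to migraine
#'   (EM/CM) images in the effect voxels of their tracer.
#' @param n_effect_voxels number of planted voxels per tracer, sampled
#'   without replacement from the effect structures (deterministic given
#'   `seed`); `NULL` applies the effect to every voxel of the structures.
#' @param phase_effect additive DVR shift on late-phase images.
#' @param noise_sd standard deviation of the white Gaussian noise before
#'   smoothing.
#' @param smoothing_fwhm_mm full-width-at-half-maximum of the Gaussian
#'   smoothing applied to the noise field (0 disables smoothing).
#' @param baseline_rich baseline DVR of receptor-rich structures.
#' @param baseline_grey baseline DVR of generic grey matter.
#' @param cfn_effect_rois,rcl_effect_rois roi names carrying the group effect
#'   for each tracer; a name may target a subregion with the
#'   `"roi(subregion)"` syntax.
#' @param seed integer seed for the planted-voxel draw.
#' @return object of class `effect_spec` with a per-label baseline table and
#'   per-tracer planted flat-voxel index sets.
#' @export
effect_spec <- function(atlas,
                        delta_bpnd = 0.5,
                        n_effect_voxels = 20L,
                        phase_effect = 0.1,
                        noise_sd = 0.3,
                        smoothing_fwhm_mm = 3,
                        baseline_rich = 2.5,
                        baseline_grey = 1.3,
                        cfn_effect_rois = c("insula(anterior)", "thalamus",
                                            "putamen"),
                        rcl_effect_rois = "putamen(anterior)",
                        seed = 1L) {
  stopifnot(noise_sd >= 0, smoothing_fwhm_mm >= 0, baseline_rich >= 0,
            baseline_grey >= 0)
  tab <- atlas$label_table
  baseline <- numeric(nrow(tab))
  rich <- c("insula", "thalamus", "putamen", "caudate", "pallidum")
  for (r in seq_len(nrow(tab))) {
    baseline[r] <- if (tab$roi[r] %in% rich) baseline_rich
      else if (tab$roi[r] == GREY_MATTER_LABEL_NAME) baseline_grey
      else 1.0   # reference regions (occipital, cerebellar grey)
  }
  ref_labels <- list(CFN = atlas_labels(atlas, reference_roi("CFN")),
                     RCL = atlas_labels(atlas, reference_roi("RCL")))

  rng <- local_rng(derive_seed(seed, stage = 11L))
  resolve_labels <- function(rois) {
    unlist(lapply(rois, function(r) {
      m <- regmatches(r, regexec("^([^()]+)\\(([^()]+)\\)$", r))[[1]]
      if (length(m) == 3) atlas_labels(atlas, m[2], m[3])
      else atlas_labels(atlas, r)
    }))
  }
  pick <- function(lbls) {
    flat <- which(array(atlas$labels %in% lbls, dim = atlas$grid$dims))
    if (is.null(n_effect_voxels)) return(sort(flat))
    if (length(flat) < n_effect_voxels) {
      stop("effect_spec: effect structures hold only ", length(flat),
           " voxels, need ", n_effect_voxels)
    }
    sort(rng$sample(flat, n_effect_voxels))
  }
  effect_labels <- list(CFN = resolve_labels(cfn_effect_rois),
                        RCL = resolve_labels(rcl_effect_rois))
  effect_voxels <- list(CFN = pick(effect_labels$CFN),
                        RCL = pick(effect_labels$RCL))
  structure(list(baseline = data.frame(label = tab$label, dvr = baseline),
                 delta_bpnd = delta_bpnd, phase_effect = phase_effect,
                 noise_sd = noise_sd, smoothing_fwhm_mm = smoothing_fwhm_mm,
                 effect_labels = effect_labels,
                 effect_voxels = effect_voxels, ref_labels = ref_labels,
                 seed = as.integer(seed)),
            class = "effect_spec")
}

# separable Gaussian smoothing of a 3D field; sigma in voxels per axis
smooth_gaussian <- function(vol, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    half <- max(1L, ceiling(3 * s))
    kern <- stats::dnorm(-half:half, sd = s)
    kern <- kern / sum(kern)
    vol <- convolve_axis(vol, kern, ax)
  }
  vol
}

# 1D convolution along one axis with zero padding, via apply on matricized dims
convolve_axis <- function(vol, kern, axis) {
  d <- dim(vol)
  half <- (length(kern) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dm <- dim(v)
  m <- matrix(v, nrow = dm[1])
  n <- nrow(m)
  padded <- rbind(matrix(0, half, ncol(m)), m, matrix(0, half, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (t in seq_along(kern)) {
    out <- out + kern[t] * padded[(t - 1L) + seq_len(n), , drop = FALSE]
  }
  array(out, dm) |> aperm(order(perm))
}

#' Simulate one BP_ND image for a session record
#'
#' @param session one row of the `images` table from [generate_cohort()]
#'   (needs tracer, group, phase; `subject_id` and the rest are carried as
#'   metadata).
#' @param effects an [effect_spec()].
#' @param atlas the `labeled_atlas` the effects were built on.
#' @param seed integer; identical (session, effects, atlas, seed) gives a
#'   bit-identical volume.
#' @return object of class `pet_image`: the session metadata plus `grid` and
#'   `bpnd` (3D array, BP_ND = DVR - 1).
#' @export
simulate_image <- function(session, effects, atlas, seed = 1L) {
  tracer <- session$tracer
  ref <- effects$ref_labels[[tracer]]
  if (length(ref) == 0) stop("simulate_image: no reference label for tracer ",
                             tracer)
  dims <- atlas$grid$dims
  dvr <- array(1.0, dim = dims)  # background DVR ~ 1 outside labeled tissue
  lab <- atlas$labels
  for (r in seq_len(nrow(effects$baseline))) {
    dvr[lab == effects$baseline$label[r]] <- effects$baseline$dvr[r]
  }
  is_migraine <- session$group %in% c("EM", "CM")
  if (is_migraine && effects$delta_bpnd != 0) {
    ev <- effects$effect_voxels[[tracer]]
    dvr[ev] <- dvr[ev] + effects$delta_bpnd
  }
  if (identical(session$phase, "late") && effects$phase_effect != 0) {
    dvr[lab > 0L] <- dvr[lab > 0L] + effects$phase_effect
  }
  if (effects$noise_sd > 0) {
    rng <- local_rng(seed)
    noise <- array(rng$rnorm(prod(dims), sd = effects$noise_sd), dim = dims)
    if (effects$smoothing_fwhm_mm > 0) {
      sigma_vox <- (effects$smoothing_fwhm_mm / 2.3548) / atlas$grid$voxel_mm
      noise <- smooth_gaussian(noise, sigma_vox)
    }
    dvr <- dvr + noise
  }
  dvr[lab %in% ref] <- 1.0   # reference region pinned exactly
  dvr <- pmax(dvr, 0)
  out <- as.list(session[intersect(names(session),
                                   c("subject_id", "tracer", "group", "state",
                                     "phase", "sex", "image_id"))])
  out$grid <- atlas$grid
  out$bpnd <- dvr - 1
  structure(out, class = "pet_image")
}

#' Simulate a whole cohort of BP_ND images
#'
#' Per-image seeds derive deterministically from `seed` and the image row
#' index, so any subset of images can be regenerated independently.
#'
#' @param cohort result of [generate_cohort()].
#' @param effects an [effect_spec()].
#' @param atlas a `labeled_atlas`.
#' @param seed integer base seed.
#' @return list of `pet_image` objects, one per row of `cohort$images`.
#' @export
simulate_cohort <- function(cohort, effects, atlas, seed = 1L) {
  imgs <- cohort$images
  lapply(seq_len(nrow(imgs)), function(r) {
    simulate_image(imgs[r, , drop = FALSE], effects, atlas,
                   seed = derive_seed(seed, stage = 1L, counter = r))
  })
}

#' Write simulated images as NIfTI files with a TSV manifest
#'
#' @param images list of `pet_image` objects.
#' @param directory output directory (created if missing).
#' @param gz write `.nii.gz` (default) or plain `.nii`.
#' @return the manifest data.frame (also written as `manifest.tsv`), with one
#'   row per image and a `filename` column relative to `directory`.
#' @export
write_cohort <- function(images, directory, gz = TRUE) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gz) ".nii.gz" else ".nii"
  rows <- lapply(images, function(im) {
    fn <- paste0(im$image_id, ext)
    path <- file.path(directory, fn)
    ok <- tryCatch(write_nifti(im$bpnd, im$grid, path),
                   error = function(e) stop("write_cohort: failed writing '",
                                            fn, "': ", conditionMessage(e)))
    data.frame(subject_id = im$subject_id, tracer = im$tracer,
               group = im$group, state = im$state, phase = im$phase,
               sex = im$sex, filename = fn, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(directory, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
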