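test_that("default atlas contains every required structure with >= 20 voxels", {
  atlas <- test_atlas()
  tab <- atlas$label_table
  required <- list(
    c("insula", "anterior"), c("insula", "posterior"),
    c("thalamus", "pulvinar"), c("thalamus", "medial dorsal"),
    c("thalamus", "ventral lateral"), c("thalamus", "VPL"),
    c("thalamus", "VPM"),
    c("putamen", "anterior"), c("putamen", "posterior"),
    c("caudate", ""), c("pallidum", ""), c("occipital", ""),
    c("cerebellar grey", ""), c("grey matter", ""))
  sizes <- table(atlas$labels[atlas$labels > 0])
  for (rs in required) {
    lbls <- atlas_labels(atlas, rs[1],
                         subregion = if (nzchar(rs[2])) rs[2] else NULL)
    expect_gt(length(lbls), 0, label = paste("labels for", rs[1], rs[2]))
    expect_true(all(sizes[as.character(lbls)] >= 20),
                label = paste(rs[1], rs[2], ">= 20 voxels"))
  }
  # every nonzero label value present in the table and vice versa
  expect_setequal(sort(unique(atlas$labels[atlas$labels > 0])), tab$label)
  # left/right copies share the roi name
  mirrored <- tab[tab$hemisphere %in% c("L", "R"), ]
  expect_true(all(table(paste(mirrored$roi, mirrored$subregion)) == 2))
})

test_that("atlas construction is deterministic and fails on tiny grids", {
  g <- test_grid()
  expect_identical(build_default_atlas(g, seed = 7)$labels,
                   build_default_atlas(g, seed = 7)$labels)
  expect_false(identical(build_default_atlas(g, seed = 7)$labels,
                         build_default_atlas(g, seed = 8)$labels))
  expect_error(build_default_atlas(brain_grid(c(8, 8, 8), c(4, 4, 4))),
               "too small|too crowded")
})

test_that("default cohort reproduces the design arithmetic", {
  counts <- cohort_counts(generate_cohort(default_cohort_spec()))
  expect_equal(counts$images_total, 198)
  expect_equal(counts$subjects_cfn, 61)
  expect_equal(counts$images_cfn, 138)
  expect_equal(counts$subjects_rcl, 22)
  expect_equal(counts$images_rcl, 60)
  expect_equal(counts$images_migraine, 132)
  # restricted specs agree with the full one
  cfn <- cohort_counts(generate_cohort(default_cohort_spec("CFN")))
  expect_equal(cfn$images_cfn, 138)
  expect_equal(cfn$subjects_cfn, 61)
})

test_that("image count is 2 x session count for arbitrary specs", {
  spec <- structure(list(
    cohort_stratum("CFN", "HC", "none", 5, 3, id = "a"),
    cohort_stratum("CFN", "EM", "interictal", 4, 2, id = "b"),
    cohort_stratum("CFN", "EM", "ictal", 2, 1, id = "c", subset_of = "b")
  ), class = "cohort_spec")
  co <- generate_cohort(spec)
  expect_equal(nrow(co$images), 2 * nrow(co$sessions))
  expect_equal(nrow(co$sessions), 5 + 4 + 2)
  # linked subjects keep their ids
  expect_true(all(co$sessions$subject_id[co$sessions$stratum == "c"] %in%
                    co$sessions$subject_id[co$sessions$stratum == "b"]))
})

test_that("oversized linked stratum fails loudly", {
  spec <- structure(list(
    cohort_stratum("CFN", "EM", "interictal", 3, 2, id = "b"),
    cohort_stratum("CFN", "EM", "ictal", 5, 2, id = "c", subset_of = "b")
  ), class = "cohort_spec")
  expect_error(generate_cohort(spec), "linked stratum")
})

test_that("noise-free simulation recovers the stated construction exactly", {
  atlas <- test_atlas()
  # flat baseline 1 everywhere, no effects: DVR identically 1, bpnd 0
  eff0 <- effect_spec(atlas, delta_bpnd = 0, phase_effect = 0, noise_sd = 0,
                      baseline_rich = 1, baseline_grey = 1, seed = 1)
  hc <- data.frame(subject_id = "H1", tracer = "CFN", group = "HC",
                   state = "none", phase = "early", sex = "F")
  im <- simulate_image(hc, eff0, atlas, seed = 1)
  expect_true(all(im$bpnd == 0))

  # delta +0.5 in the whole insula: migraine-minus-HC difference is 0.5
  # inside the insula and 0 elsewhere
  eff <- effect_spec(atlas, delta_bpnd = 0.5, n_effect_voxels = NULL,
                     phase_effect = 0, noise_sd = 0,
                     cfn_effect_rois = "insula", seed = 1)
  em <- data.frame(subject_id = "E1", tracer = "CFN", group = "EM",
                   state = "interictal", phase = "early", sex = "F")
  im_hc <- simulate_image(hc, eff, atlas, seed = 1)
  im_em <- simulate_image(em, eff, atlas, seed = 2)
  dif <- im_em$bpnd - im_hc$bpnd
  insula <- atlas$labels %in% atlas_labels(atlas, "insula")
  expect_equal(unique(dif[insula]), 0.5)
  expect_true(all(dif[!insula] == 0))
})

test_that("reference region is pinned at DVR 1 even under noise", {
  atlas <- test_atlas()
  eff <- effect_spec(atlas, noise_sd = 0.3, seed = 1)
  ses <- data.frame(subject_id = "S", tracer = "CFN", group = "EM",
                    state = "interictal", phase = "late", sex = "M")
  im <- simulate_image(ses, eff, atlas, seed = 9)
  occ <- atlas$labels %in% atlas_labels(atlas, "occipital")
  expect_true(all(im$bpnd[occ] == 0))
  expect_true(all(im$bpnd >= -1))          # DVR clipped at 0
  expect_gt(stats::sd(im$bpnd[!occ]), 0.1) # noise really present elsewhere
})

test_that("simulation is deterministic given the seed", {
  atlas <- test_atlas()
  eff <- effect_spec(atlas, noise_sd = 0.3, seed = 1)
  ses <- data.frame(subject_id = "S", tracer = "CFN", group = "CM",
                    state = "ictal", phase = "early", sex = "F")
  expect_identical(simulate_image(ses, eff, atlas, seed = 123)$bpnd,
                   simulate_image(ses, eff, atlas, seed = 123)$bpnd)
  expect_false(identical(simulate_image(ses, eff, atlas, seed = 123)$bpnd,
                         simulate_image(ses, eff, atlas, seed = 124)$bpnd))
})

test_that("write_cohort emits one NIfTI per image plus a matching manifest", {
  atlas <- test_atlas()
  eff <- effect_spec(atlas, noise_sd = 0.2, seed = 1)
  spec <- structure(list(cohort_stratum("CFN", "HC", "none", 1, 1, id = "h"),
                         cohort_stratum("CFN", "EM", "interictal", 1, 0,
                                        id = "e")),
                    class = "cohort_spec")
  co <- generate_cohort(spec)
  imgs <- simulate_cohort(co, eff, atlas, seed = 3)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(imgs, dir)
  expect_equal(nrow(manifest), 4)
  expect_true(all(file.exists(file.path(dir, manifest$filename))))
  back <- read_cohort(dir)
  expect_equal(length(back), 4)
  for (i in seq_along(back)) {
    expect_lt(max(abs(back[[i]]$bpnd - imgs[[i]]$bpnd)), 1e-6)
    expect_identical(back[[i]]$subject_id, imgs[[i]]$subject_id)
  }
})
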