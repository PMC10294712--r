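test_that("draw_subsamples honors sizes, stratification and determinism", {
  y <- rep(c(1, 0), c(60, 40))
  spec <- subsample_spec(M = 5, CSR = 50, FSR = 20, seed = 3)
  subs <- draw_subsamples(100, 200, y, spec)
  expect_length(subs, 5)
  for (sb in subs) {
    expect_length(sb$rows, 50)
    expect_length(sb$features, 20)
    expect_false(anyDuplicated(sb$rows) > 0)
    expect_false(anyDuplicated(sb$features) > 0)
    # class ratio preserved to within one row (60% cases)
    expect_equal(sum(y[sb$rows]), 30, tolerance = 1)
  }
  expect_identical(draw_subsamples(100, 200, y, spec),
                   draw_subsamples(100, 200, y, spec))
  # FSR = p means every feature appears in every subsample
  spec_all <- subsample_spec(M = 3, CSR = 10, FSR = 200, seed = 1)
  expect_true(all(vapply(draw_subsamples(100, 200, y, spec_all),
                         function(s) identical(s$features, 1:200), TRUE)))
  expect_error(draw_subsamples(10, 20, y[1:10],
                               subsample_spec(M = 1, CSR = 11, FSR = 5)),
               "CSR")
  expect_error(draw_subsamples(10, 20, y[1:10],
                               subsample_spec(M = 1, CSR = 5, FSR = 21)),
               "FSR")
})

test_that("run_cbda returns one scored record per subsample", {
  vm <- toy_matrix(n = 20, p = 50)
  spec <- subsample_spec(M = 10, CSR = 20, FSR = 10, seed = 2)
  recs <- run_cbda(vm, spec, library = c("glm", "knn"), V = 5)
  expect_length(recs, 10)
  acc <- vapply(recs, `[[`, numeric(1), "accuracy")
  expect_true(all(acc >= 0 & acc <= 1))
  # feature ids are original flat indices via col_map
  expect_true(all(unlist(lapply(recs, `[[`, "feature_ids")) %in%
                    vm$col_map$flat_index))
  # a subsample containing the perfectly separating voxel scores 1.0
  with_signal <- vapply(recs, function(r) 1L %in% r$features, TRUE)
  expect_true(any(with_signal))
  expect_true(all(acc[with_signal] == 1))
  expect_identical(recs, run_cbda(vm, spec, library = c("glm", "knn"), V = 5))
})

test_that("rank_features follows the documented count/total/id ordering", {
  recs <- list(list(feature_ids = c(1L, 2L, 3L), accuracy = 0.9),
               list(feature_ids = c(2L, 3L, 4L), accuracy = 0.8),
               list(feature_ids = c(4L, 5L, 6L), accuracy = 0.6))
  spec <- subsample_spec(M = 3, CSR = 10, FSR = 3, top_fraction = 2 / 3)
  rk <- rank_features(recs, spec)
  # top 2 records by accuracy: counts 2:{2,3}, 1:{1,4}; ties inside the
  # count-1 pair break on total appearances (4 appears twice overall), then
  # feature id
  expect_equal(rk$feature_id, c(2L, 3L, 4L, 1L))
  expect_equal(rk$top_count, c(2L, 2L, 1L, 1L))
  expect_equal(rk$total_count, c(2L, 2L, 2L, 1L))
  # top_fraction 1: counts equal raw appearance counts
  rk_all <- rank_features(recs, subsample_spec(M = 3, CSR = 10, FSR = 3,
                                               top_fraction = 1))
  expect_equal(rk_all$top_count, rk_all$total_count)
  # single record: all its features, count 1
  rk1 <- rank_features(recs[1], subsample_spec(M = 1, CSR = 10, FSR = 3,
                                               top_fraction = 1))
  expect_equal(rk1$feature_id, c(1L, 2L, 3L))
  expect_equal(rk1$top_count, c(1L, 1L, 1L))
})

test_that("normalized ranking divides top counts by sampling frequency", {
  recs <- list(list(feature_ids = c(1L, 2L), accuracy = 0.9),
               list(feature_ids = c(2L, 3L), accuracy = 0.2),
               list(feature_ids = c(2L, 4L), accuracy = 0.1))
  spec <- subsample_spec(M = 3, CSR = 10, FSR = 2, top_fraction = 1 / 3)
  rk <- rank_features(recs, spec, normalize = TRUE)
  # feature 1: 1/1 = 1; feature 2: 1/3
  expect_equal(rk$score[rk$feature_id == 1L], 1)
  expect_equal(rk$score[rk$feature_id == 2L], 1 / 3)
  expect_equal(rk$feature_id[1], 1L)
})

test_that("nested_topk finds perfect accuracy within the planted prefix", {
  vm <- toy_matrix(n = 30, p = 20)
  # rank the separating voxel (flat id 7 = column 1) first
  ranking <- data.frame(feature_id = vm$col_map$flat_index[c(1, 5, 9)],
                        top_count = c(3, 2, 1), total_count = c(3, 2, 1))
  res <- nested_topk(vm, ranking, kmax = 3, library = "glm", V = 5, seed = 2)
  expect_equal(nrow(res$metrics), 3)
  expect_equal(res$best_accuracy, 1)
  expect_lte(res$best_k, 3)
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in%
                    names(res$metrics)))
  expect_warning(nested_topk(vm, ranking, kmax = 10, library = "glm", V = 5),
                 "truncating")
})

test_that("replications merge to R*K non-unique voxels with seed-driven overlap", {
  vm <- toy_matrix(n = 20, p = 60)
  spec <- subsample_spec(M = 8, CSR = 20, FSR = 30, top_fraction = 0.25,
                         K = 10, R = 3, seed = 5)
  run <- run_replications(vm, spec, library = "glm", V = 5)
  expect_length(run$merged, 3 * 10)
  expect_length(run$top_lists, 3)
  expect_gte(run$overlap_fraction, 0)
  expect_lte(run$overlap_fraction, 1)
  # R = 1: overlap 0 by convention
  spec1 <- subsample_spec(M = 8, CSR = 20, FSR = 30, top_fraction = 0.25,
                          K = 10, R = 1, seed = 5)
  expect_equal(run_replications(vm, spec1, library = "glm",
                                V = 5)$overlap_fraction, 0)
})

test_that("external split is subject-level, stratified, and exhaustive", {
  w <- cfn_world()
  sp <- external_split(w$vm$row_meta, validation_fraction = 0.2, seed = 3)
  # the reference demographics give 4 control + 8 migraine subjects
  meta <- w$vm$row_meta
  val_meta <- meta[sp$validation, ]
  val_subj <- unique(val_meta[, c("subject_id", "group", "sex")])
  expect_equal(sum(val_subj$group == "HC"), 4)
  expect_equal(sum(val_subj$group != "HC"), 8)
  expect_equal(nrow(val_meta), 24)  # 8 + 16 images
  # sex balance within each class
  expect_equal(sum(val_subj$group == "HC" & val_subj$sex == "M"), 2)
  expect_equal(sum(val_subj$group != "HC" & val_subj$sex == "M"), 4)
  # no subject spans both partitions; union covers all rows
  expect_length(intersect(meta$subject_id[sp$train],
                          meta$subject_id[sp$validation]), 0)
  expect_setequal(c(sp$train, sp$validation), seq_len(nrow(meta)))
  # early/late pairs travel together
  tab <- table(val_meta$subject_id, val_meta$phase)
  expect_true(all(tab[, "early"] == tab[, "late"]))
  expect_error(external_split(data.frame(subject_id = "a", group = "HC",
                                         sex = "F")), "fewer than 2")
})
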