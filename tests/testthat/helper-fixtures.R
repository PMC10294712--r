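# Shared fixtures, memoized so expensive simulations run once per suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_grid <- function() default_grid()

test_atlas <- function() memo("atlas", build_default_atlas(test_grid(), seed = 1L))

# a minimal grid object for hand-sized toy volumes (bypasses the >= 8 floor,
# which only guards realistic use)
toy_grid <- function(dims, voxel_mm = c(1, 1, 1)) {
  affine <- diag(c(voxel_mm, 1))
  structure(list(dims = as.integer(dims), voxel_mm = voxel_mm,
                 affine = affine), class = "brain_grid")
}

toy_image <- function(bpnd, grid, tracer = "CFN", group = "HC",
                      state = "none", phase = "early", subject_id = "S01",
                      sex = "F") {
  structure(list(subject_id = subject_id, tracer = tracer, group = group,
                 state = state, phase = phase, sex = sex,
                 image_id = paste0(subject_id, "_", phase),
                 grid = grid, bpnd = bpnd),
            class = "pet_image")
}

all_ones_mask <- function(grid) {
  structure(list(grid = grid, mask = array(1L, dim = grid$dims)),
            class = "mask_volume")
}

# full synthetic CFN world at the stated defaults (delta 0.5, 20 planted
# voxels, noise sd 0.3), memoized
cfn_world <- function(delta = 0.5) {
  key <- paste0("cfn_world_", delta)
  memo(key, {
    atlas <- test_atlas()
    eff <- effect_spec(atlas, delta_bpnd = delta, seed = 1L)
    cohort <- generate_cohort(default_cohort_spec("CFN"))
    images <- simulate_cohort(cohort, eff, atlas, seed = 42L)
    vm <- assemble_matrix(images, atlas_mask(atlas, "grey"),
                          threshold_spec(2.0, 0.8))
    list(atlas = atlas, effects = eff, cohort = cohort, images = images,
         vm = vm)
  })
}

# small separable toy matrix: first column separates the classes perfectly,
# remaining columns are noise
toy_matrix <- function(n = 30, p = 10, seed = 5) {
  rng_old <- get0(".Random.seed", globalenv())
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- y * 2 - 1 + rnorm(n, sd = 0.05)
  if (!is.null(rng_old)) assign(".Random.seed", rng_old, globalenv())
  vm <- structure(list(X = X, y = y,
                       row_meta = data.frame(subject_id = sprintf("S%02d",
                                                                  seq_len(n))),
                       col_map = data.frame(col = seq_len(p),
                                            flat_index = seq_len(p) * 7L,
                                            i = NA, j = NA, k = NA),
                       grid = NULL),
                  class = "voxel_matrix")
  vm
}
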