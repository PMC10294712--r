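# The CBDA procedure: repeated case/feature subsampling, per-subsample
# stacked-ensemble fitting and accuracy scoring, frequency-based feature
# ranking over the top-scoring subsamples, nested top-k validation,
# replication merging, and the subject-level external split.

#' Subsampling specification
#'
#' @param M number of subsamples. The reference protocol uses 5000; desk-
#'   scale runs use far fewer.
#' @param CSR cases per subsample (an absolute count; the reference protocol
#'   sets it to the full row count, e.g. 138 or 60).
#' @param FSR features per subsample (absolute count, reference value 20).
#' @param top_fraction fraction of subsamples, by accuracy, whose features
#'   are counted for the ranking (default 0.05).
#' @param K length of the top-feature list per replication (default 50).
#' @param R number of replications (default 5).
#' @param seed integer base seed.
#' @return a `subsample_spec` list.
#' @export
subsample_spec <- function(M, CSR, FSR, top_fraction = 0.05, K = 50L,
                           R = 5L, seed = 1L) {
  stopifnot(M >= 1, CSR >= 1, FSR >= 1, top_fraction > 0, top_fraction <= 1,
            K >= 1, R >= 1)
  structure(list(M = as.integer(M), CSR = as.integer(CSR),
                 FSR = as.integer(FSR), top_fraction = top_fraction,
                 K = as.integer(K), R = as.integer(R),
                 seed = as.integer(seed)),
            class = "subsample_spec")
}

#' Draw the case/feature index pairs for all subsamples
#'
#' Rows are sampled without replacement, stratified on the outcome so the
#' class ratio is preserved to within one row; features are sampled
#' uniformly without replacement.
#'
#' @param n,p row and column counts of the design matrix.
#' @param y binary outcome (length n) used for stratification.
#' @param spec a [subsample_spec()].
#' @param seed overrides `spec$seed` when given.
#' @return list of `spec$M` elements, each `list(rows, features, seed)`.
#' @export
draw_subsamples <- function(n, p, y, spec, seed = NULL) {
  if (spec$CSR > n) stop("draw_subsamples: CSR = ", spec$CSR,
                         " exceeds n = ", n)
  if (spec$FSR > p) stop("draw_subsamples: FSR = ", spec$FSR,
                         " exceeds p = ", p)
  seed <- seed %||% spec$seed
  rng <- local_rng(derive_seed(seed, stage = 5L))
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  n1 <- round(spec$CSR * length(idx1) / n)
  n1 <- min(max(n1, if (spec$CSR >= 2) 1L else 0L), length(idx1))
  n0 <- min(spec$CSR - n1, length(idx0))
  sub_seeds <- rng$seeds(spec$M)
  lapply(seq_len(spec$M), function(m) {
    rows <- sort(c(idx1[rng$sample_int(length(idx1), n1)],
                   idx0[rng$sample_int(length(idx0), n0)]))
    feats <- sort(rng$sample_int(p, spec$FSR))
    list(rows = rows, features = feats, seed = sub_seeds[m])
  })
}

#' Run the CBDA subsample loop
#'
#' Fits the stacked ensemble on every subsample with internal V-fold
#' cross-validation and records its out-of-fold ensemble accuracy. A
#' subsample degenerating to a single class is redrawn once, then skipped
#' with a warning.
#'
#' @param vm a `voxel_matrix` (see [assemble_matrix()]).
#' @param spec a [subsample_spec()].
#' @param library learner names; default is the fast subset
#'   (`default_library(fast = TRUE)`).
#' @param V internal fold count (capped at the subsample row count).
#' @param seed overrides `spec$seed`.
#' @return list of subsample records: `rows`, `features` (column indices),
#'   `feature_ids` (original flat voxel indices via `col_map`), `accuracy`,
#'   `weights`, `seed`.
#' @export
run_cbda <- function(vm, spec, library = default_library(fast = TRUE),
                     V = 10L, seed = NULL) {
  X <- vm$X; y <- vm$y
  if (length(unique(y)) < 2) stop("run_cbda: outcome has a single class")
  seed <- seed %||% spec$seed
  learners <- get_learners(library)
  subs <- draw_subsamples(nrow(X), ncol(X), y, spec, seed = seed)
  records <- vector("list", length(subs))
  for (m in seq_along(subs)) {
    sb <- subs[[m]]
    if (length(unique(y[sb$rows])) < 2) {
      redraw <- draw_subsamples(nrow(X), ncol(X), y, spec,
                                seed = derive_seed(seed, 6L, m))[[m]]
      if (length(unique(y[redraw$rows])) < 2) {
        warning("run_cbda: subsample ", m,
                " single-class after redraw; skipped")
        next
      }
      sb <- redraw
    }
    Xs <- X[sb$rows, sb$features, drop = FALSE]
    ys <- y[sb$rows]
    Vm <- min(V, length(ys))
    fit <- fit_superlearner(Xs, ys, library = learners, V = Vm,
                            seed = sb$seed)
    records[[m]] <- list(rows = sb$rows, features = sb$features,
                         feature_ids = vm$col_map$flat_index[sb$features],
                         accuracy = oof_accuracy(fit),
                         weights = fit$weights, seed = sb$seed)
  }
  Filter(Negate(is.null), records)
}

#' Frequency-rank features over the top-scoring subsamples
#'
#' The `ceil(top_fraction * M)` records with the highest accuracy are
#' selected (accuracy ties broken by record order); feature occurrences are
#' counted within them and ranked by that count (descending), then by the
#' feature's appearance count across all records (descending), then by
#' feature id (ascending).
#'
#' @param records output of [run_cbda()].
#' @param spec the [subsample_spec()] (supplies `top_fraction`).
#' @param normalize if TRUE, rank by top-count divided by total appearance
#'   count instead of the raw top-count (an alternative stabilization; off
#'   by default).
#' @return data.frame `feature_ranking`: feature_id, top_count, total_count,
#'   plus `score` when normalized.
#' @export
rank_features <- function(records, spec, normalize = FALSE) {
  stopifnot(length(records) >= 1)
  acc <- vapply(records, `[[`, numeric(1), "accuracy")
  n_top <- min(length(records), ceiling(spec$top_fraction * spec$M))
  top_idx <- order(-acc, seq_along(acc))[seq_len(n_top)]
  all_ids <- unlist(lapply(records, `[[`, "feature_ids"))
  top_ids <- unlist(lapply(records[top_idx], `[[`, "feature_ids"))
  total_tab <- table(all_ids)
  top_tab <- table(top_ids)
  ids <- as.integer(names(top_tab))
  top_count <- as.integer(top_tab)
  total_count <- as.integer(total_tab[names(top_tab)])
  if (normalize) {
    score <- top_count / total_count
    ord <- order(-score, -total_count, ids)
    out <- data.frame(feature_id = ids[ord], top_count = top_count[ord],
                      total_count = total_count[ord], score = score[ord])
  } else {
    ord <- order(-top_count, -total_count, ids)
    out <- data.frame(feature_id = ids[ord], top_count = top_count[ord],
                      total_count = total_count[ord])
  }
  class(out) <- c("feature_ranking", class(out))
  out
}

#' Nested top-k validation of a feature ranking
#'
#' For k = 1..kmax, fits the stacked ensemble on the top-k ranked voxels
#' with internal cross-validation and reports out-of-fold accuracy,
#' sensitivity and specificity, plus the smallest k attaining the maximum
#' accuracy (the overfitting check: accuracy should plateau well before
#' kmax on real signal and hover at prevalence on none).
#'
#' @param vm a `voxel_matrix`.
#' @param ranking a `feature_ranking`.
#' @param kmax largest subset size (default 50; truncated with a warning if
#'   the ranking is shorter).
#' @param library learner names (default fast subset).
#' @param V fold count.
#' @param seed integer seed.
#' @return list with `metrics` (data.frame k, accuracy, sensitivity,
#'   specificity), `best_k`, `best_accuracy`.
#' @export
nested_topk <- function(vm, ranking, kmax = 50L,
                        library = default_library(fast = TRUE), V = 10L,
                        seed = 1L) {
  stopifnot(nrow(ranking) >= 1)
  if (kmax > nrow(ranking)) {
    warning("nested_topk: kmax = ", kmax, " exceeds ranking length ",
            nrow(ranking), "; truncating")
    kmax <- nrow(ranking)
  }
  cols <- match(ranking$feature_id[seq_len(kmax)], vm$col_map$flat_index)
  if (anyNA(cols)) stop("nested_topk: ranking contains feature ids not in col_map")
  learners <- get_learners(library)
  rows <- lapply(seq_len(kmax), function(k) {
    fit <- fit_superlearner(vm$X[, cols[seq_len(k)], drop = FALSE], vm$y,
                            library = learners, V = V,
                            seed = derive_seed(seed, 8L, k))
    pred <- classify(fit$oof)
    cm <- confusion_metrics(vm$y, pred)
    data.frame(k = k, accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity)
  })
  metrics <- do.call(rbind, rows)
  best_k <- metrics$k[which.max(metrics$accuracy)]  # first max = minimal k
  list(metrics = metrics, best_k = best_k,
       best_accuracy = max(metrics$accuracy))
}

#' Run R CBDA replications and merge their top-K lists
#'
#' Replication r runs the full subsample-rank procedure with seed
#' `seed + r`; the per-replication top-K feature lists are concatenated
#' without deduplication (so the merged length is R * K), and the overlap
#' fraction is the share of distinct voxels appearing in at least two
#' replications.
#'
#' @param vm a `voxel_matrix`.
#' @param spec a [subsample_spec()] (`R` and `K` are taken from it).
#' @param library learner names.
#' @param V fold count.
#' @param seed overrides `spec$seed`.
#' @return list with `replications` (per-replication rankings), `top_lists`,
#'   `merged` (concatenated feature ids), `overlap_fraction`.
#' @export
run_replications <- function(vm, spec, library = default_library(fast = TRUE),
                             V = 10L, seed = NULL) {
  seed <- seed %||% spec$seed
  reps <- lapply(seq_len(spec$R), function(r) {
    recs <- run_cbda(vm, spec, library = library, V = V, seed = seed + r)
    rank_features(recs, spec)
  })
  top_lists <- lapply(reps, function(rk) {
    k <- min(spec$K, nrow(rk))
    if (k < spec$K) warning("run_replications: ranking shorter than K (",
                            nrow(rk), " < ", spec$K, ")")
    rk$feature_id[seq_len(k)]
  })
  merged <- unlist(top_lists)
  overlap <- if (spec$R == 1L) 0 else {
    in_rep <- table(unlist(lapply(top_lists, unique)))
    mean(in_rep >= 2)
  }
  list(replications = reps, top_lists = top_lists, merged = merged,
       overlap_fraction = overlap)
}

#' Subject-level stratified external validation split
#'
#' Splits at the subject level (both phase images of a subject travel
#' together), stratified by class. The validation count per class is
#' `round(fraction * n_subjects)` decremented to an even number so the draw
#' can be balanced between male and female subjects; with the reference
#' Carfentanil demographics (23 HC, 38 migraine) this yields 4 control and 8
#' migraine validation subjects (8 + 16 images).
#'
#' @param row_meta data.frame with columns subject_id, group, sex (one row
#'   per image).
#' @param validation_fraction fraction of subjects per class to hold out.
#' @param seed integer seed.
#' @param sex_balance balance the held-out subjects between sexes.
#' @return list with `train` and `validation` row indices and
#'   `validation_subjects`.
#' @export
external_split <- function(row_meta, validation_fraction = 0.2, seed = 1L,
                           sex_balance = TRUE) {
  cls <- ifelse(row_meta$group == "HC", "HC", "migraine")
  subj <- unique(data.frame(subject_id = row_meta$subject_id, cls = cls,
                            sex = row_meta$sex, stringsAsFactors = FALSE))
  n_img <- table(row_meta$subject_id)
  rng <- local_rng(derive_seed(seed, stage = 9L))
  # draw from the subjects with the fewest images first (repeat-state
  # subjects carry four images; holding them out would push the validation
  # image share past the subject share)
  draw <- function(avail, k) {
    counts <- as.integer(n_img[avail])
    avail <- avail[order(counts, rng$runif(length(avail)))]
    avail[seq_len(k)]
  }
  val_subjects <- character(0)
  for (cl in c("HC", "migraine")) {
    pool <- subj[subj$cls == cl, , drop = FALSE]
    if (nrow(pool) < 2) stop("external_split: class stratum '", cl,
                             "' has fewer than 2 subjects")
    n_val <- round(validation_fraction * nrow(pool))
    if (sex_balance && n_val %% 2 == 1) n_val <- n_val - 1L
    n_val <- max(n_val, if (sex_balance) 2L else 1L)
    if (sex_balance) {
      per_sex <- n_val %/% 2L
      for (sx in c("M", "F")) {
        avail <- pool$subject_id[pool$sex == sx]
        if (length(avail) < per_sex) {
          stop("external_split: stratum '", cl, "/", sx, "' has only ",
               length(avail), " subjects, need ", per_sex)
        }
        val_subjects <- c(val_subjects, draw(avail, per_sex))
      }
    } else {
      val_subjects <- c(val_subjects, draw(pool$subject_id, n_val))
    }
  }
  val_rows <- which(row_meta$subject_id %in% val_subjects)
  train_rows <- setdiff(seq_len(nrow(row_meta)), val_rows)
  list(train = train_rows, validation = val_rows,
       validation_subjects = sort(val_subjects))
}
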