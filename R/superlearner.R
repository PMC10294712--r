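# Cross-validated stacked ensemble ("SuperLearner"-style): V-fold
# out-of-fold prediction for each base learner, NNLS meta-weighting of the
# out-of-fold probability matrix against the outcome, and full-data refits
# for prediction.

#' Outcome-stratified (optionally group-aware) V-fold assignment
#'
#' Folds are near-equal in size (difference at most 1 when rows are
#' ungrouped) and stratified on the outcome. If `groups` is given, all rows
#' of a group are assigned to the same fold (e.g. the early/late image pair
#' of one subject), with stratification on the group's outcome.
#'
#' @param n number of rows.
#' @param V number of folds (2 <= V <= n).
#' @param seed integer seed.
#' @param strata optional outcome vector for stratification.
#' @param groups optional per-row group ids that must not be split.
#' @return integer fold id (1..V) per row.
#' @export
make_folds <- function(n, V = 10L, seed = 1L, strata = NULL, groups = NULL) {
  if (V > n) stop("make_folds: V = ", V, " exceeds n = ", n)
  if (V < 2L) stop("make_folds: V must be >= 2")
  rng <- local_rng(derive_seed(seed, stage = 2L))
  if (is.null(groups)) groups <- seq_len(n)
  gid <- unique(groups)
  g_stratum <- if (is.null(strata)) rep(0, length(gid)) else
    vapply(gid, function(g) strata[match(g, groups)], numeric(1))
  fold_of_group <- integer(length(gid))
  names(fold_of_group) <- as.character(gid)
  fold_sizes <- numeric(V)
  for (s in unique(g_stratum)) {
    members <- gid[g_stratum == s]
    members <- members[rng$sample_int(length(members))]
    for (g in members) {
      g_n <- sum(groups == g)
      f <- which.min(fold_sizes)
      fold_of_group[as.character(g)] <- f
      fold_sizes[f] <- fold_sizes[f] + g_n
    }
  }
  unname(fold_of_group[as.character(groups)])
}

#' Out-of-fold base-learner predictions
#'
#' Trains each learner on every fold complement and predicts the held-out
#' fold, producing the n x L matrix the meta-learner is fit on. A learner
#' that fails on any fold is dropped entirely with a warning rather than
#' aborting the run.
#'
#' @param X numeric feature matrix.
#' @param y binary outcome.
#' @param library character vector of registered learner names, or the
#'   result of [get_learners()].
#' @param folds integer fold assignment per row (see [make_folds()]).
#' @param seed integer seed (per-learner/fold seeds derive from it).
#' @return matrix Z (n x surviving learners) with learner names as columns.
#' @export
cv_predictions <- function(X, y, library, folds, seed = 1L) {
  learners <- if (is.character(library)) get_learners(library) else library
  n <- nrow(X)
  V <- max(folds)
  cols <- list()
  for (li in seq_along(learners)) {
    ln <- learners[[li]]
    z <- rep(NA_real_, n)
    ok <- TRUE
    for (v in seq_len(V)) {
      test <- which(folds == v)
      train <- which(folds != v)
      res <- tryCatch({
        model <- ln$fit(X[train, , drop = FALSE], y[train],
                        seed = derive_seed(seed, stage = 3L,
                                           counter = li * 1000L + v),
                        hyper = ln$hyper)
        ln$predict(model, X[test, , drop = FALSE])
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning("cv_predictions: learner '", ln$name, "' failed on fold ",
                v, " (", conditionMessage(res), "); dropping its column")
        ok <- FALSE
        break
      }
      z[test] <- clip(res, 0, 1)
    }
    if (ok) cols[[ln$name]] <- z
  }
  if (length(cols) == 0) stop("cv_predictions: all learners failed")
  Z <- do.call(cbind, cols)
  colnames(Z) <- names(cols)
  Z
}

#' Fit the cross-validated stacked ensemble
#'
#' @param X numeric feature matrix.
#' @param y binary outcome (0/1).
#' @param library learner names (default [default_library()]).
#' @param V fold count, default 10.
#' @param seed integer seed.
#' @param groups optional per-row group ids passed to [make_folds()].
#' @param hyper optional per-learner hyperparameter overrides.
#' @return object of class `sl_fit`: learner names, folds, `Z` (out-of-fold
#'   probabilities), `cv_risk` (per-learner out-of-fold MSE), `weights`
#'   (NNLS convex combination), full-data refits, and `oof` (out-of-fold
#'   ensemble probabilities).
#' @export
fit_superlearner <- function(X, y, library = default_library(), V = 10L,
                             seed = 1L, groups = NULL, hyper = NULL) {
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) stop("fit_superlearner: y has a single class")
  learners <- if (is.character(library)) get_learners(library, hyper) else library
  folds <- make_folds(nrow(X), V = V, seed = seed, strata = y,
                      groups = groups)
  Z <- cv_predictions(X, y, learners, folds, seed = seed)
  surviving <- colnames(Z)
  cv_risk <- colMeans((Z - y)^2)
  alpha <- nnls_weights(Z, y, cv_risk = cv_risk)
  names(alpha) <- surviving
  fits <- lapply(surviving, function(nm) {
    ln <- learners[[nm]]
    ln$fit(X, y, seed = derive_seed(seed, stage = 4L,
                                    counter = match(nm, surviving)),
           hyper = ln$hyper)
  })
  names(fits) <- surviving
  structure(list(library = surviving, folds = folds, Z = Z,
                 cv_risk = cv_risk, weights = alpha, fits = fits,
                 learners = learners[surviving],
                 oof = clip(drop(Z %*% alpha), 0, 1), y = y,
                 V = V, seed = seed),
            class = "sl_fit")
}

#' @exportS3Method base::print
print.sl_fit <- function(x, ...) {
  cat("<sl_fit>\n  weights:\n")
  for (nm in x$library) {
    cat(sprintf("    %-9s %.3f  (cv risk %.4f)\n", nm, x$weights[nm],
                x$cv_risk[nm]))
  }
  cat(sprintf("  out-of-fold accuracy: %.4f\n",
              mean((x$oof >= 0.5) == (x$y == 1))))
  invisible(x)
}

#' Predict ensemble probabilities for new data
#' @param object an `sl_fit`.
#' @param newX numeric matrix with the training columns.
#' @param ... unused.
#' @return probabilities in \[0, 1\].
#' @export
predict.sl_fit <- function(object, newX, ...) {
  P <- vapply(object$library, function(nm) {
    object$learners[[nm]]$predict(object$fits[[nm]],
                                  newX)
  }, numeric(nrow(newX)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  clip(drop(P %*% object$weights), 0, 1)
}

#' Classify at the 0.5 probability cut
#' @param prob probabilities.
#' @return integer 0/1 (probability >= 0.5 maps to 1).
#' @export
classify <- function(prob) as.integer(prob >= 0.5)

#' Out-of-fold ensemble accuracy of a fitted stack
#' @param fit an `sl_fit`.
#' @return accuracy in \[0, 1\].
#' @export
oof_accuracy <- function(fit) mean(classify(fit$oof) == fit$y)
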