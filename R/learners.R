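# Base-learner registry for the stacked ensemble.
#
# Each learner is a list(fit = function(X, y, seed) model,
#                        predict = function(model, X) probabilities)
# where X is a numeric matrix and y a 0/1 vector; predictions are clipped to
# [0, 1]. Learners must be deterministic given the seed. The registry is
# extensible via register_learner(); the built-in library is:
#   glm      logistic regression (IRLS, unpenalized)
#   ridge    L2-penalized logistic regression (glmnet, alpha = 0)
#   lasso    L1-penalized logistic regression (glmnet, alpha = 1)
#   rf       bagged CART forest (gini splits, random feature subsets)
#   knn      k-nearest neighbours on standardized features
#   constant training-set prevalence
#
# The penalized learners use a fixed penalty at `lambda_frac` of the maximal
# penalty by default; this keeps the many thousands of small fits of a CBDA
# run affordable. Set `cv_lambda = TRUE` in the hyperparameters to select the
# penalty by internal cross-validation instead.

.learner_registry <- new.env(parent = emptyenv())

#' Register a base learner
#' @param name learner name used in library specifications.
#' @param fit function(X, y, seed, hyper) returning a model object.
#' @param predict function(model, X) returning probabilities in \[0, 1\].
#' @param hyper named list of default hyperparameters.
#' @return `name`, invisibly.
#' @export
register_learner <- function(name, fit, predict, hyper = list()) {
  assign(name, list(fit = fit, predict = predict, hyper = hyper),
         envir = .learner_registry)
  invisible(name)
}

#' Look up registered learners
#' @param names character vector of learner names; NULL lists all names.
#' @param hyper optional named list of per-learner hyperparameter overrides,
#'   e.g. `list(knn = list(k = 5))`.
#' @return list of learner definitions (or all names if `names` is NULL).
#' @export
get_learners <- function(names = NULL, hyper = NULL) {
  if (is.null(names)) return(sort(ls(.learner_registry)))
  missing <- setdiff(names, ls(.learner_registry))
  if (length(missing) > 0) {
    stop("unknown learner(s): ", paste(missing, collapse = ", "),
         "; registered: ", paste(ls(.learner_registry), collapse = ", "))
  }
  out <- lapply(names, function(nm) {
    ln <- get(nm, envir = .learner_registry)
    if (!is.null(hyper[[nm]])) ln$hyper <- utils::modifyList(ln$hyper,
                                                             hyper[[nm]])
    ln$name <- nm
    ln
  })
  names(out) <- names
  out
}

#' Default base-learner library
#' @param fast if TRUE, the cheap subset used inside CBDA subsample loops.
#' @return character vector of learner names.
#' @export
default_library <- function(fast = FALSE) {
  if (fast) c("glm", "lasso", "knn")
  else c("glm", "ridge", "lasso", "rf", "knn", "constant")
}

# ---- glm ------------------------------------------------------------------

fit_glm <- function(X, y, seed, hyper) {
  df <- ncol(X)
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  co <- fit$coefficients
  co[is.na(co)] <- 0
  list(coef = co)
}

predict_glm <- function(model, X) {
  clip(stats::plogis(drop(cbind(1, X) %*% model$coef)), 0, 1)
}

# ---- glmnet (ridge / lasso) ----------------------------------------------

fit_glmnet <- function(X, y, seed, hyper, alpha) {
  if (ncol(X) < 2) {  # glmnet needs >= 2 columns; pad with a zero column
    X <- cbind(X, 0)
    pad <- TRUE
  } else pad <- FALSE
  if (isTRUE(hyper$cv_lambda)) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                            nfolds = hyper$nfolds %||% 5L,
                            standardize = TRUE)
    list(fit = cv$glmnet.fit, s = cv$lambda.min, pad = pad)
  } else {
    # small-lambda convergence notices from the path fit are routine for
    # near-separable subsamples; anything else still surfaces
    fit <- withCallingHandlers(
      glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                     standardize = TRUE,
                     nlambda = hyper$nlambda %||% 30L),
      warning = function(w) {
        if (grepl("Convergence|lambda", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    lam <- fit$lambda
    s <- max(min(lam), max(lam) * (hyper$lambda_frac %||% 0.05))
    list(fit = fit, s = s, pad = pad)
  }
}

predict_glmnet <- function(model, X) {
  if (model$pad) X <- cbind(X, 0)
  p <- stats::predict(model$fit, newx = X, s = model$s, type = "response")
  clip(drop(p), 0, 1)
}

# ---- random forest (bagged CART) -----------------------------------------

# Vectorized best-split search for one feature: returns c(gini, threshold)
best_split_feature <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cum1 <- cumsum(ys)
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(c(Inf, NA))
  nl <- i; nr <- n - i
  p1l <- cum1[i] / nl
  p1r <- (cum1[n] - cum1[i]) / nr
  gini <- (nl * 2 * p1l * (1 - p1l) + nr * 2 * p1r * (1 - p1r)) / n
  gini[!valid] <- Inf
  b <- which.min(gini)
  c(gini[b], (xs[b] + xs[b + 1L]) / 2)
}

grow_tree <- function(X, y, mtry, maxdepth, minsplit, rng) {
  build <- function(idx, depth) {
    node <- list(prob = mean(y[idx]))
    if (depth >= maxdepth || length(idx) < minsplit ||
        length(unique(y[idx])) == 1L) {
      return(node)
    }
    feats <- rng$sample_int(ncol(X), min(mtry, ncol(X)))
    best <- c(Inf, NA); best_f <- NA
    for (f in feats) {
      sp <- best_split_feature(X[idx, f], y[idx])
      if (sp[1] < best[1]) { best <- sp; best_f <- f }
    }
    if (!is.finite(best[1])) return(node)
    left <- idx[X[idx, best_f] <= best[2]]
    right <- idx[X[idx, best_f] > best[2]]
    if (length(left) == 0L || length(right) == 0L) return(node)
    node$feature <- best_f
    node$threshold <- best[2]
    node$left <- build(left, depth + 1L)
    node$right <- build(right, depth + 1L)
    node
  }
  build(seq_len(nrow(X)), 0L)
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  rec <- function(node, idx) {
    if (is.null(node$feature)) { out[idx] <<- node$prob; return(invisible()) }
    go_left <- X[idx, node$feature] <= node$threshold
    if (any(go_left)) rec(node$left, idx[go_left])
    if (any(!go_left)) rec(node$right, idx[!go_left])
  }
  rec(node, seq_len(n))
  out
}

fit_rf <- function(X, y, seed, hyper) {
  rng <- local_rng(derive_seed(seed, stage = 7L))
  ntree <- hyper$ntree %||% 30L
  mtry <- hyper$mtry %||% max(1L, floor(sqrt(ncol(X))))
  maxdepth <- hyper$maxdepth %||% 4L
  minsplit <- hyper$minsplit %||% 5L
  n <- nrow(X)
  trees <- lapply(seq_len(ntree), function(t) {
    boot <- rng$sample_int(n, n, replace = TRUE)
    grow_tree(X[boot, , drop = FALSE], y[boot], mtry, maxdepth, minsplit, rng)
  })
  list(trees = trees)
}

predict_rf <- function(model, X) {
  preds <- vapply(model$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  clip(rowMeans(preds), 0, 1)
}

# ---- k-nearest neighbours -------------------------------------------------

fit_knn <- function(X, y, seed, hyper) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, "/"), y = y, mu = mu, sd = sd,
       k = hyper$k %||% 9L)
}

predict_knn <- function(model, X) {
  Xs <- sweep(sweep(X, 2, model$mu), 2, model$sd, "/")
  tr <- model$X
  k <- min(model$k, nrow(tr))
  # squared Euclidean cross-distances
  d2 <- outer(rowSums(Xs^2), rowSums(tr^2), "+") - 2 * Xs %*% t(tr)
  p <- apply(d2, 1, function(row) {
    mean(model$y[order(row)[seq_len(k)]])
  })
  clip(p, 0, 1)
}

# ---- constant -------------------------------------------------------------

fit_constant <- function(X, y, seed, hyper) list(p = mean(y))
predict_constant <- function(model, X) rep(model$p, nrow(X))

# registration at load time
register_builtin_learners <- function() {
  register_learner("glm", fit_glm, predict_glm)
  register_learner("ridge",
                   function(X, y, seed, hyper) fit_glmnet(X, y, seed, hyper, 0),
                   predict_glmnet,
                   hyper = list(lambda_frac = 0.05, nlambda = 30L,
                                cv_lambda = FALSE))
  register_learner("lasso",
                   function(X, y, seed, hyper) fit_glmnet(X, y, seed, hyper, 1),
                   predict_glmnet,
                   hyper = list(lambda_frac = 0.05, nlambda = 30L,
                                cv_lambda = FALSE))
  register_learner("rf", fit_rf, predict_rf,
                   hyper = list(ntree = 30L, maxdepth = 4L, minsplit = 5L))
  register_learner("knn", fit_knn, predict_knn, hyper = list(k = 9L))
  register_learner("constant", fit_constant, predict_constant)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_learners()
}
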