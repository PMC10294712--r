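# Classification metrics with exact binomial confidence intervals, and
# ROI-level frequency tables for top predictive voxels.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Closed form via beta quantiles: lower = qbeta(a/2, x, n - x + 1),
#' upper = qbeta(1 - a/2, x + 1, n - x), with lower = 0 at x = 0 and
#' upper = 1 at x = n. Endpoints are exact; rounding happens only at
#' presentation.
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (> 0).
#' @param level confidence level, default 0.95.
#' @return numeric `c(lower, upper)`.
#' @export
exact_binomial_ci <- function(successes, n, level = 0.95) {
  if (n <= 0) stop("exact_binomial_ci: n must be positive")
  stopifnot(successes >= 0, successes <= n)
  a <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(a / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - a / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Confusion-matrix classification metrics
#'
#' Sensitivity and specificity are the two class-conditional correct rates.
#' Which class counts as "positive" is a labeling convention
#' (`positive = 1` by default: sensitivity is the correct rate among
#' `y_true == 1`); both per-class rates and class sizes are always reported
#' so either convention can be read off.
#'
#' @param y_true,y_pred binary vectors of equal length.
#' @param positive the class treated as positive (0 or 1).
#' @param level confidence level for the accuracy interval.
#' @return object of class `classification_metrics`: n, per-class correct
#'   counts and sizes, accuracy, sensitivity, specificity, ci (exact
#'   binomial interval for accuracy).
#' @export
confusion_metrics <- function(y_true, y_pred, positive = 1L, level = 0.95) {
  stopifnot(length(y_true) == length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% 0:1), all(y_pred %in% 0:1))
  n <- length(y_true)
  pos <- y_true == positive
  neg <- !pos
  correct_pos <- sum(y_pred[pos] == y_true[pos])
  correct_neg <- sum(y_pred[neg] == y_true[neg])
  sens <- if (sum(pos) == 0) {
    warning("confusion_metrics: no rows of the positive class; sensitivity undefined")
    NA_real_
  } else correct_pos / sum(pos)
  spec <- if (sum(neg) == 0) {
    warning("confusion_metrics: no rows of the negative class; specificity undefined")
    NA_real_
  } else correct_neg / sum(neg)
  correct <- correct_pos + correct_neg
  structure(list(n = n, positive = positive,
                 n_positive = sum(pos), n_negative = sum(neg),
                 correct_positive = correct_pos,
                 correct_negative = correct_neg,
                 accuracy = correct / n,
                 sensitivity = sens, specificity = spec,
                 ci = exact_binomial_ci(correct, n, level)),
            class = "classification_metrics")
}

#' @exportS3Method base::print
print.classification_metrics <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f\n95%% CI: (%.4f, %.4f)\n", x$accuracy,
              x$ci["lower"], x$ci["upper"]))
  cat(sprintf("Sensitivity: %.4f  (class %d, n = %d)\n", x$sensitivity,
              x$positive, x$n_positive))
  cat(sprintf("Specificity: %.4f  (class %d, n = %d)\n", x$specificity,
              1L - x$positive, x$n_negative))
  invisible(x)
}

#' ROI / subregion frequency table for a merged top-voxel list
#'
#' Counts how many entries of a (non-unique) merged feature list fall in
#' each atlas ROI (or subregion), as a percentage of the list length.
#' Features outside any label are tallied separately as `unlabeled` and do
#' not enter the table, so percentages sum to at most 100.
#'
#' @param feature_ids integer flat voxel indices (repetitions allowed and
#'   counted).
#' @param atlas a `labeled_atlas`.
#' @param by `"roi"` (whole-brain mode) or `"subregion"` (ROI mode; the
#'   subregion name falls back to the roi name where no subregion exists).
#' @return object of class `roi_frequency`: data.frame (name, count,
#'   percent) sorted by percent descending, with attributes `n_total` and
#'   `n_unlabeled`.
#' @export
roi_frequency <- function(feature_ids, atlas, by = c("roi", "subregion")) {
  by <- match.arg(by)
  if (length(feature_ids) == 0) {
    out <- data.frame(name = character(0), count = integer(0),
                      percent = numeric(0))
    attr(out, "n_total") <- 0L
    attr(out, "n_unlabeled") <- 0L
    class(out) <- c("roi_frequency", class(out))
    return(out)
  }
  labs <- atlas$labels[feature_ids]
  tab <- atlas$label_table
  name_of <- if (by == "roi") tab$roi else
    ifelse(tab$subregion == "", tab$roi,
           sprintf("%s(%s)", tab$roi, tab$subregion))
  nm <- ifelse(labs == 0L, NA_character_, name_of[match(labs, tab$label)])
  unlab <- sum(is.na(nm))
  counts <- table(nm[!is.na(nm)])
  out <- data.frame(name = names(counts), count = as.integer(counts),
                    percent = 100 * as.integer(counts) / length(feature_ids),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_total") <- length(feature_ids)
  attr(out, "n_unlabeled") <- unlab
  class(out) <- c("roi_frequency", class(out))
  out
}

#' Assemble the human-readable run report
#'
#' Prints per-replication metric blocks, the nested top-k curve, and the
#' ROI/subregion frequency tables of the merged top-voxel list, plus the
#' configuration echo and seeds. Regeneration from the same inputs is
#' byte-identical.
#'
#' @param run result of [run_replications()].
#' @param atlas a `labeled_atlas`.
#' @param vm the `voxel_matrix` the run used.
#' @param topk optional result of [nested_topk()].
#' @param metrics optional list of `classification_metrics`, one per
#'   replication.
#' @param config_echo optional named list echoed verbatim.
#' @param file optional path; the report is also returned as a character
#'   vector of lines.
#' @return character vector of report lines, invisibly if `file` is given.
#' @export
report_run <- function(run, atlas, vm, topk = NULL, metrics = NULL,
                       config_echo = NULL, file = NULL) {
  if (is.null(run$merged)) stop("report_run: run is missing 'merged'")
  lines <- c("== CBDA run report ==", "")
  if (!is.null(config_echo)) {
    lines <- c(lines, "-- config --",
               sprintf("%s: %s", names(config_echo),
                       vapply(config_echo, function(v)
                         paste(format(v), collapse = ","), "")),
               "")
  }
  lines <- c(lines, sprintf("images: %d   voxels retained: %d",
                            nrow(vm$X), ncol(vm$X)),
             sprintf("replications: %d   merged top list: %d voxels   overlap: %.3f",
                     length(run$replications), length(run$merged),
                     run$overlap_fraction), "")
  if (!is.null(metrics)) {
    for (r in seq_along(metrics)) {
      m <- metrics[[r]]
      lines <- c(lines, sprintf("-- replication %d --", r),
                 sprintf("Accuracy: %.4f", m$accuracy),
                 sprintf("95%% CI: (%.4f, %.4f)", m$ci["lower"],
                         m$ci["upper"]),
                 sprintf("Sensitivity: %.4f", m$sensitivity),
                 sprintf("Specificity: %.4f", m$specificity), "")
    }
  }
  if (!is.null(topk)) {
    lines <- c(lines, "-- nested top-k --",
               sprintf("best k: %d  best accuracy: %.4f", topk$best_k,
                       topk$best_accuracy),
               "k\taccuracy\tsensitivity\tspecificity",
               sprintf("%d\t%.4f\t%.4f\t%.4f", topk$metrics$k,
                       topk$metrics$accuracy, topk$metrics$sensitivity,
                       topk$metrics$specificity), "")
  }
  for (mode in c("roi", "subregion")) {
    ft <- roi_frequency(run$merged, atlas, by = mode)
    lines <- c(lines, sprintf("-- frequency by %s --", mode),
               "name\tcount\tpercent",
               sprintf("%s\t%d\t%.2f", ft$name, ft$count, ft$percent),
               sprintf("(unlabeled: %d of %d)", attr(ft, "n_unlabeled"),
                       attr(ft, "n_total")), "")
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
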