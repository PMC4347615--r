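#' Group-aware k-fold assignment
#'
#' Randomly assigns samples to k folds of near-equal size while keeping all
#' samples that share a group key (the duplicated copies of a
#' multi-location protein) in the same fold, so a protein never sits on
#' both sides of a train/test boundary.  Multi-sample groups are placed
#' first, each into the currently smallest fold, then single-sample groups
#' even the counts out.
#'
#' @param samples a \code{"sample_table"} (see [expand_manifest()]), or any
#'   data.frame with a \code{group} column.
#' @param k number of folds (default 10).
#' @param seed integer seed; the assignment is a pure function of
#'   (samples, k, seed).
#' @return integer vector of fold indices in 1..k, one per sample.
#' @export
kfold_split <- function(samples, k = 10L, seed = 1L) {
  stopifnot(is.data.frame(samples), "group" %in% names(samples))
  if (nrow(samples) < k) stop("fewer samples than folds")
  groups <- unique(samples$group)
  if (k > length(groups)) {
    stop("k = ", k, " exceeds the number of independent groups (",
         length(groups), ")")
  }
  sizes <- table(samples$group)[groups]
  with_seed(seed, {
    ord <- sample(seq_along(groups))
    groups <- groups[ord]
    sizes <- as.integer(sizes[ord])
    ## multi-sample groups first so singletons can level the folds
    ord2 <- order(-sizes)
    groups <- groups[ord2]
    sizes <- sizes[ord2]
    counts <- integer(k)
    fold_of <- integer(length(groups))
    for (i in seq_along(groups)) {
      f <- which.min(counts)
      fold_of[i] <- f
      counts[f] <- counts[f] + sizes[i]
    }
    fold_of[match(samples$group, groups)]
  })
}

#' Overall prediction accuracy Q
#'
#' \eqn{Q = 100 \cdot C / N}: the percentage of correctly classified
#' samples, with each (protein, location) sample counted once.
#'
#' @param predictions predicted labels.
#' @param truth true labels, same length.
#' @return accuracy in percent.
#' @export
accuracy_Q <- function(predictions, truth) {
  if (length(predictions) != length(truth)) {
    stop("predictions and truth must have equal length")
  }
  if (length(truth) == 0L) stop("empty input")
  100 * sum(as.character(predictions) == as.character(truth)) / length(truth)
}

#' Per-location prediction accuracy
#'
#' Accuracy restricted to the samples truly belonging to each location.  A
#' location with no samples is reported as \code{NA} (undefined), not 0,
#' so empty classes are never conflated with fully misclassified ones.
#'
#' @inheritParams accuracy_Q
#' @param labels ordered label universe; defaults to the labels present in
#'   \code{truth}.
#' @return named numeric vector of percentages (NA where undefined).
#' @export
per_location_accuracy <- function(predictions, truth, labels = NULL) {
  truth <- as.character(truth)
  predictions <- as.character(predictions)
  if (is.null(labels)) labels <- sort(unique(truth))
  if (!all(truth %in% labels)) {
    stop("truth contains labels outside the given universe")
  }
  vapply(stats::setNames(labels, labels), function(lb) {
    idx <- truth == lb
    if (!any(idx)) return(NA_real_)
    accuracy_Q(predictions[idx], truth[idx])
  }, 0)
}

#' Cross-validated evaluation of the Rotation Forest pipeline
#'
#' Runs group-aware k-fold cross-validation: per fold, a Rotation Forest is
#' fitted on the other k-1 folds and its predictions recorded for the
#' held-out fold.  The report aggregates the union of held-out predictions
#' into overall accuracy Q, per-location accuracies and a confusion
#' matrix.
#'
#' @param samples a \code{"sample_table"} with one row per (protein,
#'   location) sample.
#' @param x numeric feature matrix, rows aligned with \code{samples}.
#' @param k number of folds (default 10).
#' @param seed integer seed for both the fold split and the per-fold model
#'   seeds.
#' @param ... passed to [rotation_forest()] (\code{ntree},
#'   \code{subset_size}, ...).
#' @return an object of class \code{"cv_report"}: a list with
#'   \code{fold_assignments}, \code{predictions}, \code{truth},
#'   \code{overall_Q}, \code{per_location_Q}, \code{confusion}, \code{k},
#'   \code{seed} and \code{n}.
#' @export
cross_validate <- function(samples, x, k = 10L, seed = 1L, ...) {
  stopifnot(is.data.frame(samples))
  x <- as.matrix(x)
  if (nrow(x) != nrow(samples)) {
    stop("feature matrix rows (", nrow(x), ") do not match sample count (",
         nrow(samples), ")")
  }
  labels <- attr(samples, "label_universe") %||% sort(unique(samples$label))
  folds <- kfold_split(samples, k = k, seed = seed)
  truth <- as.character(samples$label)
  pred <- character(nrow(samples))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- rotation_forest(x[!test, , drop = FALSE],
                           factor(truth[!test], levels = labels),
                           seed = derive_seed(seed, 10000L + f), ...)
    pred[test] <- as.character(
      predict(fit, x[test, , drop = FALSE]))
  }
  confusion <- table(truth = factor(truth, levels = labels),
                     predicted = factor(pred, levels = labels))
  structure(list(fold_assignments = folds,
                 predictions = pred,
                 truth = truth,
                 overall_Q = accuracy_Q(pred, truth),
                 per_location_Q = per_location_accuracy(pred, truth, labels),
                 confusion = confusion,
                 k = as.integer(k), seed = as.integer(seed),
                 n = nrow(samples)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, digits = 1, ...) {
  cat(x$k, "-fold cross-validation over ", x$n, " samples (seed ", x$seed,
      ")\n\n", sep = "")
  tab <- data.frame(
    Location = names(x$per_location_Q),
    Samples = as.integer(rowSums(x$confusion)),
    `Accuracy (%)` = ifelse(is.na(x$per_location_Q), "-",
                            formatC(x$per_location_Q, digits = digits,
                                    format = "f")),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  cat("\nOverall Q = ", formatC(x$overall_Q, digits = digits, format = "f"),
      "%\n", sep = "")
  invisible(x)
}

#' Serialize a CV report to JSON
#'
#' Writes fold assignments, predictions, the confusion matrix and the
#' accuracy table as a single JSON document.
#'
#' @param report a \code{"cv_report"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_cv_report <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  jsonlite::write_json(
    list(k = report$k, seed = report$seed, n = report$n,
         overall_Q = report$overall_Q,
         per_location_Q = as.list(report$per_location_Q),
         fold_assignments = report$fold_assignments,
         predictions = report$predictions,
         truth = report$truth,
         confusion = list(labels = rownames(report$confusion),
                          counts = unclass(unname(report$confusion)))),
    path, auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Paired two-sided t-test
#'
#' Standard paired t-test on two equal-length vectors of accuracies (or any
#' paired measurements): \eqn{t = \bar d / (s_d / \sqrt{n})} on n - 1
#' degrees of freedom, two-sided.  Refuses all-identical differences,
#' where t is undefined.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return a list with \code{statistic}, \code{df} and \code{p.value}.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  n <- length(a)
  if (n < 2L) stop("need at least 2 pairs")
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    stop("degenerate paired t-test: all differences identical (t undefined)")
  }
  tstat <- mean(d) / (s / sqrt(n))
  list(statistic = tstat, df = n - 1L,
       p.value = 2 * stats::pt(-abs(tstat), df = n - 1L))
}
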