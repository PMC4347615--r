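#' Rotation Forest ensemble classifier
#'
#' Fits a Rotation Forest: an ensemble of decision trees in which each tree
#' is trained on a copy of the data linearly transformed by a per-tree
#' rotation matrix.  The rotation is assembled by splitting the N features
#' at random into disjoint subsets of \code{subset_size}, applying PCA to a
#' class-subsampled bootstrap of each subset, and placing each subset's
#' principal-axis loadings as a column block aligned with the original
#' feature order.  Rotating with (near-)orthogonal blocks preserves the
#' information in the data while presenting every tree with differently
#' oriented split axes, which is what gives the ensemble its diversity.
#' Predictions are combined by majority vote.
#'
#' Principal components with eigenvalue below 1e-12 are dropped, so the
#' rotated feature count M can be smaller than N for rank-deficient
#' subsets; a subset whose sampled rows are constant falls back to an
#' identity block.  Base learners are unpruned CART trees
#' (\code{rpart} with \code{cp = 0}).
#'
#' Fitting is deterministic: member t draws its feature partition, class
#' subsample and bootstrap from a substream derived from \code{seed} and t,
#' so \code{fit + predict} is a pure function of (x, y, configuration).
#'
#' @param x numeric matrix of samples x features (default method), or a
#'   model formula.
#' @param y class labels (factor or character), one per row of \code{x}.
#' @param ntree ensemble size (number of rotations/trees), default 100.
#' @param subset_size features per PCA subset, default 3.
#' @param class_sample_fraction bootstrap fraction of the selected classes'
#'   rows used to estimate each subset's principal axes, default 0.75.
#' @param seed integer seed controlling all randomness in the fit.
#' @param min_split minimum node size passed to the tree grower.
#' @param max_depth maximum tree depth.
#' @param ... unused (signature compatibility).
#' @return an object of class \code{"rotation_forest"} with components
#'   \code{members} (list of \code{rotation}/\code{tree} pairs),
#'   \code{classes}, \code{feature_count} and \code{config}.
#' @seealso [predict.rotation_forest()], [cross_validate()]
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 3), 50))
#' y <- rep(c("a", "b"), each = 50)
#' fit <- rotation_forest(x, y, ntree = 11, seed = 7)
#' table(predict(fit, x), y)
#' @export
rotation_forest <- function(x, ...) UseMethod("rotation_forest")

#' @rdname rotation_forest
#' @export
rotation_forest.default <- function(x, y, ntree = 100L, subset_size = 3L,
                                    class_sample_fraction = 0.75,
                                    seed = 1L, min_split = 2L,
                                    max_depth = 30L, ...) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be a numeric matrix")
  if (any(!is.finite(x))) stop("'x' contains non-finite values")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (ntree < 1L || subset_size < 1L) {
    stop("ntree and subset_size must be >= 1")
  }
  if (class_sample_fraction <= 0 || class_sample_fraction > 1) {
    stop("class_sample_fraction must be in (0, 1]")
  }
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) {
    stop("rotation forest needs at least 2 classes; got ",
         nlevels(y))
  }
  control <- rpart::rpart.control(minsplit = min_split, cp = 0, xval = 0,
                                  maxcompete = 0, maxsurrogate = 0,
                                  usesurrogate = 0,
                                  maxdepth = max_depth)
  members <- vector("list", ntree)
  for (t in seq_len(ntree)) {
    members[[t]] <- with_seed(derive_seed(seed, t), {
      rot <- build_rotation(x, y, subset_size = subset_size,
                            class_sample_fraction = class_sample_fraction)
      z <- as.data.frame(x %*% rot)
      colnames(z) <- paste0("RC", seq_len(ncol(z)))
      z$.class <- y
      tree <- rpart::rpart(.class ~ ., data = z, method = "class",
                           control = control)
      list(rotation = rot, tree = tree)
    })
  }
  structure(list(members = members,
                 classes = levels(y),
                 feature_count = ncol(x),
                 config = list(ntree = as.integer(ntree),
                               subset_size = as.integer(subset_size),
                               class_sample_fraction = class_sample_fraction,
                               seed = as.integer(seed),
                               min_split = as.integer(min_split),
                               max_depth = as.integer(max_depth))),
            class = "rotation_forest")
}

#' @rdname rotation_forest
#' @param formula a formula of the form \code{label ~ .}.
#' @param data a data.frame holding the label and feature columns.
#' @export
rotation_forest.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  rotation_forest.default(x, y, ...)
}

#' Build one rotation matrix for a Rotation Forest member
#'
#' Partitions the feature indices at random into subsets of
#' \code{subset_size}, and for each subset estimates PCA loadings from a
#' bootstrap (of \code{class_sample_fraction} of the rows) drawn from a
#' random non-empty subset of classes.  Loadings with eigenvalue > 1e-12
#' form the subset's column block; degenerate subsets get an identity
#' block.  Blocks are placed on rows matching their features, so the
#' result is an N x M matrix (M <= N) that is orthonormal within each
#' block.
#'
#' Uses the current RNG state; [rotation_forest()] seeds it per member.
#'
#' @inheritParams rotation_forest.default
#' @return an N x M rotation matrix.
#' @export
build_rotation <- function(x, y, subset_size = 3L,
                           class_sample_fraction = 0.75) {
  x <- as.matrix(x)
  y <- factor(y)
  N <- ncol(x)
  perm <- sample.int(N)
  groups <- split(perm, ceiling(seq_along(perm) / subset_size))
  classes <- levels(y)
  blocks <- lapply(groups, function(g) {
    keep_classes <- classes[stats::runif(length(classes)) < 0.5]
    if (length(keep_classes) == 0L) {
      keep_classes <- classes[sample.int(length(classes), 1L)]
    }
    rows <- which(y %in% keep_classes)
    nb <- max(2L, ceiling(class_sample_fraction * length(rows)))
    boot <- rows[sample.int(length(rows), nb, replace = TRUE)]
    sub <- x[boot, g, drop = FALSE]
    cv <- stats::cov(sub)
    if (any(!is.finite(cv)) || all(abs(cv) < 1e-24)) {
      return(diag(length(g)))
    }
    e <- eigen(cv, symmetric = TRUE)
    keep <- e$values > 1e-12
    if (!any(keep)) return(diag(length(g)))
    e$vectors[, keep, drop = FALSE]
  })
  M <- sum(vapply(blocks, ncol, 0L))
  rot <- matrix(0, N, M)
  col0 <- 0L
  for (b in seq_along(blocks)) {
    nc <- ncol(blocks[[b]])
    rot[groups[[b]], col0 + seq_len(nc)] <- blocks[[b]]
    col0 <- col0 + nc
  }
  rot
}

#' Predict class labels with a Rotation Forest
#'
#' Each member votes with its tree's prediction on its own rotated copy of
#' the data; the plurality label wins, with vote ties broken by the lowest
#' class index in \code{object$classes}.
#'
#' @param object a \code{"rotation_forest"}.
#' @param newdata numeric matrix with \code{object$feature_count} columns.
#' @param type \code{"class"} for labels (default) or \code{"votes"} for
#'   the raw vote-count matrix.
#' @param ... unused.
#' @return a factor of predicted labels, or an n x classes vote matrix.
#' @export
predict.rotation_forest <- function(object, newdata,
                                    type = c("class", "votes"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$feature_count) {
    stop("newdata has ", ncol(newdata), " columns; model expects ",
         object$feature_count)
  }
  classes <- object$classes
  votes <- matrix(0L, nrow(newdata), length(classes),
                  dimnames = list(rownames(newdata), classes))
  for (m in object$members) {
    z <- as.data.frame(newdata %*% m$rotation)
    colnames(z) <- paste0("RC", seq_len(ncol(z)))
    p <- predict(m$tree, z, type = "class")
    idx <- cbind(seq_len(nrow(newdata)), match(as.character(p), classes))
    votes[idx] <- votes[idx] + 1L
  }
  if (type == "votes") return(votes)
  factor(classes[max.col(votes, ties.method = "first")], levels = classes)
}

#' @export
print.rotation_forest <- function(x, ...) {
  ms <- vapply(x$members, function(m) ncol(m$rotation), 0L)
  cat("Rotation Forest: ", length(x$members), " trees, ",
      x$feature_count, " features (rotated M in [", min(ms), ", ", max(ms),
      "]), classes: ", paste(x$classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rotation_forest <- function(object, ...) {
  cfg <- object$config
  cat("Rotation Forest fit\n")
  cat("  trees:                 ", cfg$ntree, "\n")
  cat("  features per subset:   ", cfg$subset_size, "\n")
  cat("  class sample fraction: ", cfg$class_sample_fraction, "\n")
  cat("  seed:                  ", cfg$seed, "\n")
  cat("  classes:               ", paste(object$classes, collapse = ", "),
      "\n")
  cat("  input features (N):    ", object$feature_count, "\n")
  depth <- vapply(object$members, function(m) {
    max(floor(log2(as.integer(rownames(m$tree$frame)))) ) + 1L
  }, 0L)
  cat("  tree depth:             median ", stats::median(depth),
      " (max ", max(depth), ")\n", sep = "")
  invisible(object)
}

#' Save / load a Rotation Forest model archive
#'
#' The archive is a single file holding a versioned schema: the schema tag,
#' the fitting configuration, the class list and every member's rotation
#' matrix and tree.
#'
#' @param model a \code{"rotation_forest"}.
#' @param path archive path.
#' @return \code{write_rotation_forest}: \code{path}, invisibly;
#'   \code{read_rotation_forest}: the restored model.
#' @export
write_rotation_forest <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(list(schema = "pssmloc/rotation_forest/1", model = model), path)
  invisible(path)
}

#' @rdname write_rotation_forest
#' @export
read_rotation_forest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "pssmloc/rotation_forest/1")) {
    stop("'", path, "' is not a rotation-forest archive (schema: ",
         if (is.null(obj$schema)) "none" else obj$schema, ")")
  }
  obj$model
}
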