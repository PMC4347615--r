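## Two well-separated Gaussian blobs per class.
gaussian_classes <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  N <- ncol(centers)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c) {
    matrix(rnorm(n_per * N, mean = rep(centers[c, ], each = n_per), sd = sd),
           n_per, N)
  }))
  list(x = x, y = factor(rep(rownames(centers), each = n_per),
                         levels = rownames(centers)))
}

sep2 <- function(n_per = 100, seed = 1) {
  centers <- rbind(a = rep(0, 10), b = rep(3, 10))
  gaussian_classes(n_per, centers, sd = 1, seed = seed)
}

test_that("a full-width PCA subset yields an orthogonal, distance-preserving rotation", {
  set.seed(10)
  x <- matrix(rnorm(200), 40, 5)
  y <- factor(rep(c("a", "b"), 20))
  rot <- build_rotation(x, y, subset_size = 5, class_sample_fraction = 1)
  expect_equal(dim(rot), c(5L, 5L))
  expect_equal(crossprod(rot), diag(5), tolerance = 1e-9)
  d0 <- dist(x)
  d1 <- dist(x %*% rot)
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
})

test_that("rotation blocks are orthonormal and M never exceeds N", {
  set.seed(11)
  x <- matrix(rnorm(60 * 13), 60, 13)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  for (rep in 1:10) {
    rot <- build_rotation(x, y, subset_size = 3)
    expect_lte(ncol(rot), 13)
    expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-9)
  }
})

test_that("constant subsets fall back to identity blocks", {
  x <- cbind(matrix(rnorm(40), 20, 2), 1, 1, 1) # features 3:5 constant
  y <- factor(rep(c("a", "b"), 10))
  set.seed(12)
  for (rep in 1:5) {
    rot <- build_rotation(x, y, subset_size = 5)
    expect_equal(crossprod(rot), diag(ncol(rot)), tolerance = 1e-9)
    ## rank cannot exceed 3 nonconstant directions + identity fallbacks
    expect_true(all(is.finite(rot)))
  }
})

test_that("duplicated features drop zero-eigenvalue components (M < N)", {
  set.seed(13)
  base <- matrix(rnorm(60), 30, 2)
  x <- cbind(base, base, base) # rank 2 in every 3-subset on average
  y <- factor(rep(c("a", "b"), 15))
  ms <- replicate(10, ncol(build_rotation(x, y, subset_size = 6)))
  expect_true(all(ms <= 6))
  expect_true(any(ms < 6))
})

test_that("training separable classes reaches 100% and is seed-stable", {
  d <- sep2(100, seed = 21)
  fit <- rotation_forest(d$x, d$y, ntree = 25, seed = 1)
  expect_equal(accuracy_Q(predict(fit, d$x), d$y), 100)

  held <- sep2(50, seed = 22)
  p1 <- predict(rotation_forest(d$x, d$y, ntree = 25, seed = 5), held$x)
  p2 <- predict(rotation_forest(d$x, d$y, ntree = 25, seed = 6), held$x)
  expect_gte(mean(p1 == p2) * 100, 95)
})

test_that("fit and predict are deterministic given the seed", {
  d <- sep2(40, seed = 31)
  f1 <- rotation_forest(d$x, d$y, ntree = 7, seed = 99)
  f2 <- rotation_forest(d$x, d$y, ntree = 7, seed = 99)
  held <- sep2(30, seed = 32)
  expect_identical(predict(f1, held$x), predict(f2, held$x))
  expect_equal(f1$members[[3]]$rotation, f2$members[[3]]$rotation)
})

test_that("degenerate inputs are rejected", {
  d <- sep2(20, seed = 41)
  expect_error(rotation_forest(d$x, rep("a", nrow(d$x))), "at least 2 classes")
  bad <- d$x
  bad[1, 1] <- NA
  expect_error(rotation_forest(bad, d$y), "non-finite")
  fit <- rotation_forest(d$x, d$y, ntree = 3, seed = 1)
  expect_error(predict(fit, d$x[, 1:5]), "columns")
})

test_that("a one-tree ensemble equals its single tree and ties break low", {
  d <- sep2(40, seed = 51)
  fit <- rotation_forest(d$x, d$y, ntree = 1, seed = 3)
  m <- fit$members[[1]]
  z <- as.data.frame(d$x %*% m$rotation)
  colnames(z) <- paste0("RC", seq_len(ncol(z)))
  expect_equal(as.character(predict(fit, d$x)),
               as.character(predict(m$tree, z, type = "class")))

  ## synthetic tied vote: 2 votes each with classes ordered (a, b) -> a
  votes <- matrix(c(2L, 2L), 1, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(colnames(votes)[max.col(votes, ties.method = "first")], "a")
  fit4 <- rotation_forest(d$x, d$y, ntree = 4, seed = 8)
  v <- predict(fit4, d$x, type = "votes")
  p <- predict(fit4, d$x)
  firsts <- fit4$classes[max.col(v, ties.method = "first")]
  expect_equal(as.character(p), firsts)
})

test_that("ensemble beats the mean single member on an overlapping problem", {
  centers <- rbind(a = rep(0, 8), b = rep(1.1, 8))
  gains <- vapply(1:10, function(s) {
    train <- gaussian_classes(60, centers, sd = 1, seed = 100 + s)
    test <- gaussian_classes(60, centers, sd = 1, seed = 200 + s)
    fit <- rotation_forest(train$x, train$y, ntree = 15, seed = s)
    ens <- accuracy_Q(predict(fit, test$x), test$y)
    singles <- vapply(fit$members, function(m) {
      z <- as.data.frame(test$x %*% m$rotation)
      colnames(z) <- paste0("RC", seq_len(ncol(z)))
      accuracy_Q(predict(m$tree, z, type = "class"), test$y)
    }, 0)
    ens - mean(singles)
  }, 0)
  expect_gte(mean(gains), 0)
})

test_that("10-fold CV on a separable 3-class problem reaches 95%", {
  centers <- rbind(a = c(rep(4, 7), rep(0, 13)),
                   b = c(rep(0, 7), rep(4, 7), rep(0, 6)),
                   c = c(rep(0, 14), rep(4, 6)))
  d <- gaussian_classes(167, centers, sd = 1, seed = 71)
  n <- nrow(d$x)
  samples <- data.frame(protein_id = sprintf("s%03d", seq_len(n)),
                        label = as.character(d$y),
                        group = sprintf("s%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
  class(samples) <- c("sample_table", "data.frame")
  rep <- cross_validate(samples, d$x, k = 10, seed = 2, ntree = 25)
  expect_gte(rep$overall_Q, 95)
})

test_that("model archives round-trip through the versioned schema", {
  d <- sep2(30, seed = 81)
  fit <- rotation_forest(d$x, d$y, ntree = 3, seed = 1)
  f <- withr::local_tempfile(fileext = ".rds")
  write_rotation_forest(fit, f)
  back <- read_rotation_forest(f)
  expect_identical(predict(back, d$x), predict(fit, d$x))
  saveRDS(list(schema = "something-else"), f)
  expect_error(read_rotation_forest(f), "not a rotation-forest archive")
})
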