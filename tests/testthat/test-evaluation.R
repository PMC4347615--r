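make_samples <- function(n_singles, n_doubles = 0, labels = c("x", "y")) {
  ids <- c(sprintf("s%04d", seq_len(n_singles)),
           sprintf("d%04d", seq_len(n_doubles)))
  lab <- lapply(seq_along(ids), function(i) {
    if (i <= n_singles) sample(labels, 1) else sample(labels, 2)
  })
  expand_manifest(new_manifest(ids, lab, label_universe = labels))
}

test_that("ungrouped samples split into exactly even folds", {
  set.seed(1)
  st <- make_samples(100)
  folds <- kfold_split(st, k = 10, seed = 3)
  expect_equal(as.integer(sort(table(folds))), rep(10L, 10))
})

test_that("duplicated proteins land in the same fold", {
  set.seed(2)
  st <- make_samples(30, n_doubles = 5)
  folds <- kfold_split(st, k = 5, seed = 1)
  for (g in unique(st$group)) {
    expect_length(unique(folds[st$group == g]), 1L)
  }
})

test_that("the 523-sample layout makes folds of 52 or 53", {
  set.seed(3)
  st <- make_samples(515, n_doubles = 4, labels = paste0("l", 1:4))
  expect_equal(nrow(st), 523L)
  folds <- kfold_split(st, k = 10, seed = 7)
  sizes <- as.integer(table(factor(folds, levels = 1:10)))
  expect_equal(sum(sizes), 523L)
  expect_true(all(sizes %in% c(52L, 53L)))
})

test_that("fold assignment is a pure function of (samples, k, seed)", {
  set.seed(4)
  st <- make_samples(40, n_doubles = 3)
  expect_identical(kfold_split(st, 10, seed = 5), kfold_split(st, 10, seed = 5))
  expect_false(identical(kfold_split(st, 10, seed = 5),
                         kfold_split(st, 10, seed = 6)))
  expect_error(kfold_split(st[1:4, ], k = 5), "fewer samples")
})

test_that("accuracy Q is 100 C / N", {
  expect_equal(accuracy_Q(c("a", "b"), c("a", "b")), 100)
  expect_equal(accuracy_Q(c("a", "b"), c("b", "a")), 0)
  expect_equal(accuracy_Q(c("a", "a", "b", "b"), c("a", "a", "b", "a")), 75)
  expect_error(accuracy_Q(character(0), character(0)), "empty")
  expect_error(accuracy_Q("a", c("a", "b")), "equal length")
})

test_that("per-location accuracy counts each true class separately", {
  truth <- c("A", "A", "A", "A", "B", "B")
  pred <- c("A", "A", "A", "B", "B", "B")
  acc <- per_location_accuracy(pred, truth, c("A", "B", "C"))
  expect_equal(unname(acc["A"]), 75)
  expect_equal(unname(acc["B"]), 100)
  expect_true(is.na(acc["C"])) # no samples: undefined, not 0
  perfect <- per_location_accuracy(truth, truth, c("A", "B"))
  expect_equal(unname(perfect), c(100, 100))
})

test_that("cross-validation covers every sample once and conserves counts", {
  spec <- fixture_spec(n_classes = 3, samples_per_class = 12,
                       length_range = c(30, 60), class_signal = 0.6,
                       seed = 11)
  d <- synth_dataset(spec)
  m <- build_feature_matrix(d$pssms, d$samples, synth_attribute_scale(2))
  rep <- cross_validate(d$samples, m, k = 6, seed = 4, ntree = 11)
  expect_length(rep$predictions, nrow(d$samples))
  expect_true(all(nzchar(rep$predictions)))
  expect_equal(sum(rep$confusion), nrow(d$samples))
  expect_equal(rep$overall_Q,
               100 * sum(diag(rep$confusion)) / sum(rep$confusion))
  ## per-location consistency with the confusion matrix
  for (lb in rownames(rep$confusion)) {
    row <- rep$confusion[lb, ]
    if (sum(row) > 0) {
      expect_equal(unname(rep$per_location_Q[lb]),
                   100 * row[[lb]] / sum(row))
    }
  }
})

test_that("CV reports serialize to JSON and survive re-reading", {
  spec <- fixture_spec(n_classes = 2, samples_per_class = 8,
                       length_range = c(25, 40), class_signal = 0.8,
                       seed = 21)
  d <- synth_dataset(spec)
  m <- build_feature_matrix(d$pssms, d$samples, synth_attribute_scale(3))
  rep <- cross_validate(d$samples, m, k = 4, seed = 2, ntree = 5)
  f <- withr::local_tempfile(fileext = ".json")
  write_cv_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$overall_Q, rep$overall_Q)
  expect_equal(back$n, rep$n)
  expect_equal(sum(back$confusion$counts), rep$n)
})

test_that("paired t-test matches the reference implementation", {
  a <- c(81.2, 79.4, 85.1, 83.0, 78.8, 82.5)
  b <- c(79.9, 78.1, 84.7, 80.2, 78.0, 81.1)
  got <- paired_ttest(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$p.value, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)

  d <- c(1, 2, 3, 4, 5)
  got2 <- paired_ttest(d, rep(0, 5))
  ref2 <- t.test(d, rep(0, 5), paired = TRUE)
  expect_equal(got2$p.value, unname(ref2$p.value), tolerance = 1e-9)
})

test_that("paired t-test degenerate and zero-mean cases behave as defined", {
  expect_error(paired_ttest(c(1, 2, 3), c(1, 2, 3) - 2), "degenerate")
  got <- paired_ttest(c(1, -1, 1, -1), rep(0, 4))
  expect_equal(got$statistic, 0)
  expect_equal(got$p.value, 1)
})
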