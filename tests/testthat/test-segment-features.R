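test_that("segment boundaries follow the floor-and-clamp length rule", {
  expect_equal(segment_boundary(rep(0.5, 100), 5), 5L)
  expect_equal(segment_boundary(rep(0.5, 10), 5), 1L) # floor(0.5) clamps to 1
  expect_equal(segment_boundary(rep(0.5, 137), 75), floor(0.75 * 137))
  expect_error(segment_boundary(rep(0.5, 10), 0), "percent")
  expect_error(segment_boundary(rep(0.5, 10), 100), "percent")
})

test_that("mass-fraction boundaries follow the cumulative-sum scan", {
  v <- rep(0.3, 10)
  expect_equal(segment_boundary(v, 50, mode = "mass_fraction"), 5L)
  ## front-loaded mass reaches 50% after a single residue
  w <- c(10, rep(0.1, 9))
  expect_equal(segment_boundary(w, 50, mode = "mass_fraction"), 1L)
  ## from the right the same mass needs almost the whole sequence
  expect_equal(segment_boundary(w, 50, side = "right",
                                mode = "mass_fraction"), 10L)
  ## independent cumulative-scan oracle on random values
  set.seed(3)
  for (rep in 1:10) {
    x <- runif(sample(5:80, 1))
    d <- sample(c(10, 30, 50, 70), 1)
    cum <- 0
    expected <- length(x)
    for (i in seq_along(x)) {
      cum <- cum + x[i]
      if (cum >= d / 100 * sum(x)) { expected <- i; break }
    }
    expect_equal(segment_boundary(x, d, mode = "mass_fraction"), expected)
  }
})

test_that("global density is the mean attribute value", {
  expect_equal(global_density(rep(1, 7)), 1)
  expect_equal(global_density(c(0.2, 0.4, 0.6)), 0.4)
  r <- random_attr_seq(200, seed = 55)
  expect_equal(global_density(r), oracle_global_density(r),
               tolerance = 1e-12)
})

test_that("OSD on an all-ones length-100 sequence gives exact prefix sums", {
  f <- osd_features(rep(1, 100))
  expect_length(f, 31)
  expect_equal(unname(f[1]), 1) # global density
  expect_equal(unname(f[2:16]), seq(5, 75, by = 5))
  expect_equal(unname(f[17:31]), seq(5, 75, by = 5))
})

test_that("OSD right block equals the left block of the reversed sequence", {
  r <- random_attr_seq(83, seed = 12)
  f <- osd_features(r)
  g <- osd_features(rev(r))
  expect_equal(unname(f[17:31]), unname(g[2:16]), tolerance = 1e-12)
})

test_that("OSD matches the brute-force prefix-sum oracle", {
  for (seed in 1:10) {
    L <- c(2, 3, 7, 19, 50, 137, 200, 311, 400, 500)[seed]
    r <- random_attr_seq(L, seed = 1000 + seed)
    expect_equal(unname(osd_features(r)), oracle_osd(r), tolerance = 1e-12)
  }
})

test_that("OSA on an all-ones sequence is 1 wherever the lag fits", {
  f <- osa_features(rep(1, 100))
  expect_length(f, 150)
  expect_true(all(f %in% c(0, 1)))
  ## at L = 100 the 10% segment holds 10 residues: lags 1..9 defined, lag 10 not
  expect_equal(unname(f[1:9]), rep(1, 9))
  expect_equal(unname(f[10]), 0)
  expect_equal(unname(f[141:150]), rep(1, 10)) # global block, L - 10 > 0
})

test_that("OSA short segments yield zero coefficients by rule", {
  r <- rep(0.8, 5) # 10% segment boundary clamps to 1 residue -> all lags 0
  f <- osa_features(r)
  expect_equal(unname(f[1:10]), rep(0, 10))
})

test_that("OSA matches the double-loop brute-force oracle", {
  for (seed in 1:8) {
    L <- c(2, 5, 13, 60, 101, 250, 399, 500)[seed]
    r <- random_attr_seq(L, seed = 2000 + seed)
    expect_equal(unname(osa_features(r)), oracle_osa(r), tolerance = 1e-12)
  }
})

test_that("OSD scales linearly and OSA quadratically in the attribute values", {
  r <- random_attr_seq(90, seed = 31)
  c0 <- 2.5
  expect_equal(unname(osd_features(r * c0))[-1],
               unname(osd_features(r))[-1] * c0, tolerance = 1e-12)
  expect_equal(unname(osd_features(r * c0))[1],
               unname(osd_features(r))[1] * c0, tolerance = 1e-12)
  expect_equal(unname(osa_features(r * c0)),
               unname(osa_features(r)) * c0^2, tolerance = 1e-12)
})

test_that("OSA right block reflects the reversed sequence", {
  r <- random_attr_seq(64, seed = 77)
  f <- osa_features(r)
  g <- osa_features(rev(r))
  expect_equal(unname(f[71:140]), unname(g[1:70]), tolerance = 1e-12)
})

test_that("feature counts track the segmentation configuration", {
  cfg <- seg_config(osd_step = 10, osd_max = 70, osa_step = 20, osa_max = 60,
                    distance_factor = 4)
  r <- random_attr_seq(40, seed = 5)
  expect_length(osd_features(r, cfg), 1 + 2 * 7)
  expect_length(osa_features(r, cfg), (3 + 3 + 1) * 4)
})

test_that("seg_config validates its invariants", {
  expect_error(seg_config(osd_step = 7), "divide")
  expect_error(seg_config(osa_max = 100), "below 100")
  expect_error(seg_config(distance_factor = 0), ">= 1")
})

test_that("length-normalized OSD divides each segment sum by its length", {
  r <- random_attr_seq(120, seed = 8)
  cfg <- seg_config(osd_normalize = TRUE)
  f <- osd_features(r, cfg)
  raw <- osd_features(r)
  ds <- seq(5, 75, by = 5)
  for (q in seq_along(ds)) {
    b <- oracle_boundary_length(120, ds[q])
    expect_equal(unname(f[1 + q]), unname(raw[1 + q]) / b, tolerance = 1e-12)
  }
})
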