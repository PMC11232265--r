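# Spatial-mean-attention fusion layer: weight normalization, convexity,
# symmetry and agreement with the per-pixel formula oracle.

test_that("identical sources get uniform weights and a fixed point", {
  f <- array(runif(8 * 6 * 4), c(8, 6, 4))
  w <- compute_weight_maps(list(f, f))
  expect_lt(max(abs(w - 0.5)), 1e-6)
  fused <- fuse_features(list(f, f), w)
  expect_lt(max(abs(fused - f)), 1e-12)
})

test_that("weights follow the normalized channel means", {
  # Q1 = 3, Q2 = 1 at every pixel forces weights 0.75 / 0.25
  f1 <- array(3, c(8, 8, 5)); f2 <- array(1, c(8, 8, 5))
  w <- compute_weight_maps(list(f1, f2), epsilon = 0)
  expect_equal(max(abs(w[, , 1] - 0.75)), 0, tolerance = 1e-12)
  expect_equal(max(abs(w[, , 2] - 0.25)), 0, tolerance = 1e-12)
})

test_that("degenerate weights select a single source exactly", {
  f1 <- array(runif(6 * 6 * 3), c(6, 6, 3))
  f2 <- array(runif(6 * 6 * 3), c(6, 6, 3))
  w <- array(c(rep(1, 36), rep(0, 36)), c(6, 6, 2))
  expect_identical(fuse_features(list(f1, f2), w), f1)
})

test_that("weight maps and fusion match the per-pixel oracle", {
  set.seed(10)
  feats <- list(array(runif(8 * 4 * 4), c(4, 4, 8)),
                array(runif(8 * 4 * 4), c(4, 4, 8)))
  got_w <- compute_weight_maps(feats, epsilon = 0)
  want_w <- oracle_weight_maps(feats)
  expect_lt(max(abs(got_w - want_w)), 1e-6)
  expect_lt(max(abs(apply(got_w, c(1, 2), sum) - 1)), 1e-6)
  got_f <- fuse_features(feats, got_w)
  expect_lt(max(abs(got_f - oracle_fuse(feats, want_w))), 1e-6)
})

test_that("fusion invariants hold across seeded trials", {
  for (trial in 1:25) {
    set.seed(trial)
    d <- c(sample(4:9, 1), sample(4:9, 1), sample(2:6, 1))
    feats <- list(array(runif(prod(d)), d), array(runif(prod(d)), d))
    w <- compute_weight_maps(feats)
    # normalization
    expect_lt(max(abs(apply(w, c(1, 2), sum) - 1)), 1e-6)
    expect_true(all(w >= 0 & w <= 1))
    # convex envelope
    fused <- fuse_features(feats, w)
    lo <- pmin(feats[[1]], feats[[2]]); hi <- pmax(feats[[1]], feats[[2]])
    expect_true(all(fused >= lo - 1e-9 & fused <= hi + 1e-9))
    # permutation equivariance
    w_sw <- compute_weight_maps(feats[2:1])
    expect_equal(w_sw[, , 1], w[, , 2], tolerance = 1e-12)
    expect_lt(max(abs(fuse_features(feats[2:1], w_sw) - fused)), 1e-9)
    # scale covariance: scaling source 1 weakly increases its weight
    w_up <- compute_weight_maps(list(feats[[1]] * 2, feats[[2]]))
    expect_true(all(w_up[, , 1] >= w[, , 1] - 1e-9))
  }
})

test_that("all-zero pixels fall back to uniform weights", {
  f1 <- array(0, c(4, 4, 2)); f2 <- array(0, c(4, 4, 2))
  f1[1, 1, ] <- 1
  w <- compute_weight_maps(list(f1, f2))
  expect_equal(w[2, 2, 1], 0.5, tolerance = 1e-12)
  expect_gt(w[1, 1, 1], 0.99)
})

test_that("negative features warn and are clamped", {
  f1 <- array(runif(4 * 4 * 2), c(4, 4, 2)); f2 <- f1
  f1[1, 1, 1] <- -1
  expect_warning(w <- compute_weight_maps(list(f1, f2)), "negative")
  expect_true(all(w >= 0 & w <= 1))
})

test_that("shape mismatches are rejected", {
  f1 <- array(0.5, c(4, 4, 2)); f2 <- array(0.5, c(4, 5, 2))
  expect_error(compute_weight_maps(list(f1, f2)), "shape")
  w <- compute_weight_maps(list(f1, f1))
  expect_error(fuse_features(list(f1, f2), w), "shape")
})

test_that("the strategy registry exposes the three fusion rules", {
  expect_setequal(fusion_strategies(),
                  c("mean_attention", "addition", "average"))
  f1 <- array(runif(4 * 4 * 2), c(4, 4, 2))
  f2 <- array(runif(4 * 4 * 2), c(4, 4, 2))
  expect_equal(apply_fusion_strategy(list(f1, f2), "addition"), f1 + f2)
  expect_equal(apply_fusion_strategy(list(f1, f2), "average"), (f1 + f2) / 2)
  expect_equal(apply_fusion_strategy(list(f1, f2), "mean_attention"),
               fuse_features(list(f1, f2), compute_weight_maps(list(f1, f2))))
})

test_that("softmax mode and local windows stay normalized", {
  f1 <- array(runif(6 * 6 * 3), c(6, 6, 3))
  f2 <- array(runif(6 * 6 * 3), c(6, 6, 3))
  for (w in list(compute_weight_maps(list(f1, f2), weight_mode = "softmax"),
                 compute_weight_maps(list(f1, f2), local_window = 3))) {
    expect_lt(max(abs(apply(w, c(1, 2), sum) - 1)), 1e-6)
    expect_true(all(w >= 0 & w <= 1))
  }
})
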