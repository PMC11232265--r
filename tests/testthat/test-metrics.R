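# The eight fusion-quality metrics against closed-form values and
# independent loop-based oracles, plus the paired t-test utility.

test_that("closed-form spot checks hold", {
  m <- matrix(c(0, 0, 1, 1), 2, 2)    # [[0,1],[0,1]] in row notation
  expect_equal(average_gradient(m), sqrt(0.5), tolerance = 1e-12)
  sf <- spatial_frequency(m, components = TRUE)
  expect_equal(unname(sf["rf"]), sqrt(2 / 4), tolerance = 1e-12)
  expect_equal(unname(sf["cf"]), 0, tolerance = 1e-12)
  expect_equal(unname(sf["sf"]), sqrt(0.5), tolerance = 1e-12)

  expect_equal(average_gradient(matrix(0.7, 8, 8)), 0)
  expect_equal(spatial_frequency(matrix(0.7, 8, 8)), 0)

  half <- matrix(c(rep(0, 32), rep(1, 32)), 8, 8)
  expect_equal(image_entropy(half), 1, tolerance = 1e-12)
  expect_equal(image_entropy(matrix(0.3, 8, 8)), 0)
  uniform <- matrix((0:255) / 255, 16, 16)
  expect_equal(image_entropy(uniform), 8, tolerance = 1e-12)

  f <- structured_image(16, 1)
  f <- f * 0.9                       # leave room for the +0.1 source
  expect_equal(psnr(f, f, f + 0.1, peak = "full_scale"),
               10 * log10(1 / 0.005), tolerance = 1e-9)
  expect_equal(round(psnr(f, f, f + 0.1, peak = "full_scale"), 4), 23.0103)
  expect_identical(psnr(f, f, f), Inf)
})

test_that("AG, SF, EN, MI match the brute-force oracles", {
  set.seed(21)
  for (trial in 1:3) {
    x <- matrix(runif(16 * 16), 16, 16)
    y <- matrix(runif(16 * 16), 16, 16)
    z <- (x + y) / 2
    expect_equal(average_gradient(x), oracle_ag(x), tolerance = 1e-9)
    expect_equal(spatial_frequency(x), oracle_sf(x), tolerance = 1e-9)
    expect_equal(image_entropy(x), oracle_en(x), tolerance = 1e-9)
    expect_equal(mutual_information(z, x, y),
                 oracle_mi_pair(x, z) + oracle_mi_pair(y, z),
                 tolerance = 1e-9)
    expect_equal(mutual_information(z, x, y, mode = "pair_literal"),
                 oracle_mi_pair(x, y), tolerance = 1e-9)
    expect_equal(psnr(z, x, y), oracle_psnr(z, x, y, max(z)),
                 tolerance = 1e-6)
  }
})

test_that("SSIM, Qabf and VIFF match their reference evaluations", {
  set.seed(22)
  x <- structured_image(16, 31)
  y <- structured_image(16, 32)
  z <- pmin((x + y) / 2 + 0.05, 1)
  expect_equal(ssim_fusion(z, x, y),
               (oracle_ssim(x, z) + oracle_ssim(y, z)) / 2,
               tolerance = 1e-6)
  expect_equal(qabf(z, x, y), oracle_qabf(z, x, y), tolerance = 1e-6)

  a <- structured_image(32, 33)
  b <- structured_image(32, 34)
  fz <- (a + b) / 2
  expect_equal(viff(fz, a, b), oracle_viff(fz, a, b), tolerance = 1e-6)
})

test_that("self-fusion is perfect and degradations are detected", {
  x <- structured_image(64, 23)
  expect_equal(ssim_fusion(x, x, x), 1, tolerance = 1e-12)
  expect_gt(qabf(x, x, x), 0.95)
  v <- viff(x, x, x)
  expect_gt(v, 0.95); expect_lt(v, 1.05)
  # a flat fused image preserves no edges
  expect_lt(qabf(matrix(0.5, 64, 64), x, x), 0.05)
  # blur destroys visual information
  blurred <- res2fuse:::gaussian_smooth(x, 3)
  expect_lt(viff(blurred, x, x), viff(x, x, x))
  # inverting a structured image flips structure
  expect_lt(ssim_fusion(1 - x, x, x), ssim_fusion(x, x, x))
  # additive noise lowers ssim and qabf monotonically
  set.seed(24)
  noisy1 <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, 0.05), 64), 0), 1)
  noisy2 <- pmin(pmax(x + matrix(rnorm(64 * 64, 0, 0.15), 64), 0), 1)
  expect_gt(ssim_fusion(noisy1, x, x), ssim_fusion(noisy2, x, x))
  expect_gt(qabf(noisy1, x, x), qabf(noisy2, x, x))
  expect_lt(ssim_fusion(noisy1, x, x), 1)
})

test_that("metric symmetries and bounds hold", {
  set.seed(25)
  x <- matrix(runif(12 * 15), 12, 15)
  sf <- spatial_frequency(x, components = TRUE)
  sft <- spatial_frequency(t(x), components = TRUE)
  expect_equal(unname(sf["rf"]), unname(sft["cf"]), tolerance = 1e-12)
  expect_equal(unname(sf["sf"]), unname(sft["sf"]), tolerance = 1e-12)
  # intensity translation: AG/SF exactly invariant
  expect_equal(average_gradient(x * 0.5), average_gradient(x * 0.5 + 0.2),
               tolerance = 1e-12)
  expect_equal(spatial_frequency(x * 0.5), spatial_frequency(x * 0.5 + 0.2),
               tolerance = 1e-12)
  # EN bounded by log2(levels)
  expect_lte(image_entropy(x, levels = 16), 4)
  # MI is symmetric in the sources and each pair term non-negative
  a <- structured_image(16, 3); b <- structured_image(16, 4)
  f <- (a + b) / 2
  expect_equal(mutual_information(f, a, b), mutual_information(f, b, a),
               tolerance = 1e-12)
  expect_gte(mutual_information(f, a, a), 0)
  # qabf and viff are symmetric in the sources
  expect_equal(qabf(f, a, b), qabf(f, b, a), tolerance = 1e-12)
  a32 <- structured_image(32, 5); b32 <- structured_image(32, 6)
  f32 <- (a32 + b32) / 2
  expect_equal(viff(f32, a32, b32), viff(f32, b32, a32), tolerance = 1e-12)
  # literal pair MI of an image with itself is its entropy
  expect_equal(mutual_information(f, a, a, mode = "pair_literal"),
               image_entropy(a), tolerance = 1e-9)
})

test_that("pair-literal MI of independent images shrinks with size", {
  # histogram MI estimation is biased by (levels^2 - 1) / (2 N ln 2);
  # at 32 shared levels and 256x256 pixels the bias is ~0.01 bits
  set.seed(26)
  a <- matrix(runif(256 * 256), 256, 256)
  b <- matrix(runif(256 * 256), 256, 256)
  expect_lt(mutual_information(b, a, b, mode = "pair_literal", levels = 32),
            0.05)
})

test_that("report, table and t-test utilities behave", {
  set.seed(27)
  triples <- lapply(1:3, function(i) {
    a <- structured_image(32, i)
    b <- structured_image(32, i + 10)
    list(f = fusion_image(pmin((a + b) / 2, 1)),
         a = fusion_image(a), b = fusion_image(b))
  })
  tab <- evaluate_batch(triples)
  expect_identical(nrow(tab), 4L)
  expect_identical(colnames(tab),
                   c("ag", "sf", "en", "mi", "psnr", "ssim", "qabf", "viff"))
  expect_equal(unname(unlist(tab["mean", ])),
               unname(colMeans(tab[1:3, ])), tolerance = 1e-9)
  expect_error(evaluate_batch(list()), "empty")

  x <- c(1, 2, 3, 4, 5)
  expect_warning(tt <- paired_t_test(x, x), "zero-variance")
  expect_identical(tt$t, 0); expect_identical(tt$p, 1)
  expect_warning(tt2 <- paired_t_test(x + 1, x), "zero-variance")
  expect_lt(tt2$p, 0.01)
  set.seed(28)
  u <- rnorm(10); v <- rnorm(10)
  got <- paired_t_test(u, v); want <- oracle_paired_t(u, v)
  expect_equal(got$t, want$t, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)
  expect_error(paired_t_test(1, 1), "length")
})

test_that("undersized images are rejected", {
  expect_error(average_gradient(matrix(1, 1, 5)), "size")
  expect_error(spatial_frequency(matrix(1, 1, 5)), "size")
  expect_error(viff(matrix(0.5, 16, 16), matrix(0.5, 16, 16),
                    matrix(0.5, 16, 16)), "size")
  expect_error(psnr(matrix(0, 8, 8), matrix(0, 8, 9), matrix(0, 8, 8)),
               "shape")
})
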