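test_that("gaussian_blur preserves constants and smooths", {
  m <- matrix(7, 12, 12)
  expect_equal(gaussian_blur(m, 1.5), m, tolerance = 1e-12)
  expect_identical(gaussian_blur(m, 0), m)
  withr::with_seed(1, z <- matrix(rnorm(400), 20, 20))
  expect_lt(stats::var(as.vector(gaussian_blur(z, 2))),
            stats::var(as.vector(z)))
})

test_that("the scale space has the expected layer structure", {
  img <- generate_fixture(fixture_spec("smooth_noise", 128, 128, seed = 2))
  pyr <- gaussian_scale_space(img, octaves = 2, scales_per_octave = 3,
                              sigma0 = 1.2)
  expect_s3_class(pyr, "sift_pyramid")
  expect_length(pyr, 2)
  expect_length(pyr[[1]]$gaussians, 6)  # s + 3
  expect_length(pyr[[1]]$dogs, 5)       # s + 2
  expect_identical(dim(pyr[[2]]$gaussians[[1]]), c(64L, 64L))
  expect_equal(pyr[[2]]$factor, 2)
  # sigma doubles across an octave at the decimation level
  expect_equal(pyr[[1]]$sigmas[4], 2 * pyr[[1]]$sigmas[1])
})

test_that("octave count is reduced with a warning on small images", {
  img <- matrix(withr::with_seed(3, runif(32 * 32)), 32, 32)
  expect_warning(gaussian_scale_space(img, octaves = 4), "too small")
})

test_that("a strict extremum is required against all 26 neighbours", {
  below <- matrix(0, 5, 5); above <- matrix(0, 5, 5)
  mid <- matrix(0, 5, 5); mid[3, 3] <- 1
  msk <- medsrr:::extremum_mask(below, mid, above)
  expect_true(msk[3, 3])
  expect_equal(sum(msk), 1)
  above[3, 3] <- 1  # tie with the layer above: no longer strict
  expect_false(any(medsrr:::extremum_mask(below, mid, above)))
})

test_that("an isolated blob yields a keypoint at its centre", {
  ii <- matrix(rep(0:63, 64), 64, 64)
  jj <- t(ii)
  img <- 200 * exp(-((ii - 31)^2 + (jj - 31)^2) / (2 * 2.5^2))
  pyr <- gaussian_scale_space(img, octaves = 1, sigma0 = 1.2)
  kp <- detect_keypoints(pyr, contrast_threshold = 0.02)
  expect_gt(nrow(kp), 0)
  best <- kp[which.max(abs(kp$response)), ]
  expect_lt(abs(best$row - 32), 2.5)
  expect_lt(abs(best$col - 32), 2.5)
})

test_that("descriptors are 128-dimensional unit vectors", {
  img <- generate_fixture(fixture_spec("smooth_noise", 96, 96, seed = 6))
  fs <- test_sift(img, "noise")
  expect_s3_class(fs, "feature_set")
  expect_gt(nrow(fs$descriptors), 0)
  expect_identical(ncol(fs$descriptors), 128L)
  nrms <- sqrt(rowSums(fs$descriptors^2))
  expect_equal(nrms, rep(1, length(nrms)), tolerance = 1e-12)
  # nonnegative; individual entries may exceed the 0.2 clamp slightly
  # because the vector is renormalized after clamping
  expect_true(all(fs$descriptors >= 0 & fs$descriptors < 1))
  expect_identical(nrow(fs$keypoints), nrow(fs$descriptors))
  expect_true(all(fs$keypoints$orientation >= 0 &
                  fs$keypoints$orientation < 360))
})

test_that("identical images produce identical feature sets", {
  img <- generate_fixture(fixture_spec("smooth_noise", 96, 96, seed = 7))
  a <- test_sift(img, "a")
  b <- test_sift(img + 0, "b")
  expect_identical(a$descriptors, b$descriptors)
  expect_equal(sift_distance(a, b), 0)
})

test_that("featureless images give empty feature sets, not errors", {
  fs <- test_sift(matrix(128, 96, 96), "flat")
  expect_identical(nrow(fs$descriptors), 0L)
  expect_identical(ncol(fs$descriptors), 128L)
})
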