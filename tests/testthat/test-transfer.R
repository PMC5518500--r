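unit_rows <- function(m) m / sqrt(rowSums(m^2))

test_that("sift_distance equals a brute-force double loop", {
  withr::with_seed(21, {
    s <- matrix(runif(6 * 128), 6)
    t <- matrix(runif(9 * 128), 9)
  })
  brute <- mean(vapply(seq_len(nrow(s)), function(i) {
    min(vapply(seq_len(nrow(t)),
               function(j) sqrt(sum((s[i, ] - t[j, ])^2)), numeric(1)))
  }, numeric(1)))
  expect_equal(sift_distance(s, t), brute, tolerance = 1e-12)
})

test_that("sift_distance is zero on itself and not symmetric in general", {
  withr::with_seed(22, s <- matrix(runif(5 * 128), 5))
  expect_equal(sift_distance(s, s), 0)
  t <- s[1:2, , drop = FALSE]
  expect_equal(sift_distance(t, s), 0)   # subset: every row has an exact match
  expect_gt(sift_distance(s, t), 0)      # superset against subset does not
  expect_error(sift_distance(matrix(numeric(), 0, 128), s), "empty")
})

test_that("match_features applies the nearest-neighbour ratio test", {
  withr::with_seed(23, t <- unit_rows(matrix(runif(8 * 128), 8)))
  # exact copies match their own row: d1 = 0 beats any second neighbour
  expect_identical(match_features(t, t), 1:8)
  # one reference feature: second neighbour is infinite, so it always matches
  expect_identical(match_features(t[1:3, ], t[1, , drop = FALSE]),
                   rep(1L, 3))
  # two equidistant references tie: the ratio test rejects everything
  refs <- rbind(c(1, rep(0, 127)), c(-1, rep(0, 127)))
  cand <- matrix(c(0, 1, rep(0, 126)), 1)
  expect_identical(match_features(cand, refs), NA_integer_)
})

test_that("match_ratio counts matched candidate features", {
  withr::with_seed(24, t <- unit_rows(matrix(runif(10 * 128), 10)))
  expect_equal(match_ratio(t, t), 1)
  half <- rbind(t[1:5, ], unit_rows(matrix(runif(5 * 128) + 10, 5)))
  eta <- match_ratio(half, t)
  expect_gte(eta, 0.5)
  expect_error(match_ratio(matrix(numeric(), 0, 128), t), "empty")
  # a custom match rule overrides the default
  expect_equal(match_ratio(t, t, match_rule = function(S, T)
    rep(NA_integer_, nrow(S))), 0)
})

test_that("select_candidates admits by eta >= D and flags empty candidates", {
  withr::with_seed(25, ref <- unit_rows(matrix(runif(12 * 128), 12)))
  related <- ref[1:6, ]                             # D = 0, eta = 1
  unrelated <- unit_rows(matrix(runif(6 * 128) + 5, 6))  # D large, eta ~ 0
  empty <- matrix(numeric(), 0, 128)
  dec <- select_candidates(list(a = related, b = unrelated, c = empty),
                           list(ref))
  expect_identical(dec$candidate_id, c("1", "2", "3"))
  expect_identical(dec$admitted, c(TRUE, FALSE, FALSE))
  expect_identical(dec$flagged, c(FALSE, FALSE, TRUE))
  expect_equal(dec$D[1], 0)
  expect_equal(dec$eta[1], 1)
  expect_identical(dec$n_features, c(6L, 6L, 0L))
})

test_that("D is the minimum and eta the maximum over references", {
  withr::with_seed(26, {
    far <- unit_rows(matrix(runif(8 * 128) + 3, 8))
    near <- unit_rows(matrix(runif(8 * 128), 8))
  })
  cand <- near[1:4, ]
  dec <- select_candidates(list(cand), list(far, near))
  expect_equal(dec$D, sift_distance(cand, near))   # min over refs
  expect_equal(dec$eta, 1)                         # max over refs
})

test_that("eta_min and d_max overrides tighten admission", {
  withr::with_seed(27, ref <- unit_rows(matrix(runif(6 * 128), 6)))
  dec <- select_candidates(list(ref), list(ref), eta_min = 1.5)
  expect_false(dec$admitted)
  dec2 <- select_candidates(list(ref), list(ref), d_max = -1)
  expect_false(dec2$admitted)
})

test_that("zero-feature references are dropped; all-empty references error", {
  withr::with_seed(28, ref <- unit_rows(matrix(runif(6 * 128), 6)))
  empty <- matrix(numeric(), 0, 128)
  dec <- select_candidates(list(ref), list(empty, ref))
  expect_true(dec$admitted)
  expect_error(select_candidates(list(ref), list(empty)), "zero SIFT features")
})

test_that("tile_crops covers the image with boxed crops", {
  img <- matrix(1:(20 * 16), 20, 16)
  crops <- tile_crops(img, size = 8, stride = 8)
  expect_length(crops, 3 * 2)
  expect_identical(attr(crops[[1]], "box"), c(0, 0, 8, 8))
  expect_identical(dim(crops[[1]]), c(8L, 8L))
  # stride that does not divide evenly still reaches the far edge
  crops2 <- tile_crops(img, size = 8, stride = 5)
  boxes <- vapply(crops2, function(cr) attr(cr, "box")[3], numeric(1))
  expect_true(any(boxes == 20))
  expect_length(tile_crops(img, size = 32), 0)
})
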