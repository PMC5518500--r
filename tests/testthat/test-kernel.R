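test_that("cubic_kernel matches the closed form at eighth arguments", {
  # S(0) = 1, and the eighth-grid values that build the kernel vectors
  expect_equal(cubic_kernel(0, 1)$numerator, 512)
  expect_equal(cubic_kernel(0, 1)$denominator, 512)
  expect_equal(cubic_kernel(1, 8)$numerator, 497)
  expect_equal(cubic_kernel(3, 8)$numerator, 395)
  expect_equal(cubic_kernel(5, 8)$numerator, 237)
  expect_equal(cubic_kernel(7, 8)$numerator, 71)
  expect_equal(cubic_kernel(9, 8)$numerator, -49)
  expect_equal(cubic_kernel(11, 8)$numerator, -75)
  expect_equal(cubic_kernel(13, 8)$numerator, -45)
  expect_equal(cubic_kernel(15, 8)$numerator, -7)
  # S(1) = 0 on the second branch, S(omega >= 2) = 0
  expect_equal(cubic_kernel(8, 8)$numerator, 0)
  expect_equal(cubic_kernel(2, 1)$numerator, 0)
  expect_equal(cubic_kernel(37, 8)$numerator, 0)
})

test_that("cubic_kernel agrees with floating-point evaluation on a grid", {
  s_float <- function(w) {
    if (w < 1) 1 - 2 * w^2 + w^3
    else if (w < 2) 4 - 8 * w + 5 * w^2 - w^3
    else 0
  }
  for (num in 0:32) {
    kw <- cubic_kernel(num, 16)
    expect_equal(kw$numerator / kw$denominator, s_float(num / 16),
                 tolerance = 1e-14)
  }
})

test_that("cubic_kernel reduces non-dyadic denominators exactly", {
  kw <- cubic_kernel(1, 3)   # S(1/3) = 22/27
  expect_equal(kw$numerator, 22)
  expect_equal(kw$denominator, 27)
  kw <- cubic_kernel(1, 2)   # S(1/2) = 5/8 = 320/512
  expect_equal(kw$numerator, 320)
  expect_equal(kw$denominator, 512)
})

test_that("cubic_kernel rejects invalid arguments", {
  expect_error(cubic_kernel(-1, 8), "nonnegative")
  expect_error(cubic_kernel(1.5, 8), "integer")
  expect_error(cubic_kernel(1, 0), "den >= 1")
})

test_that("kernel vectors sum to 512 (1D partition of unity)", {
  for (num8 in c(1, 3, 5, 7)) {
    v <- medsrr:::kernel_vector(num8)
    expect_length(v, 4)
    expect_equal(sum(v), 512)
  }
  expect_equal(medsrr:::kernel_vector(1), c(-49, 497, 71, -7))
  expect_equal(medsrr:::kernel_vector(7), c(-7, 71, 497, -49))
})

test_that("derive_template is the outer product of kernel vectors", {
  tm <- derive_template(1 / 8, 3 / 8)
  V <- medsrr:::kernel_vector(3)  # row weights from v
  U <- medsrr:::kernel_vector(1)  # column weights from u
  expect_identical(tm$numerators, outer(V, U))
  expect_equal(tm$denominator, 2^18)
  expect_error(derive_template(1 / 5, 1 / 8), "denominator")
  expect_error(derive_template(0, 1 / 8), "inside")
  expect_error(derive_template(1 / 8, 1), "inside")
})

test_that("the bank enumerates (v, u) v-major over the quarter midpoints", {
  mids <- c(1, 3, 5, 7) / 8
  expect_s3_class(test_bank, "template_bank")
  expect_length(test_bank$templates, 16)
  for (k in 1:16) {
    tm <- test_bank$templates[[k]]
    expect_identical(tm$index, k)
    expect_equal(tm$v, mids[(k - 1) %/% 4 + 1])
    expect_equal(tm$u, mids[(k - 1) %% 4 + 1])
  }
  expect_equal(test_bank$templates[[1]]$numerators[1, 1], 2401)
  expect_equal(test_bank$templates[[1]]$numerators[2, 2], 247009)
})

test_that("every template sums to 2^18 and pairings hold", {
  for (k in 1:16) {
    expect_equal(sum(test_bank$templates[[k]]$numerators), 2^18)
  }
  # swapping u and v transposes the stencil
  idx <- function(u8, v8) ((v8 - 1) %/% 2) * 4 + ((u8 - 1) %/% 2) + 1
  for (u8 in c(1, 3, 5, 7)) for (v8 in c(1, 3, 5, 7)) {
    expect_identical(test_bank$templates[[idx(u8, v8)]]$numerators,
                     t(test_bank$templates[[idx(v8, u8)]]$numerators))
  }
  # point reflection of the subcell (u -> 1-u, v -> 1-v) rotates it 180 deg
  rot180 <- function(m) m[4:1, 4:1]
  for (k in 1:16) {
    a <- (k - 1) %/% 4; b <- (k - 1) %% 4
    k2 <- (3 - a) * 4 + (3 - b) + 1
    expect_identical(test_bank$templates[[k]]$numerators,
                     rot180(test_bank$templates[[k2]]$numerators))
  }
})

test_that("verification against the printed table finds the two known typos", {
  mism <- verify_against_printed(test_bank)
  expect_identical(nrow(mism), 2L)
  expect_equal(mism$template, c(7, 11))
  expect_equal(mism[mism$template == 7, c("row", "col")],
               data.frame(row = 4L, col = 1L), ignore_attr = TRUE)
  expect_equal(mism[mism$template == 11, c("row", "col")],
               data.frame(row = 1L, col = 1L), ignore_attr = TRUE)
  expect_true(all(mism$derived == 2025))
  expect_true(all(mism$printed == 2205))
})

test_that("a clean subset of the printed table verifies with no mismatches", {
  printed <- printed_template_table()[c("T1", "T6", "T16")]
  expect_identical(nrow(verify_against_printed(test_bank, printed)), 0L)
})

test_that("template bank serializes to JSON and round-trips", {
  path <- withr::local_tempfile(fileext = ".json")
  write_template_bank(test_bank, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$denominator, 2^18)
  expect_equal(nrow(obj$templates), 16)
  expect_equal(obj$templates$u[1], "1/8")
  expect_equal(obj$templates$v[16], "7/8")
  t1 <- obj$templates$numerators[[1]]
  if (is.list(t1)) t1 <- do.call(rbind, t1)
  expect_equal(t1, test_bank$templates[[1]]$numerators, ignore_attr = TRUE)
})
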