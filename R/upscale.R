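#' Upscale an image x4 with the fixed bicubic template layer
#'
#' Applies the 16 integer bicubic templates as a fixed convolutional layer:
#' output pixel `(4i + a, 4j + b)` (0-based, `a, b` in `0..3`) is the 4x4
#' input neighbourhood anchored at `(i, j)` (rows `i-1..i+2`, columns
#' `j-1..j+2`) contracted with the template whose subcell midpoints are
#' `v = (2a+1)/8`, `u = (2b+1)/8`, divided by 2^18. For integer-valued
#' input the whole contraction is integer arithmetic; the only non-integer
#' step is the final division.
#'
#' @param image numeric matrix, at least 4x4. Integer intensities in
#'   `[0, 2^bit_depth - 1]` for `rounding = "integer"`; any real values for
#'   `rounding = "none"`.
#' @param bank a [build_template_bank()] result.
#' @param rounding `"integer"` divides by 2^18, rounds half away from zero
#'   and clamps to the bit-depth range; `"none"` returns the exact quotient
#'   `numerator / 2^18` (a dyadic rational, exact in double precision)
#'   without rounding or clamping.
#' @param border `"replicate"` (edge replication, default) or `"reflect"`.
#' @param bit_depth bit depth used for clamping under `rounding = "integer"`.
#' @return A numeric matrix of size `4 * nrow(image)` by `4 * ncol(image)`,
#'   with attributes `border` and `rounding` recording the policy used.
#' @examples
#' bank <- build_template_bank()
#' up <- upscale4(matrix(100, 4, 4), bank)
#' unique(as.vector(up))  # 100: constants are reproduced exactly
#' @export
upscale4 <- function(image, bank, rounding = c("integer", "none"),
                     border = c("replicate", "reflect"), bit_depth = 8) {
  rounding <- match.arg(rounding)
  border <- match.arg(border)
  stopifnot(is.matrix(image), is.numeric(image))
  if (nrow(image) < 4 || ncol(image) < 4)
    stop("image must be at least 4x4 for x4 template upscaling")
  if (!inherits(bank, "template_bank") || length(bank$templates) != 16L)
    stop("bank must be a complete template_bank of 16 templates")
  h <- nrow(image); w <- ncol(image)
  pad <- image[border_index(h, border), border_index(w, border), drop = FALSE]
  out <- matrix(0, 4L * h, 4L * w)
  for (k in 1:16) {
    tm <- bank$templates[[k]]$numerators
    a <- (k - 1L) %/% 4L        # v subphase (row), Table layout is v-major
    b <- (k - 1L) %% 4L         # u subphase (column)
    acc <- matrix(0, h, w)
    for (r in 1:4) for (cc in 1:4) {
      acc <- acc + tm[r, cc] * pad[r:(h + r - 1L), cc:(w + cc - 1L)]
    }
    val <- acc / 2^18
    if (rounding == "integer") {
      val <- pmin(pmax(round_half_away(val), 0), 2^bit_depth - 1)
    }
    out[seq.int(a + 1L, by = 4L, length.out = h),
        seq.int(b + 1L, by = 4L, length.out = w)] <- val
  }
  attr(out, "border") <- border
  attr(out, "rounding") <- rounding
  out
}

#' Direct bicubic interpolation reference
#'
#' Independent dense evaluation of separable cubic convolution: for every
#' output pixel it forms the row-weight vector
#' `A = (S(1+v), S(v), S(1-v), S(2-v))`, the 4x4 neighbourhood matrix `B`,
#' and the column-weight vector `C = (S(1+u), S(u), S(1-u), S(2-u))`, and
#' computes `A B C` in exact integer numerator arithmetic over 2^18. It
#' shares no code with [upscale4()]'s shifted-accumulation path and serves
#' as its cross-check oracle.
#'
#' @inheritParams upscale4
#' @return A numeric matrix of size `4 * nrow(image)` by `4 * ncol(image)`
#'   holding the unrounded quotients `numerator / 2^18`.
#' @export
bicubic_reference <- function(image, border = c("replicate", "reflect")) {
  border <- match.arg(border)
  stopifnot(is.matrix(image), nrow(image) >= 4, ncol(image) >= 4)
  h <- nrow(image); w <- ncol(image)
  ri <- border_index(h, border)
  ci <- border_index(w, border)
  out <- matrix(0, 4L * h, 4L * w)
  svec <- function(num8) {
    vapply(c(8 + num8, num8, 8 - num8, 16 - num8),
           function(p) cubic_kernel(p, 8)$numerator, numeric(1))
  }
  for (i in 1:h) {
    rows <- ri[i:(i + 3L)]
    for (j in 1:w) {
      B <- image[rows, ci[j:(j + 3L)], drop = FALSE]
      for (a in 0:3) {
        A <- svec(2L * a + 1L)              # v weights, numerators over 512
        AB <- as.vector(A %*% B)
        for (b in 0:3) {
          C <- svec(2L * b + 1L)            # u weights
          out[4L * (i - 1L) + a + 1L, 4L * (j - 1L) + b + 1L] <-
            sum(AB * C) / 2^18
        }
      }
    }
  }
  out
}

#' Per-pixel arithmetic cost of the template layer
#'
#' Runs an instrumented scalar application of the template contraction over
#' the image and reports the arithmetic operations actually performed per
#' interpolated output pixel: the multiplications in the 4x4 integer dot
#' product, the additions accumulating it, and the final division by 2^18.
#'
#' @param image integer-valued numeric matrix, at least 4x4.
#' @param bank a [build_template_bank()] result.
#' @param border border policy, as in [upscale4()].
#' @return A list of class `op_count` with per-output-pixel averages
#'   `int_mul`, `int_add`, `int_div`, `float_add`, `float_mul`, plus the
#'   number of output pixels `n_pixels`.
#' @export
count_ops <- function(image, bank, border = "replicate") {
  stopifnot(is.matrix(image), all(image == round(image)))
  if (nrow(image) < 4 || ncol(image) < 4) stop("image must be at least 4x4")
  h <- nrow(image); w <- ncol(image)
  ri <- border_index(h, border)
  ci <- border_index(w, border)
  mul <- add <- dvd <- 0
  n_out <- 0L
  for (i in 1:h) for (j in 1:w) {
    B <- image[ri[i:(i + 3L)], ci[j:(j + 3L)]]
    for (k in 1:16) {
      tm <- bank$templates[[k]]$numerators
      acc <- 0
      first <- TRUE
      for (r in 1:4) for (cc in 1:4) {
        p <- tm[r, cc] * B[r, cc]; mul <- mul + 1
        if (first) { acc <- p; first <- FALSE } else { acc <- acc + p; add <- add + 1 }
      }
      acc <- acc / 2^18; dvd <- dvd + 1
      n_out <- n_out + 1L
    }
  }
  structure(list(int_mul = mul / n_out, int_add = add / n_out,
                 int_div = dvd / n_out, float_add = 0, float_mul = 0,
                 n_pixels = n_out),
            class = "op_count")
}

#' @export
print.op_count <- function(x, ...) {
  cat(sprintf(paste0("<op_count> per output pixel: %g int mul, %g int add, ",
                     "%g int div, %g float add, %g float mul (%d pixels)\n"),
              x$int_mul, x$int_add, x$int_div, x$float_add, x$float_mul,
              x$n_pixels))
  invisible(x)
}
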