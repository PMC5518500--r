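# PSNR and region-wise evaluation.

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10((2^n - 1)^2 / MSE)` in decibels, with `n` the bit depth
#' (peak 255 at the 8-bit default). Unit-interval real images (both with
#' maximum at most 1) are mapped to the bit-depth peak before comparison so
#' that PSNR values are comparable across representations. Identical images
#' give `psnr_db = Inf`.
#'
#' @param reference,test numeric matrices of identical shape.
#' @param bit_depth bit depth `n`.
#' @return A list of class `psnr_result` with `psnr_db`, `mse` (on the
#'   integer intensity scale) and `bit_depth`.
#' @examples
#' psnr(matrix(0, 2, 2), matrix(1, 2, 2))$psnr_db  # 10*log10(255^2)
#' @export
psnr <- function(reference, test, bit_depth = 8) {
  if (!identical(dim(reference), dim(test)))
    stop("reference and test images must have identical shapes")
  peak <- 2^bit_depth - 1
  if (max(reference, test) <= 1 + 1e-9) {
    reference <- reference * peak
    test <- test * peak
  }
  mse <- mean((reference - test)^2)
  db <- if (mse == 0) Inf else 10 * log10(peak^2 / mse)
  structure(list(psnr_db = db, mse = mse, bit_depth = bit_depth),
            class = "psnr_result")
}

#' @export
print.psnr_result <- function(x, ...) {
  cat(sprintf("<psnr_result> %s dB (MSE %.6g, %d-bit)\n",
              if (is.infinite(x$psnr_db)) "Inf" else sprintf("%.4f", x$psnr_db),
              x$mse, x$bit_depth))
  invisible(x)
}

#' Region specification
#'
#' @param label `"corners_edges"` or `"plain"`.
#' @param box 0-based half-open pixel box `c(row0, col0, row1, col1)`.
#' @return A list of class `region_spec`.
#' @export
region_spec <- function(label = c("corners_edges", "plain"), box) {
  label <- match.arg(label)
  stopifnot(length(box) == 4, box[3] > box[1], box[4] > box[2], all(box >= 0))
  structure(list(label = label, box = as.integer(box)), class = "region_spec")
}

#' Region-wise PSNR
#'
#' PSNR restricted to each region's pixels; a whole-image region reproduces
#' [psnr()].
#'
#' @param reference,test numeric matrices of identical shape.
#' @param regions list of [region_spec()] objects.
#' @param bit_depth bit depth.
#' @return A data.frame with columns `label`, `row0`, `col0`, `row1`,
#'   `col1`, `mse`, `psnr_db`, `n_pixels`.
#' @export
region_psnr <- function(reference, test, regions, bit_depth = 8) {
  stopifnot(identical(dim(reference), dim(test)), length(regions) >= 1)
  rows <- lapply(regions, function(rg) {
    stopifnot(inherits(rg, "region_spec"))
    b <- rg$box
    if (b[3] > nrow(reference) || b[4] > ncol(reference))
      stop("region box exceeds the image")
    rr <- (b[1] + 1):b[3]; cc <- (b[2] + 1):b[4]
    p <- psnr(reference[rr, cc, drop = FALSE], test[rr, cc, drop = FALSE],
              bit_depth)
    data.frame(label = rg$label, row0 = b[1], col0 = b[2], row1 = b[3],
               col1 = b[4], mse = p$mse, psnr_db = p$psnr_db,
               n_pixels = length(rr) * length(cc))
  })
  do.call(rbind, rows)
}

#' Label image tiles as edge/corner or plain regions
#'
#' Splits the image into `tile x tile` blocks and labels a block
#' `corners_edges` when its mean central-difference gradient magnitude
#' exceeds `threshold`, else `plain`.
#'
#' @param image numeric matrix; `tile` must divide both dimensions.
#' @param tile tile side length.
#' @param threshold mean-gradient threshold (same intensity units as the
#'   image).
#' @return A list of [region_spec()] objects covering the image.
#' @export
classify_regions <- function(image, tile, threshold) {
  h <- nrow(image); w <- ncol(image)
  stopifnot(h %% tile == 0, w %% tile == 0)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  gmag <- sqrt(gx^2 + gy^2)
  out <- list()
  for (r0 in seq(0, h - tile, by = tile)) {
    for (c0 in seq(0, w - tile, by = tile)) {
      g <- mean(gmag[(r0 + 1):(r0 + tile), (c0 + 1):(c0 + tile)])
      out[[length(out) + 1L]] <- region_spec(
        if (g > threshold) "corners_edges" else "plain",
        c(r0, c0, r0 + tile, c0 + tile))
    }
  }
  out
}

#' Evaluate a super-resolution method against a ground truth
#'
#' The standard evaluation path: the ground-truth image is scaled down x4
#' (area averaging), reconstructed by `method`, and compared with the
#' ground truth by PSNR.
#'
#' @param ground_truth numeric matrix, dimensions divisible by 4.
#' @param method function mapping an LR matrix in `[0, 1]` to a
#'   reconstructed 4x-sized matrix in `[0, 1]`.
#' @param bit_depth bit depth for PSNR.
#' @return A [psnr()] result.
#' @export
evaluate_sr <- function(ground_truth, method, bit_depth = 8) {
  gt <- ground_truth
  if (max(gt) > 1 + 1e-9) gt <- gt / (2^bit_depth - 1)
  lr <- scale_down(gt, 4L)
  rec <- method(lr)
  psnr(gt, rec, bit_depth)
}
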