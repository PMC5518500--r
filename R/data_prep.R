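# Paired training-set construction: random fixed-size HR crops and their x4
# area-averaged LR counterparts.

#' Random square crops from a corpus
#'
#' Draws `count` crops of `size x size` from a list of images: sources are
#' visited round-robin, crop origins drawn uniformly with the seeded
#' integer RNG (deterministic across platforms). Images smaller than the
#' crop are skipped with a warning.
#'
#' @param images list of numeric matrices (optionally named).
#' @param size crop side length.
#' @param count number of crops.
#' @param seed RNG seed.
#' @return A list of `count` matrices, each with attributes `source_id`,
#'   `crop_origin` (0-based `c(row, col)`) and `seed`.
#' @export
crop_patches <- function(images, size = 128, count, seed = 1L) {
  stopifnot(length(images) >= 1, count >= 1)
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  ok <- vapply(images, function(m) nrow(m) >= size && ncol(m) >= size,
               logical(1))
  if (any(!ok)) {
    warning(sprintf("%d image(s) smaller than %dx%d skipped", sum(!ok),
                    size, size))
    images <- images[ok]; ids <- ids[ok]
  }
  if (!length(images)) stop("no image in the corpus is large enough to crop")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  out <- vector("list", count)
  for (i in seq_len(count)) {
    src <- ((i - 1L) %% length(images)) + 1L
    m <- images[[src]]
    r0 <- sample.int(nrow(m) - size + 1L, 1L)
    c0 <- sample.int(ncol(m) - size + 1L, 1L)
    crop <- m[r0:(r0 + size - 1L), c0:(c0 + size - 1L)]
    attr(crop, "source_id") <- ids[src]
    attr(crop, "crop_origin") <- c(r0 - 1L, c0 - 1L)
    attr(crop, "seed") <- as.integer(seed)
    out[[i]] <- crop
  }
  out
}

#' Scale an image down by area averaging
#'
#' Each output pixel is the mean of its `factor x factor` source block (box
#' filter decimation). Deterministic and exact for dyadic inputs.
#'
#' @param image numeric matrix with both dimensions divisible by `factor`.
#' @param factor integer decimation factor.
#' @return A `nrow/factor` by `ncol/factor` matrix.
#' @export
scale_down <- function(image, factor = 4L) {
  stopifnot(is.matrix(image), factor >= 1)
  h <- nrow(image); w <- ncol(image)
  if (h %% factor != 0 || w %% factor != 0)
    stop("image dimensions must be divisible by the scaling factor")
  hh <- h %/% factor; ww <- w %/% factor
  # sum over blocks via two grouped matrix products
  rg <- matrix(0, hh, h); rg[cbind(rep(seq_len(hh), each = factor), seq_len(h))] <- 1
  cg <- matrix(0, w, ww); cg[cbind(seq_len(w), rep(seq_len(ww), each = factor))] <- 1
  (rg %*% image %*% cg) / factor^2
}

#' Build (LR, HR) training pairs from HR patches
#'
#' Normalizes each HR patch to `[0, 1]` (dividing by the bit-depth peak when
#' intensities exceed 1) and derives the LR counterpart by [scale_down()],
#' so `scale_down(pair$hr)` reproduces `pair$lr` bit for bit.
#'
#' @param hr_patches list of HR matrices (e.g. from [crop_patches()]).
#' @param factor decimation factor (LR side = HR side / factor).
#' @param bit_depth bit depth used to normalize integer-valued patches.
#' @return A list of pairs; each is a list with `lr`, `hr`, `source_id`,
#'   `crop_origin`, `seed`.
#' @export
make_pairs <- function(hr_patches, factor = 4L, bit_depth = 8) {
  lapply(hr_patches, function(hr) {
    m <- hr
    attributes(m) <- list(dim = dim(hr))
    if (max(m) > 1 + 1e-9) m <- m / (2^bit_depth - 1)
    list(lr = scale_down(m, factor), hr = m,
         source_id = attr(hr, "source_id"),
         crop_origin = attr(hr, "crop_origin"),
         seed = attr(hr, "seed"))
  })
}
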