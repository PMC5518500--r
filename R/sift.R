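# Scale-invariant feature transform: Gaussian/DoG scale space, 26-neighbour
# extremum detection, orientation assignment and the 4x4x8 = 128-dimensional
# gradient-histogram descriptor. Subpixel refinement and Hessian edge
# rejection are deliberately omitted: detection is the plain strict-extremum
# rule among the 26 scale-space neighbours.

#' Gaussian smoothing of an image
#'
#' Convolves with a truncated (radius `ceiling(3.5 * sigma)`) normalized
#' Gaussian kernel, replicate boundary. Convolution is delegated to
#' `EBImage::filter2`.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `sigma <= 0` returns
#'   the image unchanged.
#' @return A numeric matrix of the same size.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(is.matrix(image))
  if (sigma <= 0) return(image)
  r <- max(1L, ceiling(3.5 * sigma))
  # filter2 requires the kernel to fit inside the image
  r <- min(r, (min(dim(image)) - 1L) %/% 2L)
  if (r < 1L) return(image)
  xs <- (-r):r
  k1 <- exp(-xs^2 / (2 * sigma^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  out <- EBImage::filter2(image, kern, boundary = "replicate")
  matrix(as.numeric(out), nrow(image), ncol(image))
}

#' Gaussian / difference-of-Gaussians scale-space pyramid
#'
#' Builds, per octave, `scales_per_octave + 3` Gaussian-smoothed layers with
#' geometrically increasing sigma (`sigma0 * 2^(i/scales_per_octave)`) and
#' the `scales_per_octave + 2` difference-of-Gaussians layers between
#' adjacent pairs. Octaves are halved in resolution; if the image becomes
#' too small the octave count is reduced with a warning.
#'
#' @param image numeric matrix (any intensity scale; internally rescaled to
#'   `[0, 1]` by the image maximum so detection thresholds are
#'   scale-independent).
#' @param octaves requested number of octaves.
#' @param scales_per_octave DoG sampling density per octave doubling.
#' @param sigma0 base smoothing scale in pixels.
#' @return A list of class `sift_pyramid`; per octave: `gaussians`, `dogs`,
#'   `sigmas` (octave-relative), `factor` (2^(octave-1)).
#' @export
gaussian_scale_space <- function(image, octaves = 3, scales_per_octave = 3,
                                 sigma0 = 1.6) {
  stopifnot(is.matrix(image), length(image) > 0, octaves >= 1)
  mx <- max(abs(image))
  if (mx > 0) image <- image / mx
  s <- scales_per_octave
  k <- 2^(1 / s)
  min_side <- 4L * ceiling(3.5 * sigma0 * k^(s + 2)) + 1L
  max_oct <- max(1L, 1L + floor(log2(min(dim(image)) / min_side)))
  if (octaves > max_oct) {
    warning(sprintf("image too small for %d octaves; using %d", octaves,
                    max_oct))
    octaves <- max_oct
  }
  base <- image
  pyr <- vector("list", octaves)
  sigmas <- sigma0 * k^(0:(s + 2))
  for (o in seq_len(octaves)) {
    gaussians <- lapply(sigmas, function(sg) gaussian_blur(base, sg))
    dogs <- lapply(seq_len(length(gaussians) - 1L),
                   function(l) gaussians[[l + 1L]] - gaussians[[l]])
    pyr[[o]] <- list(gaussians = gaussians, dogs = dogs, sigmas = sigmas,
                     factor = 2^(o - 1))
    # next octave: level with twice the base sigma, decimated by 2
    nxt <- gaussians[[s + 1L]]
    base <- nxt[seq(1, nrow(nxt), by = 2), seq(1, ncol(nxt), by = 2),
                drop = FALSE]
  }
  structure(pyr, class = "sift_pyramid")
}

# strict 26-neighbour extremum masks for DoG layer `mid` given below/above
extremum_mask <- function(below, mid, above) {
  h <- nrow(mid); w <- ncol(mid)
  if (h < 3 || w < 3) return(matrix(FALSE, h, w))
  inner <- function(m, dr, dc) m[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc)]
  ctr <- inner(mid, 0, 0)
  gt <- matrix(TRUE, h - 2, w - 2)
  lt <- matrix(TRUE, h - 2, w - 2)
  for (dr in -1:1) for (dc in -1:1) {
    for (layer in list(below, above)) {
      v <- inner(layer, dr, dc)
      gt <- gt & (ctr > v); lt <- lt & (ctr < v)
    }
    if (dr != 0 || dc != 0) {
      v <- inner(mid, dr, dc)
      gt <- gt & (ctr > v); lt <- lt & (ctr < v)
    }
  }
  out <- matrix(FALSE, h, w)
  out[2:(h - 1), 2:(w - 1)] <- gt | lt
  out
}

#' Detect scale-space keypoints
#'
#' A pixel of an interior DoG layer is a keypoint candidate iff it is a
#' strict extremum among its 26 neighbours (8 in-plane, 9 in the scale
#' above, 9 below) and its absolute DoG response exceeds
#' `contrast_threshold`.
#'
#' @param pyramid a [gaussian_scale_space()] result.
#' @param contrast_threshold minimum `|DoG|` (unit intensity scale).
#' @return A data.frame with one row per keypoint: `row`, `col` (base-image
#'   coordinates), `octave`, `level` (Gaussian level index), `sigma`
#'   (base-image pixels), `response`.
#' @export
detect_keypoints <- function(pyramid, contrast_threshold = 0.03) {
  stopifnot(inherits(pyramid, "sift_pyramid"))
  out <- list()
  for (o in seq_along(pyramid)) {
    oct <- pyramid[[o]]
    nd <- length(oct$dogs)
    for (l in seq(2, nd - 1)) {
      msk <- extremum_mask(oct$dogs[[l - 1]], oct$dogs[[l]], oct$dogs[[l + 1]])
      msk <- msk & (abs(oct$dogs[[l]]) > contrast_threshold)
      if (!any(msk)) next
      idx <- which(msk, arr.ind = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        row = (idx[, 1] - 1) * oct$factor + 1,
        col = (idx[, 2] - 1) * oct$factor + 1,
        octave = o, level = l,
        sigma = oct$sigmas[l] * oct$factor,
        response = oct$dogs[[l]][idx])
    }
  }
  if (!length(out)) {
    return(data.frame(row = numeric(), col = numeric(), octave = integer(),
                      level = integer(), sigma = numeric(),
                      response = numeric()))
  }
  do.call(rbind, out)
}

bilinear_at <- function(m, r, c) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(c), w - 1)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
}

#' Compute 128-dimensional SIFT descriptors
#'
#' Assigns each keypoint a dominant orientation from a 36-bin
#' Gaussian-weighted gradient-orientation histogram, rotates the sampling
#' frame to it, and accumulates gradient magnitudes into a 4x4 grid of
#' 8-bin orientation histograms (a 128-vector), normalized to unit length
#' with the usual 0.2 clamp-and-renormalize. Keypoints whose sampling
#' window leaves the image are dropped; the number dropped is reported in
#' attribute `n_dropped`.
#'
#' @param pyramid a [gaussian_scale_space()] result.
#' @param keypoints a [detect_keypoints()] data.frame.
#' @return A list of class `feature_set` with `keypoints` (data.frame
#'   `x`, `y`, `scale`, `orientation` in degrees) and `descriptors`
#'   (matrix, one 128-row per keypoint).
#' @export
describe_keypoints <- function(pyramid, keypoints) {
  stopifnot(inherits(pyramid, "sift_pyramid"))
  kept <- list(); desc <- list(); dropped <- 0L
  for (i in seq_len(nrow(keypoints))) {
    kp <- keypoints[i, ]
    oct <- pyramid[[kp$octave]]
    L <- oct$gaussians[[kp$level]]
    sg <- oct$sigmas[kp$level]
    r <- (kp$row - 1) / oct$factor + 1
    c <- (kp$col - 1) / oct$factor + 1
    win <- ceiling(8 * max(sg, 1) * sqrt(2)) + 1
    if (r - win < 2 || r + win > nrow(L) - 1 ||
        c - win < 2 || c + win > ncol(L) - 1) {
      dropped <- dropped + 1L
      next
    }
    gr <- sift_gradients(L)
    theta <- dominant_orientation(gr, r, c, sg)
    d <- sift_descriptor(gr, r, c, sg, theta)
    kept[[length(kept) + 1L]] <- data.frame(
      x = kp$col, y = kp$row, scale = kp$sigma,
      orientation = (theta * 180 / pi) %% 360)
    desc[[length(desc) + 1L]] <- d
  }
  kps <- if (length(kept)) do.call(rbind, kept) else
    data.frame(x = numeric(), y = numeric(), scale = numeric(),
               orientation = numeric())
  dm <- if (length(desc)) do.call(rbind, desc) else
    matrix(numeric(), 0, 128)
  structure(list(image_id = NA_character_, keypoints = kps,
                 descriptors = dm, n_dropped = dropped),
            class = "feature_set")
}

sift_gradients <- function(L) {
  h <- nrow(L); w <- ncol(L)
  dx <- matrix(0, h, w); dy <- matrix(0, h, w)
  dx[, 2:(w - 1)] <- (L[, 3:w] - L[, 1:(w - 2)]) / 2   # along columns (x)
  dy[2:(h - 1), ] <- (L[3:h, ] - L[1:(h - 2), ]) / 2   # along rows (y)
  list(mag = sqrt(dx^2 + dy^2), ang = atan2(dy, dx))
}

dominant_orientation <- function(gr, r, c, sg) {
  rad <- max(2L, round(3 * 1.5 * sg))
  rows <- round(r) + (-rad):rad
  cols <- round(c) + (-rad):rad
  rows <- rows[rows >= 1 & rows <= nrow(gr$mag)]
  cols <- cols[cols >= 1 & cols <= ncol(gr$mag)]
  rr <- rep(rows, times = length(cols))
  cc <- rep(cols, each = length(rows))
  wgt <- exp(-((rr - r)^2 + (cc - c)^2) / (2 * (1.5 * sg)^2))
  mag <- gr$mag[cbind(rr, cc)] * wgt
  ang <- gr$ang[cbind(rr, cc)] %% (2 * pi)
  bin <- pmin(floor(ang / (2 * pi) * 36) + 1, 36)
  hist36 <- vapply(1:36, function(b) sum(mag[bin == b]), numeric(1))
  best <- which.max(hist36)
  (best - 0.5) / 36 * 2 * pi
}

sift_descriptor <- function(gr, r, c, sg, theta) {
  m <- max(sg, 1)                       # sample spacing in pixels
  offs <- seq(-7.5, 7.5, by = 1) * m    # 16 samples per axis
  du <- rep(offs, times = 16)           # along descriptor x
  dv <- rep(offs, each = 16)            # along descriptor y
  ct <- cos(theta); st <- sin(theta)
  # rotate sampling grid by theta (image coords: x = col, y = row)
  sx <- c + du * ct - dv * st
  sy <- r + du * st + dv * ct
  mag <- bilinear_at(gr$mag, sy, sx)
  ang <- (bilinear_at(gr$ang, sy, sx) - theta) %% (2 * pi)
  wgt <- exp(-(du^2 + dv^2) / (2 * (8 * m)^2))
  cell_u <- pmin(floor((du / m + 8) / 4) + 1, 4)
  cell_v <- pmin(floor((dv / m + 8) / 4) + 1, 4)
  obin <- pmin(floor(ang / (2 * pi) * 8) + 1, 8)
  d <- numeric(128)
  idx <- ((cell_v - 1) * 4 + (cell_u - 1)) * 8 + obin
  for (i in seq_along(idx)) d[idx[i]] <- d[idx[i]] + mag[i] * wgt[i]
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d <- pmin(d, 0.2)
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d
}

#' Extract SIFT features from an image
#'
#' Convenience wrapper: scale space, keypoint detection, description.
#'
#' @param image numeric matrix.
#' @param image_id identifier stored in the result.
#' @param octaves,scales_per_octave,sigma0 see [gaussian_scale_space()].
#' @param contrast_threshold see [detect_keypoints()].
#' @return A `feature_set` (see [describe_keypoints()]).
#' @export
sift_features <- function(image, image_id = NA_character_, octaves = 3,
                          scales_per_octave = 3, sigma0 = 1.6,
                          contrast_threshold = 0.03) {
  pyr <- gaussian_scale_space(image, octaves, scales_per_octave, sigma0)
  kp <- detect_keypoints(pyr, contrast_threshold)
  fs <- describe_keypoints(pyr, kp)
  fs$image_id <- image_id
  fs
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s: %d features (%d dropped at borders)\n",
              x$image_id, nrow(x$descriptors), x$n_dropped))
  invisible(x)
}
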