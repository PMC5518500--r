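# Seeded synthetic image generators: every test and training input in the
# package is built from these, so nothing needs to be downloaded. Textured
# kinds (gaussian_blobs, checkerboard, smooth_noise, sinusoid, step_edge)
# stand in for structured medical content; constant and ramp kinds provide
# featureless rejectable candidates and analytic ground truths.

#' Specification of a synthetic image
#'
#' @param kind one of `"constant"`, `"ramp"`, `"sinusoid"`,
#'   `"gaussian_blobs"`, `"checkerboard"`, `"smooth_noise"`, `"step_edge"`.
#' @param height,width image dimensions.
#' @param params per-kind parameter list (see [generate_fixture()]).
#' @param seed RNG seed (used by the stochastic kinds).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind, height, width, params = list(), seed = 1L) {
  kinds <- c("constant", "ramp", "sinusoid", "gaussian_blobs",
             "checkerboard", "smooth_noise", "step_edge")
  if (!kind %in% kinds)
    stop("unknown fixture kind: ", kind)
  structure(list(kind = kind, height = as.integer(height),
                 width = as.integer(width), params = params,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic image from a spec
#'
#' Deterministic given the spec (Mersenne-Twister seeding for the
#' stochastic kinds). Intensities are integers in `[0, 255]` unless
#' `params$integer = FALSE`. Kind parameters (all optional):
#' * `constant`: `value` (default 128).
#' * `ramp`: `alpha`, `beta`, `gamma` — `f(i, j) = alpha*i + beta*j + gamma`
#'   on 0-based indices, clamped to range.
#' * `sinusoid`: `period_i`, `period_j`, `amplitude`, `offset`.
#' * `gaussian_blobs`: `k` separated blobs (`sigma`, `amplitude`,
#'   `background`), centres seeded on a jittered grid.
#' * `checkerboard`: `cell`, `low`, `high`.
#' * `smooth_noise`: white noise smoothed with a Gaussian of `sigma`
#'   (band-limited texture), rescaled to `[low, high]`.
#' * `step_edge`: vertical step at column `at` between `low` and `high`.
#'
#' @param spec a [fixture_spec()].
#' @return A numeric matrix `height x width`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  h <- spec$height; w <- spec$width
  p <- spec$params
  gp <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  ii <- matrix(rep(0:(h - 1), w), h, w)
  jj <- matrix(rep(0:(w - 1), each = h), h, w)
  m <- switch(spec$kind,
    constant = matrix(gp("value", 128), h, w),
    ramp = gp("alpha", 0.5) * ii + gp("beta", 0.25) * jj + gp("gamma", 10),
    sinusoid = gp("offset", 128) + gp("amplitude", 100) *
      sin(2 * pi * ii / gp("period_i", 16)) *
      cos(2 * pi * jj / gp("period_j", 16)),
    gaussian_blobs = {
      k <- gp("k", 4); sg <- gp("sigma", 3)
      amp <- gp("amplitude", 150); bg <- gp("background", 40)
      # jittered grid keeps blobs separated so each yields one local maximum
      g <- ceiling(sqrt(k))
      ctr_i <- (rep(seq_len(g), each = g) - 0.5) * h / g
      ctr_j <- (rep(seq_len(g), times = g) - 0.5) * w / g
      pick <- sample.int(g * g, k)
      ctr_i <- ctr_i[pick] + stats::runif(k, -h / (8 * g), h / (8 * g))
      ctr_j <- ctr_j[pick] + stats::runif(k, -w / (8 * g), w / (8 * g))
      m <- matrix(bg, h, w)
      for (b in seq_len(k)) {
        m <- m + amp * exp(-((ii + 1 - ctr_i[b])^2 + (jj + 1 - ctr_j[b])^2) /
                             (2 * sg^2))
      }
      m
    },
    checkerboard = {
      cell <- gp("cell", 8)
      lo <- gp("low", 30); hi <- gp("high", 220)
      ifelse(((ii %/% cell) + (jj %/% cell)) %% 2 == 0, lo, hi)
    },
    smooth_noise = {
      sg <- gp("sigma", 1.5)
      lo <- gp("low", 20); hi <- gp("high", 235)
      z <- matrix(stats::rnorm(h * w), h, w)
      z <- gaussian_blur(z, sg)
      rng <- range(z)
      lo + (z - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps) * (hi - lo)
    },
    step_edge = {
      at <- gp("at", w %/% 2)
      ifelse(jj < at, gp("low", 50), gp("high", 200))
    })
  m <- pmin(pmax(m, 0), 255)
  if (gp("integer", TRUE)) m <- round(m)
  m
}

#' Generate a corpus of synthetic images on disk
#'
#' Writes each spec's image as PNG and a JSON manifest recording every spec
#' and seed, sufficient to regenerate the corpus byte-identically.
#'
#' @param specs list of [fixture_spec()] objects.
#' @param out_dir output directory (created if needed).
#' @return The manifest (a list), invisibly; written as
#'   `manifest.json` in `out_dir`.
#' @export
generate_corpus <- function(specs, out_dir) {
  stopifnot(length(specs) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    file <- sprintf("fixture_%03d_%s.png", i, sp$kind)
    write_image(generate_fixture(sp), file.path(out_dir, file))
    list(file = file, kind = sp$kind, height = sp$height, width = sp$width,
         params = sp$params, seed = sp$seed)
  })
  manifest <- list(format = "medsrr-corpus-1", images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Default mixed synthetic corpus specs
#'
#' A convenience set mixing textured kinds (stand-ins for structured
#' medical content) and flat kinds (rejectable transfer candidates).
#'
#' @param n number of specs.
#' @param height,width image dimensions.
#' @param seed base seed; image `i` uses `seed + i`.
#' @return A list of [fixture_spec()] objects.
#' @export
default_corpus_specs <- function(n = 8, height = 96, width = 96, seed = 100L) {
  kinds <- c("smooth_noise", "gaussian_blobs", "checkerboard", "sinusoid")
  lapply(seq_len(n), function(i) {
    fixture_spec(kinds[((i - 1) %% length(kinds)) + 1], height, width,
                 seed = seed + i)
  })
}
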