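#' Cubic convolution kernel, evaluated exactly
#'
#' Evaluates the piecewise-cubic convolution kernel
#' \deqn{S(\omega) = \cases{1 - 2\omega^2 + \omega^3 & 0 \le \omega < 1 \cr
#'       4 - 8\omega + 5\omega^2 - \omega^3 & 1 \le \omega < 2 \cr
#'       0 & \omega \ge 2}}
#' (the `a = -1` cubic convolution kernel) at a rational argument, in exact
#' integer arithmetic. The argument is supplied as a fraction `num/den`; when
#' `den` divides 8 the result is returned over the fixed denominator 512
#' (\eqn{8^3}), which is the form the integer interpolation templates are
#' built from. For other denominators the exact reduced fraction is returned.
#'
#' The kernel is even; callers supply \eqn{|\omega|}, and negative arguments
#' are rejected rather than silently mirrored.
#'
#' @param num,den integers with `den >= 1`; the argument is `omega = num/den`,
#'   which must be `>= 0`.
#' @return A list of class `cubic_weight` with integer fields `numerator` and
#'   `denominator` (512 whenever `den` divides 8). `numerator/denominator`
#'   equals \eqn{S(\omega)} exactly.
#' @examples
#' cubic_kernel(0, 1)      # 512/512 = 1
#' cubic_kernel(1, 8)      # 497/512
#' cubic_kernel(9, 8)      # -49/512
#' @export
cubic_kernel <- function(num, den = 1L) {
  stopifnot(length(num) == 1L, length(den) == 1L, is.finite(num), is.finite(den))
  num <- as.numeric(num); den <- as.numeric(den)
  if (num != round(num) || den != round(den) || den < 1)
    stop("omega must be a rational num/den with integer parts and den >= 1")
  if (num < 0) stop("omega must be nonnegative; supply |omega|")
  # S(num/den) over denominator den^3, all integer arithmetic (exact in
  # doubles well below 2^53 for the denominators used here)
  d3 <- den^3
  if (num / den < 1) {
    n3 <- d3 - 2 * num^2 * den + num^3
  } else if (num / den < 2) {
    n3 <- 4 * d3 - 8 * num * den^2 + 5 * num^2 * den - num^3
  } else {
    n3 <- 0
  }
  if (512 %% d3 == 0) {
    out <- list(numerator = n3 * (512 / d3), denominator = 512)
  } else {
    g <- gcd_int(abs(n3), d3)
    if (g == 0) g <- 1
    out <- list(numerator = n3 / g, denominator = d3 / g)
  }
  structure(out, class = "cubic_weight")
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' @export
print.cubic_weight <- function(x, ...) {
  cat(sprintf("<cubic_weight> %d/%d = %.8f\n",
              x$numerator, x$denominator, x$numerator / x$denominator))
  invisible(x)
}

# Kernel weight 4-vector for a fractional offset t = num/8: the factors
# (1+t, t, 1-t, 2-t) applied to the four neighbours along one axis.
# Returned as integer numerators over 512.
kernel_vector <- function(num8) {
  stopifnot(num8 >= 1, num8 <= 7)
  vapply(list(c(8 + num8, 8), c(num8, 8), c(8 - num8, 8), c(16 - num8, 8)),
         function(pq) cubic_kernel(pq[1], pq[2])$numerator, numeric(1))
}

#' Derive one bicubic interpolation template
#'
#' Builds the 4x4 integer stencil that applies separable cubic convolution
#' interpolation at fractional offset `(v, u)` inside a pixel cell: entry
#' `(r, c)` is \eqn{2^{18} S(\mathrm{rowfac}_r(v)) S(\mathrm{colfac}_c(u))}
#' with row factors \eqn{(1+v, v, 1-v, 2-v)} and column factors
#' \eqn{(1+u, u, 1-u, 2-u)}. `v` is the offset along the first (row) image
#' axis and `u` along the second (column) axis. All arithmetic is exact
#' integer; the stencil's entries always sum to \eqn{2^{18} = 262144}
#' (partition of unity).
#'
#' @param u,v fractional offsets in (0, 1), expressible in eighths
#'   (denominator dividing 8); `1/8` etc. are exact in double precision.
#' @return A list of class `bicubic_template` with fields `index` (NA unless
#'   set by [build_template_bank()]), `u`, `v`, `numerators` (4x4 integer
#'   matrix) and `denominator` (262144).
#' @seealso [build_template_bank()]
#' @export
derive_template <- function(u, v) {
  un <- u * 8; vn <- v * 8
  if (un != round(un) || vn != round(vn))
    stop("u and v must have denominator dividing 8")
  if (u <= 0 || u >= 1 || v <= 0 || v >= 1)
    stop("u and v must lie strictly inside (0, 1)")
  V <- kernel_vector(round(vn))
  U <- kernel_vector(round(un))
  numerators <- outer(V, U)          # (r, c) = V_r * U_c, integers < 512^2
  storage.mode(numerators) <- "double"
  structure(list(index = NA_integer_, u = u, v = v,
                 numerators = numerators, denominator = 2^18),
            class = "bicubic_template")
}

#' Build the full bank of 16 bicubic templates
#'
#' Enumerates the quarter-interval midpoints `u, v` in `{1/8, 3/8, 5/8, 7/8}`
#' (v-major, u-minor) and derives the corresponding 16 integer templates
#' `T1..T16`. This bank, applied as a fixed convolutional layer, performs
#' exact x4 bicubic upscaling with integer arithmetic.
#'
#' @return A list of class `template_bank` with field `templates`, a list of
#'   16 [derive_template()] results carrying `index` 1..16.
#' @examples
#' bank <- build_template_bank()
#' bank$templates[[1]]$numerators[1, 1]  # 2401
#' @export
build_template_bank <- function() {
  mids <- c(1, 3, 5, 7) / 8
  templates <- vector("list", 16L)
  k <- 0L
  for (v in mids) {
    for (u in mids) {
      k <- k + 1L
      tm <- derive_template(u, v)
      tm$index <- k
      templates[[k]] <- tm
    }
  }
  structure(list(templates = templates, denominator = 2^18),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat("<template_bank> 16 integer bicubic templates over denominator 262144\n")
  invisible(x)
}

#' @export
print.bicubic_template <- function(x, ...) {
  cat(sprintf("<bicubic_template> T%s (u = %s, v = %s), /262144\n",
              x$index, format(x$u), format(x$v)))
  print(x$numerators)
  invisible(x)
}

#' Published template table, as printed
#'
#' The 16 bicubic template solutions as they appear in print, transcribed
#' verbatim: 4x4 integer numerator matrices over the common denominator
#' 2^18. The printed table contains two typographical transpositions
#' (cells T7 (4,1) and T11 (1,1) print 2205 where the derivation from the
#' cubic kernel gives 2025); this transcription preserves them so that
#' [verify_against_printed()] can document the discrepancies.
#'
#' @return A named list `T1`..`T16` of 4x4 integer matrices.
#' @keywords internal
#' @export
printed_template_table <- function() {
  list(
    T1 = rbind(
      c(2401, -24353, -3479, 343),
      c(-24353, 247009, 35287, -3479),
      c(-3479, 35287, 5041, -497),
      c(343, -3479, -497, 49)),
    T2 = rbind(
      c(3675, -19355, -11613, 2205),
      c(-37275, 196315, 117789, -22365),
      c(-5325, 28045, 16827, -3195),
      c(525, -2765, -1659, 315)),
    T3 = rbind(
      c(2205, -11613, -19355, 3675),
      c(-22365, 117789, 196315, -37275),
      c(-3195, 16827, 28045, -5325),
      c(315, -1659, -2765, 525)),
    T4 = rbind(
      c(343, -3479, -24353, 2401),
      c(-3479, 35287, 247009, -24353),
      c(-497, 5041, 35287, -3479),
      c(49, -497, -3479, 343)),
    T5 = rbind(
      c(3675, -37275, -5325, 525),
      c(-19355, 196315, 28045, -2765),
      c(-11613, 117789, 16827, -1659),
      c(2205, -22365, -3195, 315)),
    T6 = rbind(
      c(5625, -29625, -17775, 3375),
      c(-29625, 156025, 93615, -17775),
      c(-17775, 93615, 56169, -10665),
      c(3375, -17775, -10665, 2025)),
    T7 = rbind(
      c(3375, -17775, -29625, 5625),
      c(-17775, 93615, 156025, -29625),
      c(-10665, 56169, 93615, -17775),
      c(2205, -10665, -17775, 3375)),
    T8 = rbind(
      c(525, -5325, -37275, 3675),
      c(-2765, 28045, 196315, -19355),
      c(-1659, 16827, 117789, -11613),
      c(315, -3195, -22365, 2205)),
    T9 = rbind(
      c(2205, -22365, -3195, 315),
      c(-11613, 117789, 16827, -1659),
      c(-19355, 196315, 28045, -2765),
      c(3675, -37275, -5325, 525)),
    T10 = rbind(
      c(3375, -17775, -10665, 2025),
      c(-17775, 93615, 56169, -10665),
      c(-29625, 156025, 93615, -17775),
      c(5625, -29625, -17775, 3375)),
    T11 = rbind(
      c(2205, -10665, -17775, 3375),
      c(-10665, 56169, 93615, -17775),
      c(-17775, 93615, 156025, -29625),
      c(3375, -17775, -29625, 5625)),
    T12 = rbind(
      c(315, -3195, -22365, 2205),
      c(-1659, 16827, 117789, -11613),
      c(-2765, 28045, 196315, -19355),
      c(525, -5325, -37275, 3675)),
    T13 = rbind(
      c(343, -3479, -497, 49),
      c(-3479, 35287, 5041, -497),
      c(-24353, 247009, 35287, -3479),
      c(2401, -24353, -3479, 343)),
    T14 = rbind(
      c(525, -2765, -1659, 315),
      c(-5325, 28045, 16827, -3195),
      c(-37275, 196315, 117789, -22365),
      c(3675, -19355, -11613, 2205)),
    T15 = rbind(
      c(315, -1659, -2765, 525),
      c(-3195, 16827, 28045, -5325),
      c(-22365, 117789, 196315, -37275),
      c(2205, -11613, -19355, 3675)),
    T16 = rbind(
      c(49, -497, -3479, 343),
      c(-497, 5041, 35287, -3479),
      c(-3479, 35287, 247009, -24353),
      c(343, -3479, -24353, 2401)))
}

#' Compare a derived template bank against printed values
#'
#' Regression harness for the published template table: reports every
#' (template, row, column) cell where the exact derivation and a printed
#' transcription disagree. With the full [printed_template_table()] this
#' yields exactly the two known typographical discrepancies.
#'
#' @param bank a [build_template_bank()] result.
#' @param printed a named list mapping template names (`"T1"`..`"T16"`) or
#'   indices to 4x4 integer matrices; may cover any subset of templates.
#' @return A data.frame with columns `template`, `row`, `col`, `derived`,
#'   `printed`; zero rows when everything matches.
#' @export
verify_against_printed <- function(bank, printed = printed_template_table()) {
  stopifnot(inherits(bank, "template_bank"))
  rows <- list()
  for (nm in names2_or_index(printed)) {
    k <- if (grepl("^T", nm)) as.integer(sub("^T", "", nm)) else as.integer(nm)
    der <- bank$templates[[k]]$numerators
    pr <- printed[[nm]]
    stopifnot(identical(dim(pr), c(4L, 4L)))
    diff <- which(der != pr, arr.ind = TRUE)
    if (nrow(diff)) {
      rows[[length(rows) + 1L]] <- data.frame(
        template = k, row = diff[, 1], col = diff[, 2],
        derived = der[diff], printed = pr[diff])
    }
  }
  if (!length(rows)) {
    return(data.frame(template = integer(), row = integer(), col = integer(),
                      derived = numeric(), printed = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$template, out$row, out$col), , drop = FALSE]
}

names2_or_index <- function(x) {
  nm <- names(x)
  if (is.null(nm) || any(nm == "")) as.character(seq_along(x)) else nm
}

#' Serialize a template bank to JSON
#'
#' Writes the bank in the interchange layout
#' `{"denominator": 262144, "templates": [{"index", "u", "v", "numerators"}]}`
#' with `u`, `v` as exact fraction strings (`"1/8"`, ...).
#'
#' @param bank a [build_template_bank()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_template_bank <- function(bank, path) {
  stopifnot(inherits(bank, "template_bank"))
  frac8 <- function(x) paste0(round(x * 8), "/8")
  obj <- list(
    denominator = bank$denominator,
    templates = lapply(bank$templates, function(tm) {
      list(index = tm$index, u = frac8(tm$u), v = frac8(tm$v),
           numerators = lapply(seq_len(4), function(r) tm$numerators[r, ]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
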