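# Transfer-learning sample selection: the mean-minimum descriptor distance
# D(S,T), the match ratio eta, and the admission rule eta >= D.

descriptor_matrix <- function(x) {
  if (inherits(x, "feature_set")) return(x$descriptors)
  if (is.matrix(x)) return(x)
  stop("expected a feature_set or a descriptor matrix")
}

#' Mean-minimum SIFT descriptor distance between two feature sets
#'
#' For each of the `m` descriptors of the candidate set `S`, takes the
#' minimum Euclidean distance to the `n` descriptors of the reference set
#' `T`, and averages:
#' \deqn{D(S,T) = \frac1m \sum_{i=1}^m \min_{1 \le j \le n}
#'       \sqrt{\sum_{k=1}^{128} (s_{ik} - t_{jk})^2}.}
#' Not symmetric in general.
#'
#' @param S,T `feature_set` objects or descriptor matrices (rows =
#'   features, 128 columns).
#' @return A nonnegative scalar; error if either set is empty.
#' @export
sift_distance <- function(S, T) {
  s <- descriptor_matrix(S); t <- descriptor_matrix(T)
  if (nrow(s) == 0 || nrow(t) == 0)
    stop("sift_distance is undefined for empty feature sets")
  stopifnot(ncol(s) == ncol(t))
  d2 <- cross_dist2(s, t)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

cross_dist2 <- function(s, t) {
  # squared Euclidean distances, m x n
  d2 <- outer(rowSums(s^2), rep(1, nrow(t))) +
    outer(rep(1, nrow(s)), rowSums(t^2)) - 2 * s %*% t(t)
  d2 <- pmax(d2, 0)
  # expansion round-off leaves O(1e-15) residues on identical descriptors;
  # zap them so D(S, S) is exactly zero (descriptors are unit length, so
  # genuine distances are many orders of magnitude larger)
  d2[d2 < 1e-10] <- 0
  d2
}

#' Match features between two sets (nearest neighbour + ratio test)
#'
#' A candidate feature matches when its nearest reference descriptor is
#' closer than `ratio` times its second-nearest (Lowe's ratio test). With a
#' single reference feature the second-nearest is taken as infinite, so the
#' nearest always passes.
#'
#' @param S,T `feature_set` objects or descriptor matrices.
#' @param ratio ratio-test threshold in (0, 1].
#' @return An integer vector: for each row of `S`, the matched row of `T`
#'   or `NA`.
#' @export
match_features <- function(S, T, ratio = 0.8) {
  s <- descriptor_matrix(S); t <- descriptor_matrix(T)
  if (nrow(s) == 0 || nrow(t) == 0)
    return(rep(NA_integer_, nrow(s)))
  d2 <- cross_dist2(s, t)
  out <- rep(NA_integer_, nrow(s))
  for (i in seq_len(nrow(s))) {
    ord <- order(d2[i, ])
    d1 <- sqrt(max(d2[i, ord[1]], 0))
    d2nd <- if (length(ord) >= 2) sqrt(max(d2[i, ord[2]], 0)) else Inf
    if (d1 < ratio * d2nd) out[i] <- ord[1]
  }
  out
}

#' Match ratio between a candidate and a reference set
#'
#' `eta = N_m / N_t` where `N_m` is the number of candidate features
#' matched under the matching rule and `N_t` the number of features in the
#' candidate set.
#'
#' @inheritParams match_features
#' @param match_rule function `(S, T) -> integer vector` of matches
#'   (defaults to [match_features()] with the given `ratio`).
#' @return A scalar in `[0, 1]`; error for an empty candidate set.
#' @export
match_ratio <- function(S, T, ratio = 0.8, match_rule = NULL) {
  s <- descriptor_matrix(S)
  if (nrow(s) == 0) stop("match_ratio is undefined for an empty candidate set")
  matches <- if (is.null(match_rule)) match_features(S, T, ratio)
             else match_rule(S, T)
  sum(!is.na(matches)) / nrow(s)
}

#' Admit transfer-learning candidates
#'
#' Scores each candidate subregion against a set of reference (target
#' domain) images and admits it when the criterion `eta >= D` holds, with
#' `D` aggregated as the minimum of [sift_distance()] over references and
#' `eta` as the maximum of [match_ratio()] over references. Descriptors are
#' unit length, so `D` and `eta` are on comparable O(1) scales. Candidates
#' with no features are never admitted and are flagged.
#'
#' @param candidates list of `feature_set` objects.
#' @param references nonempty list of `feature_set` objects.
#' @param ratio ratio-test threshold for matching.
#' @param eta_min,d_max optional independent overrides: additionally require
#'   `eta >= eta_min` and `D <= d_max`.
#' @return A data.frame with one row per candidate: `candidate_id`, `D`,
#'   `eta`, `n_features`, `flagged`, `admitted`.
#' @export
select_candidates <- function(candidates, references, ratio = 0.8,
                              eta_min = 0, d_max = Inf) {
  stopifnot(length(references) >= 1)
  refs <- Filter(function(r) nrow(descriptor_matrix(r)) > 0, references)
  if (!length(refs)) stop("all reference images have zero SIFT features")
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    id <- if (is.list(cand) && !is.null(cand$image_id) &&
              !is.na(cand$image_id)) cand$image_id else as.character(i)
    nf <- nrow(descriptor_matrix(cand))
    if (nf == 0) {
      return(data.frame(candidate_id = id, D = NA_real_, eta = NA_real_,
                        n_features = 0L, flagged = TRUE, admitted = FALSE))
    }
    Ds <- vapply(refs, function(r) sift_distance(cand, r), numeric(1))
    etas <- vapply(refs, function(r) match_ratio(cand, r, ratio), numeric(1))
    D <- min(Ds); eta <- max(etas)
    data.frame(candidate_id = id, D = D, eta = eta, n_features = nf,
               flagged = FALSE,
               admitted = eta >= D && eta >= eta_min && D <= d_max)
  })
  do.call(rbind, rows)
}

#' Tile an image into candidate subregions
#'
#' Extracts overlapping square crops on a regular stride grid, the candidate
#' subregions scored by [select_candidates()].
#'
#' @param image numeric matrix.
#' @param size crop side length.
#' @param stride step between crop origins.
#' @return A list of crops; each carries attribute `box`, the 0-based
#'   half-open pixel box `c(row0, col0, row1, col1)`.
#' @export
tile_crops <- function(image, size = 128, stride = 64) {
  h <- nrow(image); w <- ncol(image)
  if (h < size || w < size) return(list())
  r0s <- unique(c(seq(1, h - size + 1, by = stride), h - size + 1))
  c0s <- unique(c(seq(1, w - size + 1, by = stride), w - size + 1))
  out <- list()
  for (r0 in r0s) for (c0 in c0s) {
    crop <- image[r0:(r0 + size - 1), c0:(c0 + size - 1)]
    attr(crop, "box") <- c(r0 - 1, c0 - 1, r0 - 1 + size, c0 - 1 + size)
    out[[length(out) + 1L]] <- crop
  }
  out
}
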