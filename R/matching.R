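# Match-score computation: per-subject templates, the four distance metrics,
# min-max normalization and arithmetic-mean score-level fusion. All scores
# are dissimilarities: 0 means identical, larger means less similar, and a
# probe is accepted when the fused score falls at or below the threshold.

#' Build a per-subject template from enrollment captures
#'
#' The geometry part stores the per-feature mean and the RMS deviation from
#' that mean across the enrollment captures (floored at `sigma_floor`, which
#' keeps the Hamming gate usable when captures coincide). The vein part
#' stores the first enrollment capture's minutiae set as the reference all
#' later probes are compared against.
#'
#' @param features List (or matrix rows) of >= 2 enrollment feature vectors.
#' @param minutiae List of the corresponding [minutiae_set()] objects.
#' @param subject_id Identifier stored in the template.
#' @param sigma_floor Lower bound for the per-feature RMS spread.
#' @return Object of class `hv_template` with fields `subject_id`,
#'   `feature_means`, `feature_sigmas`, `reference_minutiae`, `n_enroll`.
#' @export
build_template <- function(features, minutiae, subject_id = "subject",
                           sigma_floor = 0.5) {
  if (is.matrix(features)) {
    features <- lapply(seq_len(nrow(features)), function(i) features[i, ])
  }
  if (length(features) < 2L) {
    hv_stop("at least 2 enrollment captures are required", "enrollment")
  }
  lens <- vapply(features, length, integer(1))
  if (length(unique(lens)) != 1L) {
    hv_stop("enrollment feature vectors differ in length", "enrollment")
  }
  x <- do.call(rbind, features)
  means <- colMeans(x)
  sigmas <- sqrt(colMeans(sweep(x, 2, means)^2))
  sigmas <- pmax(sigmas, sigma_floor)
  if (length(minutiae) < 1L || !inherits(minutiae[[1L]], "minutiae_set")) {
    hv_stop("at least one enrollment minutiae_set is required", "enrollment")
  }
  structure(list(subject_id = subject_id,
                 feature_means = means,
                 feature_sigmas = sigmas,
                 reference_minutiae = minutiae[[1L]],
                 n_enroll = length(features)),
            class = "hv_template")
}

#' Euclidean distance between a probe vector and template means
#'
#' @param x Probe feature vector.
#' @param t Template feature means (same length).
#' @return Non-negative scalar.
#' @export
euclidean_distance <- function(x, t) {
  if (length(x) != length(t)) {
    hv_stop("feature vectors differ in length", "parameter")
  }
  sqrt(sum((x - t)^2))
}

#' RMS-gated Hamming distance
#'
#' Counts the features whose deviation from the template mean strictly
#' exceeds the template's per-feature RMS spread: the number of
#' "non-unanimous" characteristics. Bounded by the feature count (62).
#'
#' @param x Probe feature vector.
#' @param template An `hv_template` (or a list with `feature_means` and
#'   `feature_sigmas`).
#' @return Integer count.
#' @export
hamming_distance <- function(x, template) {
  m <- template$feature_means
  s <- template$feature_sigmas
  if (length(x) != length(m)) {
    hv_stop("feature vectors differ in length", "parameter")
  }
  sum(abs(x - m) > s)
}

minutiae_coords <- function(x) {
  if (inherits(x, "minutiae_set")) {
    cbind(x$points$row, x$points$col)
  } else {
    as.matrix(x)[, 1:2, drop = FALSE]
  }
}

# all pairwise distances between two n x 2 point sets
cross_dist <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2)
}

check_nonempty_sets <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    hv_stop("point sets must be non-empty", "empty_set")
  }
}

#' Oriented Hausdorff distance
#'
#' `max over x in A of (min over y in B of ||x - y||)`: the farthest any
#' point of A sits from the set B. Asymmetric. Minutia kind is ignored; only
#' coordinates enter.
#'
#' @param a,b Minutiae sets ([minutiae_set()]) or n x 2 coordinate matrices;
#'   both non-empty.
#' @return Non-negative scalar.
#' @export
hausdorff_oriented <- function(a, b) {
  pa <- minutiae_coords(a); pb <- minutiae_coords(b)
  check_nonempty_sets(pa, pb)
  max(apply(cross_dist(pa, pb), 1, min))
}

#' Non-oriented (symmetric) Hausdorff distance
#'
#' The maximum of the two oriented distances. Very sensitive to a single
#' outlying point.
#'
#' @inheritParams hausdorff_oriented
#' @return Non-negative scalar.
#' @export
hausdorff <- function(a, b) {
  pa <- minutiae_coords(a); pb <- minutiae_coords(b)
  check_nonempty_sets(pa, pb)
  d <- cross_dist(pa, pb)
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

#' Modified Hausdorff distance
#'
#' Replaces the max in the oriented distance by the average nearest-neighbor
#' distance, `d(A,B) = (1/|A|) * sum over x in A of min over y in B ||x-y||`,
#' which suppresses the influence of isolated outliers. The returned score is
#' symmetrized as the maximum of the two directed averages.
#'
#' @inheritParams hausdorff_oriented
#' @return Non-negative scalar.
#' @export
mhv <- function(a, b) {
  pa <- minutiae_coords(a); pb <- minutiae_coords(b)
  check_nonempty_sets(pa, pb)
  d <- cross_dist(pa, pb)
  max(mean(apply(d, 1, min)), mean(apply(d, 2, min)))
}

# Translation registration: shift a point set to its centroid. The study
# scanner fixed the hand pose, making registration implicit; free poses need
# it before the point-set metrics.
center_minutiae <- function(x) {
  p <- minutiae_coords(x)
  sweep(p, 2, colMeans(p))
}

#' Min-max normalization of a score batch
#'
#' Maps a batch of raw scores affinely onto [0, 1]: the batch minimum to 0
#' and the maximum to 1. Invariant to affine transforms of the batch.
#'
#' @param scores Numeric vector with at least 2 distinct values.
#' @return Numeric vector in [0, 1].
#' @export
min_max_normalize <- function(scores) {
  if (length(scores) < 2L) {
    hv_stop("need at least 2 scores to normalize", "degenerate_batch")
  }
  rng <- range(scores)
  if (rng[1] == rng[2]) {
    hv_stop("all scores identical; min-max normalization undefined",
            "degenerate_batch")
  }
  (scores - rng[1]) / (rng[2] - rng[1])
}

#' Fuse normalized modality scores and decide
#'
#' The fused score is the arithmetic mean of the two normalized modality
#' scores. Scores are distances, so the claim is accepted when the fused
#' score is less than or equal to the threshold (a fused score of exactly
#' the threshold accepts).
#'
#' @param geometry_norm Normalized hand-geometry score in [0, 1].
#' @param vein_norm Normalized vein score in [0, 1].
#' @param threshold Accept threshold, default 0.5.
#' @return List with `fused` (numeric) and `accept` (logical).
#' @export
fuse_and_decide <- function(geometry_norm, vein_norm, threshold = 0.5) {
  for (v in c(geometry_norm, vein_norm)) {
    if (!is.finite(v) || v < 0 || v > 1) {
      hv_stop("normalized scores must lie in [0, 1]", "parameter")
    }
  }
  fused <- (geometry_norm + vein_norm) / 2
  list(fused = fused, accept = fused <= threshold)
}

#' Raw modality scores of a probe against a template
#'
#' Computes all four raw distances for one probe/template pair; minutiae
#' sets are centroid-aligned first when `align` is TRUE.
#'
#' @param features Probe feature vector.
#' @param minutiae Probe [minutiae_set()].
#' @param template An `hv_template`.
#' @param align Centroid-align minutiae before the point-set metrics.
#' @return Named list: `euclidean`, `hamming`, `hv`, `mhv`.
#' @export
score_pair <- function(features, minutiae, template, align = TRUE) {
  pa <- minutiae_coords(minutiae)
  pb <- minutiae_coords(template$reference_minutiae)
  if (align && nrow(pa) > 0L && nrow(pb) > 0L) {
    pa <- sweep(pa, 2, colMeans(pa))
    pb <- sweep(pb, 2, colMeans(pb))
  }
  list(euclidean = euclidean_distance(features, template$feature_means),
       hamming = hamming_distance(features, template),
       hv = hausdorff(pa, pb),
       mhv = mhv(pa, pb))
}
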