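# Brute-force oracles, kept deliberately naive and independent of the
# implementation paths they check.

o_pad <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  m[c(rep(1, k), 1:n, rep(n, k)), c(rep(1, k), 1:p, rep(p, k)), drop = FALSE]
}

# windowed statistic by explicit double loop
o_window_stat <- function(img, w, stat) {
  k <- (w - 1) / 2
  p <- o_pad(img, k)
  out <- matrix(0, nrow(img), ncol(img))
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      out[i, j] <- stat(p[i:(i + 2 * k), j:(j + 2 * k)])
    }
  }
  out
}

o_mean_filter <- function(img, w) {
  o_window_stat(img, w, function(nb) floor(mean(nb) + 0.5))
}

o_median_filter <- function(img, w) {
  o_window_stat(img, w, function(nb) stats::median(as.vector(nb)))
}

o_local_threshold <- function(img, w, t_g) {
  mu <- o_window_stat(img, w, mean)
  (img >= mu - t_g) * 1
}

# O(n^3) convex hull: a point is a hull vertex iff some line through it
# keeps all other points strictly on one side (handles it by testing every
# pair-defined direction).
o_hull_vertices <- function(pts) {
  n <- nrow(pts)
  on_hull <- rep(FALSE, n)
  for (i in 1:n) {
    for (j in 1:n) {
      if (i == j) next
      d <- pts[j, ] - pts[i, ]
      side <- sapply(seq_len(n), function(k) {
        if (k %in% c(i, j)) return(0)
        v <- pts[k, ] - pts[i, ]
        d[1] * v[2] - d[2] * v[1]
      })
      if (all(side >= 0) || all(side <= 0)) {
        on_hull[i] <- TRUE
        break
      }
    }
  }
  pts[on_hull, , drop = FALSE]
}

pts_key <- function(p) sort(paste(round(p[, 1], 6), round(p[, 2], 6)))

o_hausdorff_oriented <- function(a, b) {
  worst <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
    worst <- max(worst, best)
  }
  worst
}

o_hausdorff <- function(a, b) {
  max(o_hausdorff_oriented(a, b), o_hausdorff_oriented(b, a))
}

o_mhv <- function(a, b) {
  davg <- function(x, y) {
    mean(sapply(seq_len(nrow(x)), function(i) {
      min(sapply(seq_len(nrow(y)), function(j) sqrt(sum((x[i, ] - y[j, ])^2))))
    }))
  }
  max(davg(a, b), davg(b, a))
}

# crossing number as the count of maximal runs of 1s around the cyclic
# 8-neighborhood (an independent formulation of the transition count)
o_crossing_number <- function(nb) {
  # nb: 8 values ordered N, NE, E, SE, S, SW, W, NW
  if (all(nb == 0)) return(0L)
  if (all(nb == 1)) return(0L)  # fully surrounded: no transitions
  # rotate so the sequence starts at a 0, then count runs of 1s
  z <- which(nb == 0)[1]
  rot <- c(nb[z:8], nb[seq_len(z - 1)])
  sum(rle(rot)$values == 1)
}

# random blob mask: thresholded smoothed noise, closed and stripped of
# fragments below the thinning scale. Thinning statements are about blob
# objects: sub-scale speckle (e.g. an isolated 2x2 square, which any
# thinning deletes outright) is not a blob.
random_blob <- function(seed, n = 40, frac = 0.3) {
  set.seed(seed)
  z <- matrix(stats::rnorm(n * n), n, n)
  for (r in 1:3) {
    z <- o_pad(z, 1)
    z <- (z[1:n, 1:n] + z[1:n, 2:(n + 1)] + z[1:n, 3:(n + 2)] +
            z[2:(n + 1), 1:n] + z[2:(n + 1), 2:(n + 1)] +
            z[2:(n + 1), 3:(n + 2)] + z[3:(n + 2), 1:n] +
            z[3:(n + 2), 2:(n + 1)] + z[3:(n + 2), 3:(n + 2)]) / 9
  }
  mask <- (z > stats::quantile(z, 1 - frac)) * 1L
  mask <- close_mask(mask, 1)
  lab <- label_components(mask)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    mask[lab %in% which(sizes < 20)] <- 0L
  }
  mask
}

random_point_set <- function(n, lim = 100) {
  cbind(stats::runif(n, 1, lim), stats::runif(n, 1, lim))
}

# continuous coordinates: with probability one no three points are
# collinear, so the minimal hull vertex set is unambiguous
random_position_set <- function(n, lim = 60) {
  cbind(stats::runif(n, 0, lim), stats::runif(n, 0, lim))
}

# match two point sets at a radius; returns recall and precision
match_minutiae <- function(det, gt, radius = 3) {
  if (nrow(det) == 0L || nrow(gt) == 0L) {
    return(c(recall = 0, precision = 0, n_gt = nrow(gt), n_det = nrow(det)))
  }
  d <- sqrt(outer(det[, 1], gt[, 1], "-")^2 + outer(det[, 2], gt[, 2], "-")^2)
  c(recall = mean(apply(d, 2, min) <= radius),
    precision = mean(apply(d, 1, min) <= radius),
    n_gt = nrow(gt), n_det = nrow(det))
}
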