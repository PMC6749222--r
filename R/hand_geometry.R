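# Hand-contour landmark detection and the 62-feature geometry vector.
#
# Points are numeric c(row, col); point sequences are n x 2 matrices with
# columns (row, col). The feature vector layout (fixed, length 62):
#   L1..L5              finger lengths, thumb -> pinky            (5)
#   W<k>_<s>            10 width stations per finger, 5%..95%
#                       of the tip->base axis, tip side first     (50)
#   TD23, TD34, TD45    adjacent fingertip gaps, thumb-index
#                       pair excluded                             (3)
#   VD12, VD23, VD34    adjacent finger-valley gaps               (3)
#   L6                  palm width through the palm center        (1)

HV_N_FEATURES <- 62L

pt_dist <- function(a, b) sqrt(sum((a - b)^2))

# Clockwise 8-neighborhood cycle in image coordinates (row grows downward):
# N, NE, E, SE, S, SW, W, NW.
MOORE8 <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                dc = c(0, 1, 1, 1, 0, -1, -1, -1))

#' Trace the boundary of the largest object (Moore boundary tracing)
#'
#' Extracts the largest 8-connected component and walks its outer boundary
#' clockwise starting from the topmost-leftmost object pixel. Consecutive
#' contour points are 8-adjacent and the sequence is cyclic.
#'
#' @param mask Binary image matrix with at least one object pixel.
#' @return n x 2 matrix of (row, col) boundary points.
#' @export
trace_contour <- function(mask) {
  assert_binary(mask)
  comp <- largest_component(mask)  # errors on empty mask
  n <- nrow(comp); m <- ncol(comp)
  fg <- which(comp == 1)
  rows <- (fg - 1L) %% n + 1L
  cols <- (fg - 1L) %/% n + 1L
  r0 <- min(rows)
  c0 <- min(cols[rows == r0])
  start <- c(r0, c0)
  at <- function(p) {
    p[1] >= 1 && p[1] <= n && p[2] >= 1 && p[2] <= m && comp[p[1], p[2]] == 1
  }
  # Backtrack begins at the W neighbor (background by choice of start pixel).
  pts <- matrix(start, 1L, 2L)
  cur <- start
  dir <- 7L  # index into MOORE8 pointing W (1-based 7)
  first_next <- NULL
  repeat {
    found <- FALSE
    for (s in 0:7) {
      d <- (dir - 1L + s) %% 8L + 1L
      cand <- cur + MOORE8[d, ]
      if (at(cand)) {
        # new backtrack: one step counterclockwise from the found direction
        dir <- (d - 2L + 7L) %% 8L + 1L
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated single pixel
    if (is.null(first_next)) {
      first_next <- cur
    } else if (all(cur == start) ) {
      # closed the loop; stop before repeating the start
      break
    }
    pts <- rbind(pts, cur)
    if (nrow(pts) > 4L * (n * m)) {
      hv_stop("contour tracing failed to terminate", "segmentation")
    }
  }
  # drop a duplicated closing point if present
  if (nrow(pts) > 1L && all(pts[nrow(pts), ] == pts[1L, ])) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  dimnames(pts) <- NULL
  pts
}

#' Convex hull of a contour
#'
#' Vertices of the convex polygon containing all contour points, returned in
#' counterclockwise order (with column as x and row as y growing downward)
#' with attribute `"contour_index"` giving each vertex's position along the
#' contour.
#'
#' @param contour n x 2 matrix of (row, col) points.
#' @return m x 2 matrix of hull vertices.
#' @export
convex_hull <- function(contour) {
  if (!is.matrix(contour) || ncol(contour) != 2L || nrow(contour) < 3L) {
    hv_stop("contour must be an n x 2 matrix with n >= 3", "parameter")
  }
  idx <- grDevices::chull(contour[, 2], contour[, 1])
  if (length(idx) < 3L) {
    hv_stop("contour points are collinear; convex hull is degenerate",
            "degenerate")
  }
  hull <- contour[idx, , drop = FALSE]
  # enforce a fixed orientation via the shoelace sign (x = col, y = row)
  x <- hull[, 2]; y <- hull[, 1]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (area2 < 0) {
    hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
    idx <- rev(idx)
  }
  dimnames(hull) <- NULL
  attr(hull, "contour_index") <- idx
  hull
}

point_segment_depth <- function(p, a, b) {
  # perpendicular distance of point p from the line through a, b
  ab <- b - a
  len <- sqrt(sum(ab^2))
  if (len == 0) return(pt_dist(p, a))
  abs((b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])) / len
}

#' Convexity defects of a contour
#'
#' For every hull edge, finds the contour point between its endpoints with
#' the maximum perpendicular distance to the edge (the defect depth) and
#' keeps defects at least `min_depth` deep. On a fingers-up hand the
#' surviving defects are the valleys between fingers.
#'
#' @param contour n x 2 matrix from [trace_contour()].
#' @param hull Hull matrix from [convex_hull()] (of the same contour).
#' @param min_depth Minimum depth in pixels for a defect to be kept.
#' @return data.frame with columns `row`, `col`, `depth`, ordered left to
#'   right (thumb side first on a fingers-up right-hand dorsum); may have
#'   zero rows.
#' @export
convexity_defects <- function(contour, hull, min_depth = 20) {
  idx <- attr(hull, "contour_index")
  if (is.null(idx)) {
    key <- paste(contour[, 1], contour[, 2])
    idx <- match(paste(hull[, 1], hull[, 2]), key)
    if (anyNA(idx)) hv_stop("hull vertices not found on contour", "parameter")
  }
  idx <- sort(unique(idx))
  n <- nrow(contour)
  out <- NULL
  for (k in seq_along(idx)) {
    i1 <- idx[k]
    i2 <- if (k < length(idx)) idx[k + 1L] else idx[1L]
    between <- if (k < length(idx)) {
      if (i2 - i1 > 1L) (i1 + 1L):(i2 - 1L) else integer(0)
    } else {
      # wrap-around segment
      c(if (i1 < n) (i1 + 1L):n else integer(0),
        if (i2 > 1L) 1L:(i2 - 1L) else integer(0))
    }
    if (length(between) == 0L) next
    a <- contour[i1, ]; b <- contour[i2, ]
    depths <- vapply(between, function(i) {
      point_segment_depth(contour[i, ], a, b)
    }, numeric(1))
    dmax <- max(depths)
    if (dmax >= min_depth) {
      p <- contour[between[which.max(depths)], ]
      out <- rbind(out, c(p, dmax))
    }
  }
  if (is.null(out)) {
    return(data.frame(row = numeric(0), col = numeric(0), depth = numeric(0)))
  }
  out <- data.frame(row = out[, 1], col = out[, 2], depth = out[, 3])
  out[order(out$col), , drop = FALSE]
}

cyclic_index <- function(i, n) (i - 1L) %% n + 1L

# A convexity defect under a tilted hull chord lands on a corner of the
# inter-finger gap, not its center. Re-center each valley on the gap floor:
# take the contour points around the defect lying within 3 px of the local
# deepest row and report the midpoint of their column extent.
refine_valleys <- function(contour, defects, halfwin = 40L) {
  n <- nrow(contour)
  key <- paste(contour[, 1], contour[, 2])
  out <- defects
  for (i in seq_len(nrow(defects))) {
    di <- match(paste(defects$row[i], defects$col[i]), key)
    if (is.na(di)) next
    win <- cyclic_index(di + (-halfwin:halfwin), n)
    pts <- contour[win, , drop = FALSE]
    floor_pts <- pts[pts[, 1] >= max(pts[, 1]) - 3, , drop = FALSE]
    out$row[i] <- mean(floor_pts[, 1])
    out$col[i] <- (min(floor_pts[, 2]) + max(floor_pts[, 2])) / 2
  }
  out[order(out$col), , drop = FALSE]
}

#' Locate the five fingertips
#'
#' Clusters hull vertices (a new cluster starts where the gap between
#' consecutive vertices exceeds `cluster_gap` pixels), keeps the clusters
#' above the palm center, and — if more than five remain — the five farthest
#' from it. Within each cluster the fingertip is the contour point of
#' maximum curvature: the point minimizing the angle between the two contour
#' direction vectors `k` points away on either side.
#'
#' @param contour n x 2 contour matrix (fingers-up orientation).
#' @param hull Hull from [convex_hull()].
#' @param palm_center Numeric c(row, col).
#' @param cluster_gap Gap (px) separating fingertip clusters.
#' @param k Curvature window: offset (in contour points) of the direction
#'   vectors.
#' @return 5 x 2 matrix of fingertip (row, col), ordered thumb -> pinky
#'   (left to right).
#' @export
detect_fingertips <- function(contour, hull, palm_center,
                              cluster_gap = 10, k = 15L) {
  idx <- attr(hull, "contour_index")
  ord <- order(idx)
  idx <- idx[ord]
  pts <- hull[ord, , drop = FALSE]
  m <- nrow(pts)
  # split into clusters along the (cyclic) contour order
  gaps <- vapply(seq_len(m), function(i) {
    pt_dist(pts[i, ], pts[cyclic_index(i + 1L, m), ])
  }, numeric(1))
  cl <- cumsum(c(1, as.integer(gaps[-m] > cluster_gap)))
  if (gaps[m] <= cluster_gap && max(cl) > 1L) {
    cl[cl == max(cl)] <- 1L  # merge wrap-around cluster
  }
  clusters <- split(seq_len(m), cl)
  info <- lapply(clusters, function(ii) {
    cpts <- pts[ii, , drop = FALSE]
    list(members = ii,
         centroid = colMeans(cpts),
         dist = max(apply(cpts, 1, pt_dist, b = palm_center)))
  })
  above <- Filter(function(x) x$centroid[1] < palm_center[1], info)
  if (length(above) < 5L) {
    hv_stop(sprintf("expected 5 fingertip clusters above the palm center, found %d",
                    length(above)), "detection")
  }
  n <- nrow(contour)
  cand_tips <- t(vapply(above, function(x) {
    ci <- sort(idx[x$members])
    span <- if (max(ci) - min(ci) <= n / 2) {
      min(ci):max(ci)
    } else {  # cluster wraps the contour start
      wrap <- ci[ci > n / 2]
      head <- ci[ci <= n / 2]
      c(min(wrap):n, 1L:max(head))
    }
    # the hull touches only part of a rounded cap (the edge to a taller
    # neighbor leaves the cap before its apex); widen the search so the
    # whole cap is considered
    ext <- k + 10L
    span <- unique(cyclic_index(c(span[1] - (ext:1), span,
                                  span[length(span)] + (1:ext)), n))
    ang <- vapply(span, function(i) {
      p <- contour[i, ]
      v1 <- contour[cyclic_index(i - k, n), ] - p
      v2 <- contour[cyclic_index(i + k, n), ] - p
      den <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
      if (den == 0) return(pi)
      acos(max(-1, min(1, sum(v1 * v2) / den)))
    }, numeric(1))
    # a rounded tip has constant curvature along its cap, so the raw argmin
    # is decided by pixel jitter; break near-ties toward the cap apex (the
    # center of the topmost contour band of the whole cap)
    rows_span <- contour[span, 1]
    band <- span[rows_span <= min(rows_span) + 1]
    apex <- c(min(contour[band, 1]),
              (min(contour[band, 2]) + max(contour[band, 2])) / 2)
    cand <- span[ang <= min(ang) + 0.12]
    d2 <- (contour[cand, 1] - apex[1])^2 + (contour[cand, 2] - apex[2])^2
    contour[cand[which.min(d2)], ]
  }, numeric(2)))
  # a shallow cap can split into two hull clusters that both resolve to the
  # same tip; keep the 5 farthest mutually distinct tips
  dists <- vapply(above, `[[`, numeric(1), "dist")
  ord <- order(dists, decreasing = TRUE)
  tips <- NULL
  for (i in ord) {
    tp <- cand_tips[i, ]
    if (!is.null(tips) &&
        any(sqrt((tips[, 1] - tp[1])^2 + (tips[, 2] - tp[2])^2) < 15)) next
    tips <- rbind(tips, tp)
    if (nrow(tips) == 5L) break
  }
  if (is.null(tips) || nrow(tips) < 5L) {
    hv_stop("could not resolve 5 distinct fingertips", "detection")
  }
  tips <- tips[order(tips[, 2]), , drop = FALSE]
  dimnames(tips) <- NULL
  tips
}

#' Finger base point from the neighboring valleys
#'
#' The middle and ring fingers take the midpoint of their two adjacent
#' valleys. The thumb, index and pinky have only one reliable adjacent
#' valley; that valley is reflected across the finger axis (the vertical
#' line through the fingertip after pose normalization) and the midpoint of
#' valley and reflection is used, i.e. the base sits on the axis at the
#' valley's height.
#'
#' @param valleys 4 x 2 matrix or data.frame of valley points (row, col),
#'   ordered thumb side -> pinky side.
#' @param finger_index 1 (thumb) .. 5 (pinky).
#' @param fingertip Numeric c(row, col); required for fingers 1, 2 and 5.
#' @return Numeric c(row, col) base point.
#' @export
finger_base <- function(valleys, finger_index, fingertip = NULL) {
  v <- as.matrix(valleys)[, c("row", "col"), drop = FALSE]
  storage.mode(v) <- "numeric"
  if (nrow(v) < 4L) hv_stop("4 valley points are required", "detection")
  if (!finger_index %in% 1:5) {
    hv_stop("`finger_index` must be in 1..5", "parameter")
  }
  if (finger_index == 3L) return(unname((v[2L, ] + v[3L, ]) / 2))
  if (finger_index == 4L) return(unname((v[3L, ] + v[4L, ]) / 2))
  if (is.null(fingertip)) {
    hv_stop("`fingertip` is required for thumb, index and pinky bases",
            "parameter")
  }
  vk <- switch(as.character(finger_index), "1" = v[1L, ], "2" = v[2L, ],
               "5" = v[4L, ])
  c(vk[[1]], fingertip[[2]])
}

# March from point p along unit direction u (both (row, col)) while inside
# the mask; returns the arc length covered, in steps of `step` px.
march_extent <- function(mask, p, u, step = 0.25, max_len = 400) {
  n <- nrow(mask); m <- ncol(mask)
  t <- 0
  repeat {
    t2 <- t + step
    q <- round(p + t2 * u)
    if (q[1] < 1 || q[1] > n || q[2] < 1 || q[2] > m || mask[q[1], q[2]] != 1) {
      return(t)
    }
    t <- t2
    if (t > max_len) return(t)
  }
}

line_extent <- function(mask, p, u, step = 0.25) {
  march_extent(mask, p, u, step) + march_extent(mask, p, -u, step)
}

# Width of the mask along direction u through p, averaged over three
# parallel scan lines (offset +/-1 px along `axis`) to smooth raster
# stair-stepping. With the hand threshold at the blur half-intensity level
# the mask edge tracks the true object boundary, so no pixel-support
# correction is needed.
band_width <- function(mask, p, u, axis) {
  ext <- vapply(c(-1, 0, 1), function(d) {
    line_extent(mask, p + d * axis, u)
  }, numeric(1))
  mean(ext)
}

#' Measure the hand-geometry feature vector
#'
#' Computes the fixed-order 62-feature vector: five finger lengths (tip to
#' base), ten width stations per finger (mask extent along the perpendicular
#' at 5%, 15%, ..., 95% of the tip->base axis, measured from the tip), the
#' three adjacent fingertip gaps excluding the thumb-index pair, the three
#' adjacent valley gaps, and the palm width (mask extent through the palm
#' center perpendicular to the middle-finger axis).
#'
#' @param mask Binary hand mask (fingers up).
#' @param landmarks List with elements `fingertips` (5 x 2), `valleys`
#'   (data.frame row/col, 4 rows), `palm_center` c(row, col) and
#'   `finger_bases` (5 x 2), as produced by [detect_landmarks()].
#' @return Named numeric vector of length 62.
#' @export
measure_hand <- function(mask, landmarks) {
  assert_binary(mask)
  tips <- landmarks$fingertips
  bases <- landmarks$finger_bases
  pc <- landmarks$palm_center
  v <- as.matrix(landmarks$valleys[, c("row", "col")])
  if (nrow(tips) != 5L || nrow(bases) != 5L || nrow(v) != 4L) {
    hv_stop("landmarks must contain 5 fingertips, 5 bases and 4 valleys",
            "detection")
  }
  fractions <- seq(0.05, 0.95, by = 0.10)
  lengths <- numeric(5)
  widths <- matrix(NA_real_, 5, 10)
  for (kf in 1:5) {
    tip <- tips[kf, ]; base <- bases[kf, ]
    L <- pt_dist(tip, base)
    lengths[kf] <- L
    if (L == 0) hv_stop("degenerate finger axis", "measurement")
    a <- (base - tip) / L
    perp <- c(-a[2], a[1])
    for (s in seq_along(fractions)) {
      p <- tip + fractions[s] * L * a
      q <- round(p)
      if (q[1] < 1 || q[1] > nrow(mask) || q[2] < 1 || q[2] > ncol(mask) ||
          mask[q[1], q[2]] != 1) {
        hv_stop(sprintf("finger %d axis leaves the mask at station %d", kf, s),
                "measurement")
      }
      widths[kf, s] <- band_width(mask, p, perp, a)
    }
  }
  tip_d <- c(pt_dist(tips[2, ], tips[3, ]),
             pt_dist(tips[3, ], tips[4, ]),
             pt_dist(tips[4, ], tips[5, ]))
  val_d <- c(pt_dist(v[1, ], v[2, ]),
             pt_dist(v[2, ], v[3, ]),
             pt_dist(v[3, ], v[4, ]))
  # middle-finger axis is the pose-normalized vertical; palm width is the
  # horizontal extent through the palm center
  mid_axis <- (bases[3, ] - tips[3, ])
  mid_axis <- mid_axis / sqrt(sum(mid_axis^2))
  palm_w <- band_width(mask, pc, c(-mid_axis[2], mid_axis[1]), mid_axis)
  feats <- c(lengths, as.vector(t(widths)), tip_d, val_d, palm_w)
  names(feats) <- hv_feature_names()
  feats
}

hv_feature_names <- function() {
  c(paste0("L", 1:5),
    as.vector(t(outer(1:5, 1:10, function(f, s) sprintf("W%d_%d", f, s)))),
    c("TD23", "TD34", "TD45"),
    c("VD12", "VD23", "VD34"),
    "L6")
}

#' Estimate hand orientation and rotate to fingers-up pose
#'
#' The dominant axis of the foreground pixels (principal component of their
#' coordinates) is aligned with the vertical by the smallest rotation. The
#' capture protocol presents the hand fingers-up within +/-10 degrees, so
#' the minimal rotation never flips the hand.
#'
#' @param mask Binary hand mask.
#' @param gray Optional gray image rotated together with the mask.
#' @return List with `mask`, `gray` (NULL if not supplied), `angle` (degrees
#'   the input was rotated by) and `center` (rotation center, row/col).
#' @export
normalize_pose <- function(mask, gray = NULL) {
  assert_binary(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0L) hv_stop("mask contains no foreground pixels", "segmentation")
  cen <- colMeans(fg)
  cc <- stats::cov(fg)
  ev <- eigen(cc, symmetric = TRUE)
  major <- ev$vectors[, 1]  # (row, col) direction
  ang <- atan2(major[2], major[1]) * 180 / pi  # 0 = vertical (row axis)
  # fold into (-90, 90], then take the minimal rotation to vertical
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  rot <- -ang
  out_mask <- rotate_nn(mask, rot, cen, fill = 0)
  out_gray <- if (!is.null(gray)) rotate_nn(gray, rot, cen, fill = 0) else NULL
  list(mask = out_mask, gray = out_gray, angle = rot, center = cen)
}

# Nearest-neighbor rotation by `angle` degrees about `center` (row, col).
rotate_nn <- function(img, angle, center, fill = 0) {
  if (angle == 0) return(img)
  n <- nrow(img); m <- ncol(img)
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  rr <- matrix(seq_len(n), n, m) - center[1]
  cc <- matrix(seq_len(m), n, m, byrow = TRUE) - center[2]
  # inverse mapping: source = R(-angle) %*% dest
  sr <- round(co * rr + si * cc + center[1])
  sc <- round(-si * rr + co * cc + center[2])
  ok <- sr >= 1 & sr <= n & sc >= 1 & sc <= m
  out <- matrix(fill, n, m)
  out[ok] <- img[cbind(sr[ok], sc[ok])]
  out
}

#' Detect all hand landmarks on a pose-normalized mask
#'
#' Runs contour tracing, convex hull, convexity-defect valley detection,
#' fingertip localization and finger-base construction. Expects a single
#' fingers-up hand silhouette.
#'
#' @param mask Binary hand mask (fingers up, already pose-normalized).
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return List with `fingertips` (5 x 2), `valleys` (data.frame, 4 rows),
#'   `palm_center`, `finger_bases` (5 x 2), plus the `contour` and `hull`.
#' @export
detect_landmarks <- function(mask, config = pipeline_config()) {
  contour <- trace_contour(mask)
  hull <- convex_hull(contour)
  fg <- which(mask == 1, arr.ind = TRUE)
  centroid <- colMeans(fg)
  defects <- convexity_defects(contour, hull, min_depth = config$min_depth)
  defects <- defects[defects$row < centroid[1], , drop = FALSE]
  if (nrow(defects) < 4L) {
    hv_stop(sprintf("expected 4 finger valleys, found %d", nrow(defects)),
            "detection")
  }
  if (nrow(defects) > 4L) {
    defects <- defects[order(defects$depth, decreasing = TRUE)[1:4], ]
    defects <- defects[order(defects$col), ]
  }
  valleys <- refine_valleys(contour, defects)
  # palm center: midway between the valley line and the wrist end of the
  # mask, centered on the valleys (the whole-mask centroid sits too high,
  # pulled up by the fingers)
  palm_center <- c((max(valleys$row) + max(fg[, 1])) / 2, mean(valleys$col))
  tips <- detect_fingertips(contour, hull, palm_center,
                            cluster_gap = config$cluster_gap,
                            k = config$curvature_k)
  bases <- t(vapply(1:5, function(kf) {
    finger_base(valleys, kf, fingertip = tips[kf, ])
  }, numeric(2)))
  list(fingertips = tips, valleys = valleys, palm_center = palm_center,
       finger_bases = bases, contour = contour, hull = hull)
}
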