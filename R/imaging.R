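# Shared preprocessing and segmentation primitives.
#
# Images are plain R matrices indexed [row, col], row 1 at the top. A gray
# image holds integer intensities in 0..255; a binary image holds 0/1 with
# 1 = object of interest. All neighborhood operations replicate edge pixels,
# which avoids spurious dark frames that would fool the mean-based thresholds.

assert_gray <- function(img, name = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    hv_stop(sprintf("`%s` must be a numeric matrix", name), "parameter")
  }
  if (anyNA(img) || min(img) < 0 || max(img) > 255) {
    hv_stop(sprintf("`%s` must hold intensities in [0, 255]", name), "parameter")
  }
  invisible(img)
}

assert_binary <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    hv_stop(sprintf("`%s` must be a numeric matrix", name), "parameter")
  }
  if (anyNA(mask) || !all(mask == 0 | mask == 1)) {
    hv_stop(sprintf("`%s` must be a binary 0/1 matrix", name), "parameter")
  }
  invisible(mask)
}

# Replicate the border `k` pixels outward on every side.
pad_replicate <- function(m, k) {
  n <- nrow(m); p <- ncol(m)
  m[c(rep(1L, k), seq_len(n), rep(n, k)),
    c(rep(1L, k), seq_len(p), rep(p, k)), drop = FALSE]
}

# Windowed sums over a w x w neighborhood with edge replication, computed
# with a summed-area table; exact for integer-valued inputs.
box_sum <- function(img, w) {
  k <- (w - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  p <- pad_replicate(img, k)
  s <- apply(p, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  ss <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
  ss[-1L, -1L] <- s
  ri <- seq_len(n); ci <- seq_len(m)
  ss[ri + w, ci + w, drop = FALSE] - ss[ri, ci + w, drop = FALSE] -
    ss[ri + w, ci, drop = FALSE] + ss[ri, ci, drop = FALSE]
}

box_mean <- function(img, w) box_sum(img, w) / (w * w)

#' Mean (averaging) filter
#'
#' Replaces every pixel by the arithmetic mean of its `core_size` x
#' `core_size` neighborhood (the classic 3 x 3 averaging core, generalized to
#' any odd size). Borders are handled by edge replication and the output is
#' rounded to the nearest integer, ties away from zero.
#'
#' @param img Gray image matrix, intensities in 0..255.
#' @param core_size Odd integer >= 3, side length of the averaging core.
#' @return Gray image matrix of the same dimensions.
#' @export
#' @examples
#' m <- matrix(0, 3, 3); m[2, 2] <- 9
#' mean_filter(m, 3)[2, 2]  # 1
mean_filter <- function(img, core_size = 3L) {
  assert_gray(img)
  core_size <- assert_odd_window(core_size, "core_size")
  out <- floor(box_mean(img, core_size) + 0.5)
  dimnames(out) <- NULL
  out
}

# Stack the w x w neighborhood of every pixel as rows of a (npix x w^2)
# matrix, edge-replicated. Shared by the median filter.
neighborhood_stack <- function(img, w) {
  k <- (w - 1L) %/% 2L
  n <- nrow(img); m <- ncol(img)
  p <- pad_replicate(img, k)
  x <- matrix(0, n * m, w * w)
  col <- 1L
  for (dj in 0:(w - 1L)) {
    for (di in 0:(w - 1L)) {
      x[, col] <- as.vector(p[(1L + di):(n + di), (1L + dj):(m + dj)])
      col <- col + 1L
    }
  }
  x
}

#' Median filter
#'
#' Each output pixel is the median of its `window` x `window` neighborhood
#' (edge replication). Exact for integer images: the median (the k-th order
#' statistic, k = (window^2+1)/2) is found by a per-pixel binary search over
#' the 0..255 intensity range, so large windows stay fast.
#'
#' @param img Gray (or binary) image matrix.
#' @param window Odd integer >= 3.
#' @return Filtered matrix of the same dimensions.
#' @export
median_filter <- function(img, window = 3L) {
  assert_gray(img)
  window <- assert_odd_window(window, "window")
  x <- neighborhood_stack(img, window)
  kth <- (window * window + 1L) %/% 2L
  lo <- rep(0L, nrow(x)); hi <- rep(255L, nrow(x))
  while (any(lo < hi)) {
    mid <- (lo + hi) %/% 2L
    cnt <- rowSums(x <= mid)      # mid recycles per row (column-major)
    ge <- cnt >= kth
    hi[ge] <- mid[ge]
    lo[!ge] <- mid[!ge] + 1L
  }
  matrix(lo, nrow(img), ncol(img))
}

#' Histogram equalization
#'
#' Standard cumulative-histogram equalization stretching the used intensity
#' range to the full 0..255 scale. The mapping is monotone, so pixel rank
#' order is preserved; a constant image is returned unchanged.
#'
#' @param img Gray image matrix.
#' @return Equalized gray image matrix.
#' @export
equalize_histogram <- function(img) {
  assert_gray(img)
  iimg <- matrix(as.integer(round(img)), nrow(img), ncol(img))
  h <- tabulate(iimg + 1L, 256L)
  cdf <- cumsum(h)
  cdf_min <- cdf[which(h > 0L)[1L]]
  n <- length(iimg)
  if (n == cdf_min) return(iimg)  # single intensity level
  map <- as.integer(round((cdf - cdf_min) / (n - cdf_min) * 255))
  matrix(map[iimg + 1L], nrow(img), ncol(img))
}

#' Global mean-based threshold
#'
#' Binarizes with threshold T = mean(all pixels) - `t_g`: output 1 where
#' `img >= T`, else 0. Used to separate the bright hand from the dark matte
#' background.
#'
#' @param img Gray image matrix.
#' @param t_g Constant subtracted from the global mean intensity. Positive
#'   values lower the threshold (more pixels become object).
#' @return Binary image matrix.
#' @export
global_threshold <- function(img, t_g = 0) {
  assert_gray(img)
  (img >= mean(img) - t_g) * 1L
}

#' Local (adaptive) mean threshold
#'
#' Pixel (i, j) becomes object iff `img[i, j] >= mu_ij - t_g`, where `mu_ij`
#' is the mean over the `surrounding` x `surrounding` window centered there
#' (edge replication). With negative `t_g` a pixel must exceed its local mean
#' by `|t_g|` counts, which rejects flat regions; the vein segmentation runs
#' this on the inverted ROI so the darker veins become object.
#'
#' @param img Gray image matrix.
#' @param surrounding Odd window size >= 3.
#' @param t_g Offset subtracted from the local mean.
#' @return Binary image matrix.
#' @export
local_threshold <- function(img, surrounding, t_g = 0) {
  assert_gray(img)
  surrounding <- assert_odd_window(surrounding, "surrounding")
  mu <- box_mean(img, surrounding)
  (img >= mu - t_g) * 1L
}

# discrete disk: pixels whose centers lie within radius + 1/2, so the
# radius-1 element is the full 3 x 3 neighborhood (a plus-shaped element
# cannot bridge diagonal gaps, defeating the closing's purpose)
disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d[d$dr^2 + d$dc^2 <= (radius + 0.5)^2, , drop = FALSE]
}

# Shift a matrix so out[i, j] = m[i + dr, j + dc], filling vacated cells.
shift_matrix <- function(m, dr, dc, fill) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(fill, n, p)
  sr <- max(1L, 1L - dr):min(n, n - dr)
  sc <- max(1L, 1L - dc):min(p, p - dc)
  if (length(sr) > 0L && length(sc) > 0L) {
    out[sr, sc] <- m[sr + dr, sc + dc]
  }
  out
}

#' Binary dilation and erosion with a disk structuring element
#'
#' `dilate()` grows the object by a disk of the given radius; `erode()`
#' shrinks it. Outside the frame, dilation treats pixels as background and
#' erosion treats them as object, so the closing `erode(dilate(x))` is
#' extensive (never loses object pixels) up to the image border. The
#' composition is used to reconnect vein fragments broken by noise.
#'
#' @param mask Binary image matrix.
#' @param radius Positive integer disk radius.
#' @return Binary image matrix.
#' @export
dilate <- function(mask, radius = 1L) {
  assert_binary(mask)
  radius <- as.integer(radius)
  if (radius < 1L) hv_stop("`radius` must be a positive integer", "parameter")
  out <- matrix(0L, nrow(mask), ncol(mask))
  ofs <- disk_offsets(radius)
  for (i in seq_len(nrow(ofs))) {
    out <- out | shift_matrix(mask, ofs$dr[i], ofs$dc[i], 0L)
  }
  out * 1L
}

#' @rdname dilate
#' @export
erode <- function(mask, radius = 1L) {
  assert_binary(mask)
  radius <- as.integer(radius)
  if (radius < 1L) hv_stop("`radius` must be a positive integer", "parameter")
  out <- matrix(1L, nrow(mask), ncol(mask))
  ofs <- disk_offsets(radius)
  for (i in seq_len(nrow(ofs))) {
    out <- out & shift_matrix(mask, ofs$dr[i], ofs$dc[i], 1L)
  }
  out * 1L
}

#' Morphological closing (dilation followed by erosion)
#'
#' @inheritParams dilate
#' @return Binary image matrix containing the input as a subset.
#' @export
close_mask <- function(mask, radius = 1L) erode(dilate(mask, radius), radius)

#' Fill enclosed holes of a binary mask
#'
#' Background regions (4-connected) that do not touch the image border and
#' are at most `max_area` pixels are set to object. An adaptive threshold
#' hollows out the interior of any object wider than its window; filling
#' restores solid regions before skeletonization. The area cap keeps
#' genuine gaps between separate structures open.
#'
#' @param mask Binary image matrix.
#' @param max_area Largest hole area (px) that is filled.
#' @return Binary image matrix with holes filled.
#' @export
fill_holes <- function(mask, max_area = Inf) {
  assert_binary(mask)
  bg <- 1L - mask
  lab <- label_components(bg, connectivity = 4L)
  if (max(lab) == 0L) return(mask)
  border_labs <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                          lab[, ncol(lab)]))
  border_labs <- border_labs[border_labs > 0L]
  sizes <- tabulate(lab[lab > 0L])
  fillable <- setdiff(which(sizes <= max_area), border_labs)
  hole <- lab %in% fillable
  out <- mask
  out[hole] <- 1L
  out
}
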