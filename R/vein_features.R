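# Dorsal-vein minutiae extraction: ROI cut + rotation, vein segmentation,
# Zhang-Suen skeletonization, crossing-number spur pruning, and
# branching/ending minutiae.

#' Construct a minutiae set
#'
#' A minutiae set is a point set of vein branchings and endings inside an
#' ROI frame.
#'
#' @param points data.frame with columns `row`, `col` and `kind`
#'   ("branching" or "ending"); zero rows allowed.
#' @param frame Integer c(height, width) of the ROI the points live in.
#' @return Object of class `minutiae_set`.
#' @export
minutiae_set <- function(points, frame) {
  if (!all(c("row", "col", "kind") %in% names(points))) {
    hv_stop("minutiae points need columns row, col, kind", "parameter")
  }
  if (!all(points$kind %in% c("branching", "ending"))) {
    hv_stop("minutia kind must be 'branching' or 'ending'", "parameter")
  }
  if (nrow(points) > 0) {
    if (any(points$row < 1 | points$row > frame[1] |
            points$col < 1 | points$col > frame[2])) {
      hv_stop("minutiae must lie inside the frame", "parameter")
    }
    if (anyDuplicated(points[, c("row", "col")])) {
      hv_stop("duplicate minutia coordinates", "parameter")
    }
  }
  structure(list(points = points, frame = as.integer(frame)),
            class = "minutiae_set")
}

#' @export
print.minutiae_set <- function(x, ...) {
  cat(sprintf("<minutiae_set: %d branching, %d ending, frame %dx%d>\n",
              sum(x$points$kind == "branching"),
              sum(x$points$kind == "ending"), x$frame[1], x$frame[2]))
  invisible(x)
}

#' Cut and rotate the dorsum region of interest
#'
#' The ROI starts at the finger-joint level: its top edge spans valley 2 to
#' valley 4 (valleys numbered 1-4 from the thumb side), its width is that
#' distance and its height extends 1.4 x width toward the wrist. The crop is
#' resampled so the long (vein) axis is vertical.
#'
#' @param img Gray image (pose-normalized).
#' @param landmarks Landmarks from [detect_landmarks()].
#' @return List with `image` (height x width gray matrix) and `spec`, a list
#'   holding `origin` (valley 2, row/col), `width`, `height`, `rotation`
#'   (degrees of the top edge from horizontal), the unit vectors `u` (along
#'   the top edge) and `v` (toward the wrist), and `clipped` (TRUE if the
#'   rectangle left the frame and was clamped).
#' @export
extract_roi <- function(img, landmarks) {
  assert_gray(img)
  val <- as.matrix(landmarks$valleys[, c("row", "col")])
  if (nrow(val) < 4L) hv_stop("4 valleys are required for the ROI", "detection")
  v2 <- as.numeric(val[2L, ]); v4 <- as.numeric(val[4L, ])
  w <- pt_dist(v2, v4)
  if (w < 2) hv_stop("valleys 2 and 4 coincide; ROI undefined", "detection")
  u <- (v4 - v2) / w
  nv <- c(u[2], -u[1])
  if (nv[1] < 0) nv <- -nv  # wrist side = downward (growing row)
  W <- as.integer(round(w))
  H <- as.integer(round(1.4 * w))
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  rr <- v2[1] + (jj - 0.5) * u[1] + (ii - 0.5) * nv[1]
  cc <- v2[2] + (jj - 0.5) * u[2] + (ii - 0.5) * nv[2]
  ri <- floor(rr + 0.5); ci <- floor(cc + 0.5)  # half-up: stable on .5 grids
  clipped <- any(ri < 1 | ri > nrow(img) | ci < 1 | ci > ncol(img))
  if (clipped) {
    hv_warn("ROI exceeds image bounds; clipped to frame", "roi_clipped")
    ri <- pmin(pmax(ri, 1), nrow(img))
    ci <- pmin(pmax(ci, 1), ncol(img))
  }
  roi <- matrix(img[cbind(as.vector(ri), as.vector(ci))], H, W)
  list(image = roi,
       spec = list(origin = v2, width = W, height = H,
                   rotation = atan2(u[1], u[2]) * 180 / pi,
                   u = u, v = nv, clipped = clipped))
}

#' Map ROI coordinates back to image coordinates
#'
#' @param points Matrix or data.frame with ROI (row, col) in its first two
#'   columns.
#' @param spec ROI spec from [extract_roi()].
#' @return n x 2 matrix of image (row, col).
#' @export
roi_to_image_coords <- function(points, spec) {
  p <- as.matrix(points)[, 1:2, drop = FALSE]
  r <- spec$origin[1] + (p[, 2] - 0.5) * spec$u[1] + (p[, 1] - 0.5) * spec$v[1]
  c <- spec$origin[2] + (p[, 2] - 0.5) * spec$u[2] + (p[, 1] - 0.5) * spec$v[2]
  cbind(row = r, col = c)
}

#' Segment veins inside the ROI
#'
#' Pipeline: large median filter (default 11 px) to suppress skin texture,
#' histogram equalization, local mean thresholding of the inverted ROI (so
#' the darker veins become object), small median filter (default 3 px) to
#' drop speckle, then a morphological closing to reconnect vein fragments.
#'
#' @param roi Gray ROI matrix.
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return Binary vein mask (1 = vein). Warns (class
#'   `hv_empty_roi_warning`) and returns an empty mask when nothing
#'   vein-like is found.
#' @export
segment_veins <- function(roi, config = pipeline_config()) {
  assert_gray(roi)
  sm <- median_filter(roi, config$vein_median_large)
  eq <- equalize_histogram(sm)
  inv <- 255 - eq
  bin <- local_threshold(inv, config$vein_surrounding, config$vein_tg)
  bin <- median_filter(bin, config$vein_median_small)
  if (any(bin == 1)) {
    bin <- close_mask(bin, config$closing_radius)
    bin <- fill_holes(bin, max_area = 50)
  }
  if (!any(bin == 1)) {
    hv_warn("no vein structure found in ROI", "empty_roi")
  }
  bin
}

# 8-neighborhoods as shifted matrices, ordered clockwise from north:
# P2..P9 = N, NE, E, SE, S, SW, W, NW. Outside pixels count as background.
neighbor_shifts <- function(mask) {
  list(shift_matrix(mask, -1L,  0L, 0L),  # P2 N
       shift_matrix(mask, -1L,  1L, 0L),  # P3 NE
       shift_matrix(mask,  0L,  1L, 0L),  # P4 E
       shift_matrix(mask,  1L,  1L, 0L),  # P5 SE
       shift_matrix(mask,  1L,  0L, 0L),  # P6 S
       shift_matrix(mask,  1L, -1L, 0L),  # P7 SW
       shift_matrix(mask,  0L, -1L, 0L),  # P8 W
       shift_matrix(mask, -1L, -1L, 0L))  # P9 NW
}

#' Zhang-Suen thinning
#'
#' Iterates the two Zhang-Suen sub-passes until no pixel is deleted,
#' producing a 1-px-wide, 8-connected skeleton. Candidates of each sub-pass
#' are found on whole-image shifted copies (vectorized) and then deleted
#' one at a time with their conditions re-checked on the updated image:
#' purely parallel deletion can erase a compact object's final 2 x 2 block
#' in one sweep (destroying the component) or strand 2 x 2 blocks at
#' junctions, while sequential deletion of simple points preserves the
#' topology, so every component survives as a skeleton.
#'
#' With `pad > 0` the mask is edge-replicated by that many pixels before
#' thinning and cropped afterwards: an object cut off by the frame (a vein
#' leaving the ROI) then keeps its skeleton all the way to the edge instead
#' of retracting by half its width. Objects not touching the frame are
#' unaffected.
#'
#' @param mask Binary image matrix.
#' @param pad Replication padding in pixels (0 = plain thinning).
#' @return Binary skeleton matrix.
#' @export
zhang_suen_thin <- function(mask, pad = 0L) {
  assert_binary(mask)
  if (pad > 0L) {
    padded <- zhang_suen_thin(pad_replicate(mask, as.integer(pad)), pad = 0L)
    n <- nrow(mask); m <- ncol(mask)
    return(padded[pad + seq_len(n), pad + seq_len(m), drop = FALSE])
  }
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p <- neighbor_shifts(m)
      b <- Reduce(`+`, p)
      a <- matrix(0L, nrow(m), ncol(m))
      for (i in 1:8) {
        j <- if (i == 8L) 1L else i + 1L
        a <- a + (p[[i]] == 0L & p[[j]] == 1L)
      }
      cond <- m == 1L & b >= 2L & b <= 6L & a == 1L
      if (phase == 1L) {
        cond <- cond & (p[[1]] * p[[3]] * p[[5]] == 0L) &
                       (p[[3]] * p[[5]] * p[[7]] == 0L)
      } else {
        cond <- cond & (p[[1]] * p[[3]] * p[[7]] == 0L) &
                       (p[[1]] * p[[5]] * p[[7]] == 0L)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # --- topology repairs -------------------------------------------------
  # 1. The parallel sub-passes delete a compact object's final 2 x 2 block
  #    in one sweep; restore a representative pixel for any component of
  #    the input that has no surviving skeleton pixel.
  labi <- label_components(mask)
  if (max(labi) > 0L) {
    for (k in seq_len(max(labi))) {
      comp <- which(labi == k)
      if (!any(m[comp] == 1L)) {
        rows <- (comp - 1L) %% nr + 1L
        cols <- (comp - 1L) %/% nr + 1L
        cen <- c(mean(rows), mean(cols))
        pick <- which.min((rows - cen[1])^2 + (cols - cen[2])^2)
        m[rows[pick], cols[pick]] <- 1L
      }
    }
  }
  # 2. Staircase cleanup: at a diagonal crossing the transition count
  #    overcounts (the arms are already linked within the ring), which
  #    strands a 2 x 2 block; delete a block pixel whenever its object
  #    neighbors remain one 8-connected set without it.
  stays_connected <- function(r, c) {
    pts <- NULL
    for (i in 1:8) {
      rr <- r + MOORE8[i, 1]; cc <- c + MOORE8[i, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && m[rr, cc] == 1L) {
        pts <- rbind(pts, c(rr, cc))
      }
    }
    if (is.null(pts) || nrow(pts) < 2L) return(FALSE)
    seen <- 1L
    frontier <- 1L
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (f in frontier) {
        adj <- which(abs(pts[, 1] - pts[f, 1]) <= 1 &
                       abs(pts[, 2] - pts[f, 2]) <= 1)
        adj <- setdiff(adj, seen)
        seen <- c(seen, adj)
        nxt <- c(nxt, adj)
      }
      frontier <- nxt
    }
    length(seen) == nrow(pts)
  }
  repeat {
    blocks <- which(m[-nr, -nc] == 1L & m[-1, -nc] == 1L &
                      m[-nr, -1] == 1L & m[-1, -1] == 1L, arr.ind = TRUE)
    if (nrow(blocks) == 0L) break
    progressed <- FALSE
    for (k in seq_len(nrow(blocks))) {
      for (d in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
        r <- blocks[k, 1] + d[1]; c <- blocks[k, 2] + d[2]
        if (m[r, c] == 1L && stays_connected(r, c)) {
          m[r, c] <- 0L
          progressed <- TRUE
          break
        }
      }
    }
    if (!progressed) break
  }
  m
}

# Crossing-number map over the whole image: half the sum of absolute
# differences around the ordered 8-neighborhood cycle. Background pixels get
# NA.
cn_map <- function(skel) {
  p <- neighbor_shifts(skel)
  s <- matrix(0L, nrow(skel), ncol(skel))
  for (i in 1:8) {
    j <- if (i == 8L) 1L else i + 1L
    s <- s + abs(p[[j]] - p[[i]])
  }
  cn <- s %/% 2L
  cn[skel == 0L] <- NA_integer_
  cn
}

#' Connection (crossing) number of a skeleton pixel
#'
#' Half the sum of absolute differences around the ordered 8-neighborhood
#' cycle of `p`: 0 = isolated pixel, 1 = line ending, 2 = line interior,
#' 3-4 = branching.
#'
#' @param skel Binary skeleton matrix.
#' @param p Integer c(row, col) of an object pixel.
#' @return Integer in 0..4.
#' @export
connection_number <- function(skel, p) {
  assert_binary(skel)
  if (skel[p[1], p[2]] != 1) {
    hv_stop("p is not an object pixel", "parameter")
  }
  nb <- vapply(1:8, function(i) {
    r <- p[1] + MOORE8[i, 1]; c <- p[2] + MOORE8[i, 2]
    if (r < 1 || r > nrow(skel) || c < 1 || c > ncol(skel)) 0L
    else as.integer(skel[r, c])
  }, integer(1))
  sum(abs(diff(c(nb, nb[1])))) %/% 2L
}

in_border_band <- function(r, c, frame, band, edges = "all") {
  tb <- r <= band | r > frame[1] - band
  if (edges == "tb") return(tb)
  tb | c <= band | c > frame[2] - band
}

#' Prune skeleton artifacts
#'
#' Deletes isolated pixels (connection number 0) and iteratively removes
#' spurs: paths starting at a line ending (connection number 1) that reach a
#' branching pixel, or another ending, in fewer than `max_spur` steps.
#' Endings inside the `border_band` of the frame are true vein exits and are
#' kept. The result is re-thinned to clean up junction remnants.
#'
#' @param skel Binary skeleton (already thinned).
#' @param max_spur Maximum spur length (px) that is still removed.
#' @param border_band Width (px) of the protected frame band.
#' @param protect_edges "all" to protect endings at every frame edge, "tb"
#'   to protect only the top and bottom edges (the vein flow direction in a
#'   vertically oriented ROI; side-pointing spurs are then artifacts).
#' @return Pruned binary skeleton.
#' @export
prune_skeleton <- function(skel, max_spur = 10L, border_band = 3L,
                           protect_edges = c("all", "tb")) {
  protect_edges <- match.arg(protect_edges)
  assert_binary(skel)
  m <- skel * 1L
  frame <- dim(m)
  repeat {
    cn <- cn_map(m)
    iso <- which(!is.na(cn) & cn == 0L)
    if (length(iso) > 0L) m[iso] <- 0L
    cn <- cn_map(m)
    ends <- which(!is.na(cn) & cn == 1L, arr.ind = TRUE)
    removed_any <- FALSE
    if (nrow(ends) > 0L) {
      keep <- !in_border_band(ends[, 1], ends[, 2], frame, border_band,
                              protect_edges)
      ends <- ends[keep, , drop = FALSE]
    }
    for (e in seq_len(nrow(ends))) {
      r0 <- ends[e, 1]; c0 <- ends[e, 2]
      if (m[r0, c0] != 1L) next  # already removed as part of another spur
      path <- matrix(c(r0, c0), 1L, 2L)
      prev <- c(NA_integer_, NA_integer_)
      cur <- c(r0, c0)
      status <- "open"
      while (nrow(path) <= max_spur) {
        nbrs <- sweep(MOORE8, 2, cur, `+`)
        ok <- nbrs[, 1] >= 1 & nbrs[, 1] <= frame[1] &
              nbrs[, 2] >= 1 & nbrs[, 2] <= frame[2]
        nbrs <- nbrs[ok, , drop = FALSE]
        nbrs <- nbrs[m[nbrs] == 1L, , drop = FALSE]
        if (!any(is.na(prev))) {
          nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), ,
                       drop = FALSE]
        }
        if (nrow(nbrs) == 0L) { status <- "segment"; break }
        if (nrow(nbrs) > 1L) { status <- "junction"; break }
        nxt <- as.integer(nbrs[1L, ])
        ncn <- connection_number(m, nxt)
        if (ncn >= 3L) { status <- "junction"; break }
        prev <- cur
        cur <- nxt
        path <- rbind(path, cur)
        if (ncn == 1L) { status <- "segment"; break }
      }
      remove <- switch(status,
        junction = nrow(path) < max_spur,
        segment = nrow(path) < max_spur &&
          !any(in_border_band(path[, 1], path[, 2], frame, border_band,
                              protect_edges)),
        open = FALSE)
      if (remove) {
        m[path] <- 0L
        removed_any <- TRUE
      }
    }
    if (!removed_any && length(iso) == 0L) break
  }
  zhang_suen_thin(m)
}

#' Extract vein minutiae from a pruned skeleton
#'
#' A branching minutia is placed at every object pixel whose connection
#' number is at least `branch_min_cn` (adjacent branch pixels within
#' `merge_radius` px are merged to their rounded centroid, since thinning
#' can emit several junction pixels at one anatomical bifurcation). An
#' ending minutia is placed at every connection-number-1 pixel inside the
#' `border_band` of the frame edge — those are veins leaving the ROI.
#'
#' @param skel Pruned binary skeleton.
#' @param border_band Width (px) of the edge band where endings count.
#' @param branch_min_cn Minimum connection number for a branching (3 =
#'   crossing-number convention; 4 = the stricter literal reading).
#' @param merge_radius Single-linkage merge radius for branch clusters (px).
#' @param ending_edges "all" (default) to accept endings at any frame edge,
#'   "top" to restrict to the top edge.
#' @return A [minutiae_set()].
#' @export
extract_minutiae <- function(skel, border_band = 3L, branch_min_cn = 3L,
                             merge_radius = 3, ending_edges = c("all", "top")) {
  assert_binary(skel)
  ending_edges <- match.arg(ending_edges)
  frame <- dim(skel)
  cn <- cn_map(skel)
  br <- which(!is.na(cn) & cn >= branch_min_cn, arr.ind = TRUE)
  branches <- NULL
  if (nrow(br) > 0L) {
    if (nrow(br) == 1L) {
      branches <- br
    } else {
      hc <- stats::hclust(stats::dist(br), method = "single")
      grp <- stats::cutree(hc, h = merge_radius)
      branches <- t(vapply(split(seq_len(nrow(br)), grp), function(ii) {
        round(colMeans(br[ii, , drop = FALSE]))
      }, numeric(2)))
    }
  }
  en <- which(!is.na(cn) & cn == 1L, arr.ind = TRUE)
  if (nrow(en) > 0L) {
    inb <- if (ending_edges == "all") {
      in_border_band(en[, 1], en[, 2], frame, border_band)
    } else {
      en[, 1] <= border_band
    }
    en <- en[inb, , drop = FALSE]
  }
  pts <- data.frame(
    row = c(if (!is.null(branches)) branches[, 1], en[, 1]),
    col = c(if (!is.null(branches)) branches[, 2], en[, 2]),
    kind = c(rep("branching", if (is.null(branches)) 0L else nrow(branches)),
             rep("ending", nrow(en))),
    stringsAsFactors = FALSE)
  pts <- pts[!duplicated(pts[, c("row", "col")]), , drop = FALSE]
  rownames(pts) <- NULL
  minutiae_set(pts, frame)
}
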