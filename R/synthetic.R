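# Synthetic hand-image generator with full ground truth.
#
# The hand model is deliberately schematic but carries the statistical
# structure the pipeline assumes: a bright hand (palm = ellipse, five
# separated fingers = vertical capsules) on a dark matte background, with a
# branching dark vein tree on the dorsum inside the region of interest.
# Every subject has its own anatomy (finger lengths/widths, palm size, vein
# topology); captures of one subject differ by a small multiplicative jitter,
# an in-plane rotation of up to +/-10 degrees, a translation, mild blur and
# additive noise. All randomness is seeded, so datasets are bit-reproducible.

HV_IMG_H <- 480L
HV_IMG_W <- 640L
HV_PALM_CENTER <- c(295, 320)

#' Default cohort parameters of the synthetic generator
#'
#' Means and spreads (px) of the anatomical dimensions, drawn per subject as
#' independent normals truncated at +/-3 spreads, plus the vein-tree and
#' jitter settings. Dimensions are sized for a 640 x 480 frame.
#'
#' @return Named list of generator parameters.
#' @export
cohort_default_params <- function() {
  list(
    finger_length_mean = c(95, 135, 155, 145, 110),  # thumb -> pinky
    finger_length_sd   = c(7, 9, 9, 9, 8),
    finger_width_mean  = c(28, 25, 25, 24, 20),
    finger_width_sd    = c(2.2, 2, 2, 2, 1.8),
    palm_width_mean = 175, palm_width_sd = 9,
    palm_height_mean = 150, palm_height_sd = 8,
    finger_gap = 10,
    jitter_scale = 0.02,
    n_branch_range = c(2L, 4L),
    vein_width_range = c(6, 8),
    vein_depth_range = c(20, 40),
    hand_intensity = 180,
    background_intensity = 15
  )
}

rnorm_trunc3 <- function(n, mean, sd) {
  z <- stats::rnorm(n)
  while (any(bad <- abs(z) > 3)) z[bad] <- stats::rnorm(sum(bad))
  mean + sd * z
}

# Derived geometry of a hand with the given dimensions, in the canonical
# (un-posed) image frame: palm ellipse + five vertical capsules whose lower
# ends are buried in the palm. Valleys sit where the inter-finger gap meets
# the ellipse boundary.
hand_geometry_model <- function(dims) {
  pc <- HV_PALM_CENTER
  w <- dims$finger_widths
  gap <- dims$finger_gap
  span <- sum(w) + 4 * gap
  palm_w <- max(dims$palm_width, span + 12)
  a_col <- palm_w / 2
  a_row <- dims$palm_height / 2
  xk <- numeric(5)
  cur <- pc[2] - span / 2
  for (k in 1:5) {
    xk[k] <- cur + w[k] / 2
    cur <- cur + w[k] + gap
  }
  # superellipse palm (exponent 4): a flatter top than an ellipse, so the
  # finger valleys sit at nearly equal heights, as on a real dorsum
  y_top <- function(col) {
    t <- 1 - ((col - pc[2]) / a_col)^4
    pc[1] - a_row * pmax(t, 0)^0.25
  }
  gap_cols <- (xk[-5] + w[-5] / 2 + xk[-1] - w[-1] / 2) / 2
  valleys <- cbind(row = y_top(gap_cols), col = gap_cols)
  # knuckle arch: fingers attach along an arc (middle finger highest), as on
  # a real hand; this keeps adjacent fingertip apexes off a common line so
  # every tip is a convex-hull vertex
  arch <- c(20, 8, 0, 8, 24)
  tips <- cbind(row = y_top(xk) + arch - dims$finger_lengths, col = xk)
  outer_col <- xk + sign(xk - pc[2]) * w / 2
  seg_bot <- pmax(y_top(outer_col), y_top(xk)) + 12
  seg_top <- tips[, 1] + w / 2
  list(pc = pc, a_col = a_col, a_row = a_row, palm_width = palm_w,
       xk = xk, w = w, tips = tips, valleys = valleys,
       seg_top = seg_top, seg_bot = seg_bot, y_top = y_top)
}

# How far each fingertip apex protrudes beyond the chord joining its hull
# neighbors (positive = the tip is a convex-hull vertex with that margin in
# px). The landmark construction — like any hull-based hand-geometry
# extractor — needs every tip on the hull, so subjects are drawn
# conditionally on positive margins.
tip_convexity_margins <- function(geom) {
  tips <- geom$tips
  above_chord <- function(p, a, b) {
    # vertical clearance of p above segment a-b at p's column
    t <- (p[2] - a[2]) / (b[2] - a[2])
    (a[1] + t * (b[1] - a[1])) - p[1]
  }
  shoulder <- function(side) {
    cx <- geom$pc[2] + side * 0.97 * geom$a_col
    c(geom$y_top(cx), cx)
  }
  c(thumb = above_chord(tips[1, ], shoulder(-1), tips[2, ]),
    index = above_chord(tips[2, ], tips[1, ], tips[3, ]),
    ring = above_chord(tips[4, ], tips[3, ], tips[5, ]),
    pinky = above_chord(tips[5, ], tips[4, ], shoulder(1)))
}

# Observable vein minutiae of a capture: the exact band union the renderer
# draws is rasterized in the ROI frame, regularized by the same 11-px median
# the acquisition model assumes (which fills the wedge between diverging
# bands, exactly as it does in a real image), thinned and pruned. Each tree
# branching/ending node is then snapped to its skeleton landmark; a node
# whose landmark is unresolvable (fused with a neighbor) is dropped — it is
# not observable at this image scale. Pixel intensities are never
# consulted, so this stays a geometry-derived ground truth.
observable_minutiae <- function(tree, geom, hw) {
  roi <- analytic_roi(geom)
  W <- as.integer(round(roi$width)); H <- as.integer(round(roi$height))
  rel_r <- tree$row - roi$origin[1]; rel_c <- tree$col - roi$origin[2]
  tx <- rel_r * roi$u[1] + rel_c * roi$u[2]   # local x (column direction)
  ty <- rel_r * roi$v[1] + rel_c * roi$v[2]   # local y (row direction)
  segs <- which(tree$parent > 0L)
  rr <- matrix(seq_len(H) - 0.5, H, W)
  cc <- matrix(seq_len(W) - 0.5, H, W, byrow = TRUE)
  band <- matrix(0L, H, W)
  for (s in segs) {
    p <- tree$parent[s]
    vx <- tx[s] - tx[p]; vy <- ty[s] - ty[p]
    L2 <- vx * vx + vy * vy
    if (L2 == 0) next
    t <- pmin(pmax(((cc - tx[p]) * vx + (rr - ty[p]) * vy) / L2, 0), 1)
    d2 <- (cc - (tx[p] + t * vx))^2 + (rr - (ty[p] + t * vy))^2
    band <- band | (d2 <= hw * hw)
  }
  band <- band * 1L
  # mirror the binary-domain cleanup of the segmentation stage so the
  # stated minutiae are the ones this acquisition model can actually show
  sm <- median_filter(band, 11L)
  sm <- median_filter(sm, 3L)
  sm <- fill_holes(close_mask(sm, 1L), max_area = 50)
  sk <- prune_skeleton(zhang_suen_thin(sm, pad = 10L), 10L, 3L, protect_edges = "tb")
  mm <- extract_minutiae(sk, border_band = 3L, branch_min_cn = 3L,
                         merge_radius = 5, ending_edges = "top")
  # snap tree nodes to skeleton landmarks (greedy one-to-one), starting
  # from the geometrically displaced fallback positions. A node with no
  # landmark within reach is unobservable at this image scale (its bands
  # fused with a neighbor) and is dropped from the ground truth. Endings
  # count at the top edge only: the bottom edge sits 1.4 x the measured
  # width below the valleys, so its position is not stable across captures.
  nodes <- which(tree$kind == "branching" |
                   (tree$kind == "ending" & ty < 0.5 * H))
  moff_x <- tree$moff_row[nodes] * roi$u[1] + tree$moff_col[nodes] * roi$u[2]
  moff_y <- tree$moff_row[nodes] * roi$v[1] + tree$moff_col[nodes] * roi$v[2]
  out_r <- ty[nodes] + moff_y
  out_c <- tx[nodes] + moff_x
  observable <- rep(FALSE, length(nodes))
  for (kind in c("branching", "ending")) {
    ni <- which(tree$kind[nodes] == kind)
    cand <- mm$points[mm$points$kind == kind, , drop = FALSE]
    used <- rep(FALSE, nrow(cand))
    maxd <- if (kind == "branching") 15 else 8
    for (i in ni) {
      if (nrow(cand) == 0L) break
      d <- sqrt((cand$row - out_r[i])^2 + (cand$col - out_c[i])^2)
      d[used] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= maxd) {
        out_r[i] <- cand$row[j] - 0.5   # back to continuous local coords
        out_c[i] <- cand$col[j] - 0.5
        used[j] <- TRUE
        observable[i] <- TRUE
      }
    }
  }
  # local -> canonical coordinates
  can_r <- roi$origin[1] + out_c * roi$u[1] + out_r * roi$v[1]
  can_c <- roi$origin[2] + out_c * roi$u[2] + out_r * roi$v[2]
  out <- data.frame(row = can_r, col = can_c, kind = tree$kind[nodes],
                    stringsAsFactors = FALSE)
  out[observable, , drop = FALSE]
}

# The measurement definitions applied to the ideal geometry: what a perfect
# extractor would report. This is the per-capture ground truth the pipeline
# is scored against.
analytic_features <- function(geom) {
  tips <- geom$tips
  v <- geom$valleys
  bases <- rbind(
    c(v[1, 1], tips[1, 2]),
    c(v[2, 1], tips[2, 2]),
    (v[2, ] + v[3, ]) / 2,
    (v[3, ] + v[4, ]) / 2,
    c(v[4, 1], tips[5, 2]))
  lengths <- sqrt(rowSums((tips - bases)^2))
  fractions <- seq(0.05, 0.95, by = 0.10)
  widths <- matrix(0, 5, 10)
  for (k in 1:5) {
    wk <- geom$w[k]
    d <- fractions * lengths[k]          # depth below the tip apex
    cap <- d < wk / 2
    widths[k, ] <- ifelse(cap, 2 * sqrt(pmax((wk / 2)^2 - (wk / 2 - d)^2, 0)),
                          wk)
  }
  tip_d <- sqrt(rowSums((tips[2:4, ] - tips[3:5, ])^2))
  val_d <- sqrt(rowSums((v[1:3, ] - v[2:4, ])^2))
  feats <- c(lengths, as.vector(t(widths)), tip_d, val_d, 2 * geom$a_col)
  names(feats) <- hv_feature_names()
  feats
}

# Analytic ROI frame (canonical coords): top edge valley2 -> valley4, height
# 1.4 x width toward the wrist.
analytic_roi <- function(geom) {
  v2 <- geom$valleys[2, ]; v4 <- geom$valleys[4, ]
  w <- sqrt(sum((v4 - v2)^2))
  u <- (v4 - v2) / w
  nv <- c(u[2], -u[1])
  if (nv[1] < 0) nv <- -nv
  list(origin = v2, u = u, v = nv, width = w, height = 1.4 * w)
}

# Grow a planar rooted vein tree inside the subject's ROI. Branches start at
# the bottom (wrist side), wander upward with angular wobble toward assigned
# lateral targets (so siblings fan out instead of merging), split at
# scheduled steps with a wide opening angle, and leave through the top edge;
# segments overshoot the ROI a little so skeleton endings reliably cross the
# detected frame. Nodes are returned in canonical image coordinates.
#
# For each branching node the observable bifurcation is displaced from the
# centerline node by halfwidth / sin(opening/2) along the children's
# bisector: that is where the two rendered bands actually separate, and it
# is the position stored as the minutia ground truth (moff_* offsets).
grow_vein_tree <- function(geom, params, vein_width) {
  roi <- analytic_roi(geom)
  W <- roi$width; H <- roi$height
  step <- 7
  overshoot <- 12
  hw <- vein_width / 2
  to_canon <- function(x, y) roi$origin + x * roi$u + y * roi$v
  n_branch <- sample(params$n_branch_range[1]:params$n_branch_range[2], 1L)
  # every leaf needs its own exit corridor through the top edge; corridors
  # narrower than band width + the median's gap-survival width (~13.5 px)
  # would fuse, so the ROI width caps the number of branchings
  n_leaves_max <- max(3L, floor((W - 24) / 13.5))
  n_branch <- max(2L, min(n_branch, n_leaves_max - 1L))
  n_leaves <- n_branch + 1L
  for (try in 1:20) {
    slots <- sort(12 + (seq_len(n_leaves) - 0.5) * (W - 24) / n_leaves +
                    stats::rnorm(n_leaves, 0, 3))
    if (n_leaves == 1L || min(diff(slots)) >= 11) break
  }
  # splits happen in the lower ~60% of the ROI, well apart vertically
  smax <- max(8L, as.integer(0.62 * H / step))
  split_steps <- sort(sample(seq(2L, smax, by = 3L), n_branch))
  nodes <- data.frame(id = integer(0), parent = integer(0),
                      row = numeric(0), col = numeric(0),
                      kind = character(0),
                      moff_row = numeric(0), moff_col = numeric(0),
                      stringsAsFactors = FALSE)
  add_node <- function(parent, x, y, kind, moff = c(0, 0)) {
    id <- nrow(nodes) + 1L
    p <- to_canon(x, y)
    nodes[id, ] <<- list(id, parent, p[1], p[2], kind, moff[1], moff[2])
    id
  }
  x0 <- stats::runif(1, 0.4, 0.6) * W
  # the vein enters from the wrist: the band overshoots the bottom edge, the
  # ground-truth ending sits on the edge itself
  stub <- add_node(0L, x0, H + overshoot, "overshoot")
  root <- add_node(stub, x0, H, "ending")
  active <- list(list(node = root, x = x0, y = H,
                      angle = stats::rnorm(1, 0, 6), slots = seq_len(n_leaves)))
  stepno <- 0L
  splits_done <- 0L
  while (length(active) > 0L && stepno < 400L) {
    stepno <- stepno + 1L
    nxt <- list()
    split_branch <- 0L
    pending <- sum(split_steps <= stepno) - splits_done
    if (pending > 0L) {
      # split a branch that still owns several exit slots, preferring one
      # clear of the side margins; force a margin split rather than lose
      # the branching once the carrier is running out of vertical room
      xs <- vapply(active, `[[`, 0, "x")
      ys <- vapply(active, `[[`, 0, "y")
      nslots <- vapply(active, function(b) length(b$slots), 0L)
      eligible <- which(nslots >= 2L & xs > 16 & xs < W - 16)
      if (length(eligible) == 0L) {
        eligible <- which(nslots >= 2L & ys < 0.5 * H)
      }
      if (length(eligible) > 0L) {
        split_branch <- eligible[sample.int(length(eligible), 1L)]
        splits_done <- splits_done + 1L
      }
    }
    xs <- vapply(active, `[[`, 0, "x")
    for (bi in seq_along(active)) {
      br <- active[[bi]]
      target <- mean(slots[br$slots])
      steer <- 0.5 * max(-20, min(20, target - br$x))
      # residual repulsion between bands that still run close; coincident
      # branches (fresh splits) part according to their own heading
      too_close <- xs[-bi][abs(xs[-bi] - br$x) < 13]
      repel <- if (length(too_close) > 0) {
        dx <- br$x - too_close
        push <- ifelse(abs(dx) > 1, sign(dx), sign(br$angle + 1e-9))
        7 * sum(push)
      } else 0
      br$angle <- max(-45, min(45, br$angle + stats::rnorm(1, 0, 4) + repel +
                                 0.4 * (steer - br$angle * 0.35)))
      # straighten near the top so exits cross the edge perpendicularly,
      # and keep clear of the side edges (all exits leave through the top)
      if (br$y < 0.3 * H) br$angle <- br$angle * 0.5
      if (br$x < 10) br$angle <- max(br$angle, 10)
      if (br$x > W - 10) br$angle <- min(br$angle, -10)
      a <- br$angle * pi / 180
      nx <- br$x + step * sin(a)
      ny <- br$y - step * cos(a)
      if (ny <= 0) {
        # leaves through the top: overshoot past the ROI edge
        t <- (br$y - 0) / (br$y - ny)
        ex <- br$x + t * (nx - br$x)
        end_id <- add_node(br$node, ex, 0, "ending")
        add_node(end_id, ex + (nx - br$x) * 0.5, -overshoot, "overshoot")
        next
      }
      if (bi == split_branch) {
        opening <- stats::runif(1, 50, 75)
        # observable bifurcation: where the two bands separate, displaced
        # from the centerline node along the travel direction (the
        # children's bisector). The wedge between the diverging bands only
        # becomes visible once it is wide enough to survive the 11-px
        # median of the segmentation stage, which adds about a
        # quarter-window of fill.
        disp <- (hw + 2.75) / sin(opening / 2 * pi / 180)
        bis <- br$angle * pi / 180
        travel <- sin(bis) * roi$u - cos(bis) * roi$v  # local (dx, dy=-1) up
        bid <- add_node(br$node, nx, ny, "branching", moff = disp * travel)
        k <- length(br$slots)
        left <- br$slots[seq_len(ceiling(k / 2))]
        right <- setdiff(br$slots, left)
        nxt[[length(nxt) + 1L]] <- list(node = bid, x = nx, y = ny,
                                        angle = br$angle - opening / 2,
                                        slots = left)
        nxt[[length(nxt) + 1L]] <- list(node = bid, x = nx, y = ny,
                                        angle = br$angle + opening / 2,
                                        slots = right)
      } else {
        nid <- add_node(br$node, nx, ny, "path")
        nxt[[length(nxt) + 1L]] <- list(node = nid, x = nx, y = ny,
                                        angle = br$angle, slots = br$slots)
      }
    }
    active <- nxt
  }
  nodes
}

#' Generate a synthetic subject
#'
#' Draws the subject's anatomical dimensions from the cohort distributions
#' (independent normals truncated at +/-3 spreads) and grows a random vein
#' tree with 2-4 branchings on the dorsum inside the subject's ROI.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed; fully determines the subject.
#' @param cohort_params Parameter list, see [cohort_default_params()].
#' @param subject_id Identifier; defaults to `"subj<seed>"`.
#' @return Object of class `subject_model`.
#' @export
generate_subject <- function(seed, cohort_params = cohort_default_params(),
                             subject_id = NULL) {
  p <- utils::modifyList(cohort_default_params(), cohort_params)
  sds <- c(p$finger_length_sd, p$finger_width_sd, p$palm_width_sd,
           p$palm_height_sd)
  if (any(sds <= 0)) hv_stop("cohort spreads must be positive", "parameter")
  if (p$jitter_scale < 0 || p$jitter_scale >= 0.1) {
    hv_stop("jitter_scale must be in [0, 0.1)", "parameter")
  }
  set.seed(as.integer(seed))
  for (try in 1:100) {
    dims <- list(
      finger_lengths = rnorm_trunc3(5, p$finger_length_mean, p$finger_length_sd),
      finger_widths = rnorm_trunc3(5, p$finger_width_mean, p$finger_width_sd),
      palm_width = rnorm_trunc3(1, p$palm_width_mean, p$palm_width_sd),
      palm_height = rnorm_trunc3(1, p$palm_height_mean, p$palm_height_sd),
      finger_gap = p$finger_gap)
    geom <- hand_geometry_model(dims)
    if (all(tip_convexity_margins(geom) >= 6)) break
  }
  vein_width <- stats::runif(1, p$vein_width_range[1], p$vein_width_range[2])
  # a narrow ROI cannot resolve three wide exit corridors: cap the band
  # width so adjacent exits keep a gap that survives the median filter
  vein_width <- min(vein_width, max(6, (analytic_roi(geom)$width - 24) / 3 - 5.5))
  vein_depth <- stats::runif(1, p$vein_depth_range[1], p$vein_depth_range[2])
  vein_tree <- grow_vein_tree(geom, p, vein_width)
  structure(list(
    subject_id = if (is.null(subject_id)) paste0("subj", seed) else subject_id,
    finger_lengths = dims$finger_lengths,
    finger_base_widths = dims$finger_widths,
    palm_width = dims$palm_width,
    palm_height = dims$palm_height,
    palm_center = HV_PALM_CENTER,
    finger_gap = dims$finger_gap,
    vein_tree = vein_tree,
    vein_width = vein_width,
    vein_depth = vein_depth,
    jitter_scale = p$jitter_scale,
    seed = as.integer(seed),
    params = p), class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model %s: lengths %s, %d vein branchings>\n",
              x$subject_id,
              paste(round(x$finger_lengths), collapse = "/"),
              sum(x$vein_tree$kind == "branching")))
  invisible(x)
}

#' Default capture-noise parameters
#'
#' @param blur Number of 3 x 3 averaging passes applied to the rendered
#'   frame.
#' @param noise_sd Spread of the additive Gaussian pixel noise (counts).
#' @param rot_range In-plane rotation range (degrees, uniform +/-).
#' @param trans_range Translation range (px, uniform +/- each axis).
#' @param seed Optional explicit jitter seed; by default derived from the
#'   subject seed and capture index.
#' @return Named list.
#' @export
noise_default <- function(blur = 1L, noise_sd = 4, rot_range = 10,
                          trans_range = 15, seed = NULL) {
  list(blur = as.integer(blur), noise_sd = noise_sd, rot_range = rot_range,
       trans_range = trans_range, seed = seed)
}

#' @rdname noise_default
#' @export
noise_zero <- function() noise_default(blur = 0L, noise_sd = 0, rot_range = 0,
                                       trans_range = 0)

# forward pose transform of (row, col) points
pose_transform <- function(pts, theta_deg, translation, center = HV_PALM_CENTER) {
  th <- theta_deg * pi / 180
  co <- cos(th); si <- sin(th)
  p <- as.matrix(pts)
  dr <- p[, 1] - center[1]; dc <- p[, 2] - center[2]
  cbind(row = co * dr - si * dc + center[1] + translation[1],
        col = si * dr + co * dc + center[2] + translation[2])
}

#' Render one capture of a subject
#'
#' Applies the subject's intra-subject jitter and a random in-plane pose,
#' rasterizes the 640 x 480 8-bit frame (dark background, bright hand, darker
#' vein bands) and returns it together with the capture's ground truth.
#'
#' @param subject A `subject_model`.
#' @param capture_index Positive integer; seeds the capture jitter.
#' @param noise Noise parameters, see [noise_default()]; use [noise_zero()]
#'   for a canonical noise-free render.
#' @return List with `image` (gray matrix) and `gt`: `true_features` (named
#'   62-vector), `true_minutiae` ([minutiae_set()] in image coordinates),
#'   `silhouette` (binary matrix), `pose` (theta, translation) and
#'   `landmarks` (ideal fingertip/valley image coordinates).
#' @export
render_capture <- function(subject, capture_index, noise = noise_default()) {
  noise <- utils::modifyList(noise_default(), noise)
  seed <- if (!is.null(noise$seed)) noise$seed else
    (subject$seed + 7919L * as.integer(capture_index)) %% .Machine$integer.max
  set.seed(as.integer(seed))
  js <- subject$jitter_scale
  dims <- list(
    finger_lengths = subject$finger_lengths * (1 + js * stats::rnorm(5)),
    finger_widths = subject$finger_base_widths * (1 + js * stats::rnorm(5)),
    palm_width = subject$palm_width * (1 + js * stats::rnorm(1)),
    palm_height = subject$palm_height * (1 + js * stats::rnorm(1)),
    finger_gap = subject$finger_gap)
  geom <- hand_geometry_model(dims)
  tree <- subject$vein_tree
  if (js > 0) {
    tree$row <- tree$row + stats::rnorm(nrow(tree), 0, js * 40)
    tree$col <- tree$col + stats::rnorm(nrow(tree), 0, js * 40)
  }
  theta <- stats::runif(1, -noise$rot_range, noise$rot_range)
  translation <- stats::runif(2, -noise$trans_range, noise$trans_range)

  h <- HV_IMG_H; w <- HV_IMG_W
  pc <- geom$pc
  th <- theta * pi / 180
  co <- cos(th); si <- sin(th)
  rr <- matrix(seq_len(h), h, w) - pc[1] - translation[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - pc[2] - translation[2]
  cr <- co * rr + si * cc + pc[1]   # canonical coordinates of each pixel
  cn <- -si * rr + co * cc + pc[2]
  mask <- ((cr - pc[1]) / geom$a_row)^4 + ((cn - pc[2]) / geom$a_col)^4 <= 1
  for (k in 1:5) {
    dr <- cr - pmin(pmax(cr, geom$seg_top[k]), geom$seg_bot[k])
    dc <- cn - geom$xk[k]
    mask <- mask | (dr * dr + dc * dc <= (geom$w[k] / 2)^2)
  }
  if (any(mask[1, ]) || any(mask[h, ]) || any(mask[, 1]) || any(mask[, w])) {
    hv_stop("hand placed partially out of frame", "render")
  }
  p <- subject$params
  img <- matrix(p$background_intensity, h, w)
  img[mask] <- p$hand_intensity

  # vein bands: darker curvilinear bands along the tree edges
  segs <- tree[tree$parent > 0L, , drop = FALSE]
  if (nrow(segs) > 0L) {
    r1 <- tree$row[segs$parent]; c1 <- tree$col[segs$parent]
    r2 <- segs$row; c2 <- segs$col
    box <- cr >= min(r1, r2) - 10 & cr <= max(r1, r2) + 10 &
           cn >= min(c1, c2) - 10 & cn <= max(c1, c2) + 10 & mask
    idx <- which(box)
    if (length(idx) > 0L) {
      pr <- cr[idx]; pcn <- cn[idx]
      vein <- logical(length(idx))
      hw <- subject$vein_width / 2
      for (s in seq_along(r2)) {
        vr <- r2[s] - r1[s]; vc <- c2[s] - c1[s]
        L2 <- vr * vr + vc * vc
        if (L2 == 0) next
        t <- pmin(pmax(((pr - r1[s]) * vr + (pcn - c1[s]) * vc) / L2, 0), 1)
        d2 <- (pr - (r1[s] + t * vr))^2 + (pcn - (c1[s] + t * vc))^2
        vein <- vein | (d2 <= hw * hw)
      }
      img[idx[vein]] <- p$hand_intensity - subject$vein_depth
    }
  }
  img <- round(img)
  silhouette <- mask * 1L
  if (noise$blur > 0L) {
    for (b in seq_len(noise$blur)) img <- mean_filter(img, 3L)
  }
  if (noise$noise_sd > 0) {
    img <- img + round(stats::rnorm(length(img), 0, noise$noise_sd))
    img <- pmin(pmax(img, 0), 255)
  }

  feats <- analytic_features(geom)
  obs <- observable_minutiae(tree, geom, subject$vein_width / 2)
  mnodes <- obs
  mpts <- pose_transform(cbind(mnodes$row, mnodes$col), theta, translation)
  gt_min <- minutiae_set(
    data.frame(row = pmin(pmax(mpts[, 1], 1), h),
               col = pmin(pmax(mpts[, 2], 1), w),
               kind = mnodes$kind, stringsAsFactors = FALSE),
    frame = c(h, w))
  list(image = img,
       gt = list(
         true_features = feats,
         true_minutiae = gt_min,
         silhouette = silhouette,
         pose = list(theta = theta, translation = translation),
         landmarks = list(
           fingertips = pose_transform(geom$tips, theta, translation),
           valleys = pose_transform(geom$valleys, theta, translation))),
       subject_id = subject$subject_id,
       capture_index = as.integer(capture_index))
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_subjects` x `captures_per_subject` 8-bit grayscale PNGs plus a
#' ground-truth JSON per capture and a manifest CSV. The first `n_enroll`
#' captures of each subject are flagged for enrollment, mirroring a protocol
#' of seven captures per subject of which two train the system.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param captures_per_subject Captures per subject (>= 3).
#' @param seed Master seed; subject seeds and all noise derive from it.
#' @param out_dir Output directory (created if needed).
#' @param n_enroll Enrollment captures flagged per subject.
#' @param cohort_params See [cohort_default_params()].
#' @param noise See [noise_default()].
#' @return The manifest data.frame (invisibly); also written as
#'   `manifest.csv` in `out_dir`.
#' @export
generate_dataset <- function(n_subjects, captures_per_subject, seed, out_dir,
                             n_enroll = 2L,
                             cohort_params = cohort_default_params(),
                             noise = noise_default()) {
  if (n_subjects < 2L) hv_stop("need at least 2 subjects", "parameter")
  if (captures_per_subject < 3L) hv_stop("need at least 3 captures per subject",
                                         "parameter")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) hv_stop(paste("cannot create", out_dir), "io")
  probe <- file.path(out_dir, ".write_test")
  if (!isTRUE(tryCatch({ file.create(probe) }, warning = function(w) FALSE))) {
    hv_stop(paste("output directory not writable:", out_dir), "io")
  }
  unlink(probe)
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(10000000L, n_subjects)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", i)
    subj <- generate_subject(subject_seeds[i], cohort_params, subject_id = sid)
    for (ci in seq_len(captures_per_subject)) {
      cap <- render_capture(subj, ci, noise)
      img_path <- sprintf("%s_c%02d.png", sid, ci)
      gt_path <- sprintf("%s_c%02d_gt.json", sid, ci)
      write_gray_png(cap$image, file.path(out_dir, img_path))
      write_ground_truth(cap$gt, file.path(out_dir, gt_path))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, capture_idx = ci, path = img_path,
        is_enrollment = ci <= n_enroll, gt_path = gt_path,
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
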