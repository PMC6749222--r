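# Contour tracing, hull, valleys, fingertips and the 62-feature vector.

test_that("connected-component labeling honors connectivity", {
  m <- matrix(0L, 5, 5)
  m[cbind(1:4, 1:4)] <- 1L   # diagonal chain
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 4L)

  m2 <- matrix(0L, 6, 6)
  m2[1:2, 1:2] <- 1L
  m2[4:6, 4:6] <- 1L
  big <- largest_component(m2)
  expect_equal(sum(big), 9)

  expect_error(largest_component(matrix(0L, 3, 3)),
               class = "hv_segmentation_error")
})

test_that("contour tracing walks the boundary of the largest object", {
  sq <- matrix(0L, 5, 5)
  sq[2:4, 2:4] <- 1L
  ct <- trace_contour(sq)
  expect_equal(nrow(ct), 8)          # 3x3 square: all but the center
  expect_false(any(ct[, 1] == 3 & ct[, 2] == 3))

  single <- matrix(0L, 3, 3); single[2, 2] <- 1L
  expect_equal(trace_contour(single), matrix(c(2, 2), 1, 2))

  two <- matrix(0L, 8, 8)
  two[2, 2] <- 1L
  two[5:7, 5:7] <- 1L
  ct2 <- trace_contour(two)
  expect_true(all(ct2[, 1] >= 5))    # only the larger blob is traced

  expect_error(trace_contour(matrix(0L, 4, 4)),
               class = "hv_segmentation_error")
})

test_that("convex hull matches the exhaustive oracle and is idempotent", {
  sq <- rbind(c(0, 0), c(0, 10), c(10, 0), c(10, 10),
              c(5, 5), c(3, 7), c(6, 2))
  h <- convex_hull(sq)
  expect_setequal(pts_key(h), pts_key(sq[1:4, ]))

  h2 <- convex_hull(h)
  expect_setequal(pts_key(h2), pts_key(h))

  set.seed(11)
  pts <- random_position_set(50)
  expect_setequal(pts_key(convex_hull(pts)), pts_key(o_hull_vertices(pts)))

  line <- cbind(1:5, 1:5)
  expect_error(convex_hull(line), class = "hv_degenerate_error")
})

test_that("convexity defects find deep valleys only", {
  # convex disk: no defects at any positive depth
  disk <- matrix(0L, 41, 41)
  rr <- row(disk) - 21; cc <- col(disk) - 21
  disk[rr^2 + cc^2 <= 15^2] <- 1L
  ct <- trace_contour(disk)
  h <- convex_hull(ct)
  expect_equal(nrow(convexity_defects(ct, h, min_depth = 3)), 0L)

  # U-shape with a 20-px-deep notch
  u <- matrix(1L, 30, 31)
  u[1:20, 14:18] <- 0L
  ctu <- trace_contour(u)
  hu <- convex_hull(ctu)
  d <- convexity_defects(ctu, hu, min_depth = 10)
  expect_equal(nrow(d), 1L)
  expect_gte(d$depth, 18)
  expect_true(abs(d$col - 16) <= 3)   # at the bottom of the notch
  expect_equal(nrow(convexity_defects(ctu, hu, min_depth = 25)), 0L)
})

test_that("a fingerless silhouette raises a hand-detection error", {
  disk <- matrix(0L, 101, 101)
  rr <- row(disk) - 51; cc <- col(disk) - 51
  disk[rr^2 + cc^2 <= 40^2] <- 1L
  expect_error(detect_landmarks(disk), class = "hv_detection_error")
})

test_that("finger bases follow the midpoint / reflection rules", {
  valleys <- data.frame(row = c(100, 100, 100, 100),
                        col = c(20, 40, 60, 80))
  expect_equal(finger_base(valleys, 3), c(100, 50))
  expect_equal(finger_base(valleys, 4), c(100, 70))
  # index: adjacent valley reflected across the vertical finger axis
  expect_equal(finger_base(valleys, 2, fingertip = c(10, 33)), c(100, 33))
  expect_equal(finger_base(valleys, 1, fingertip = c(40, 10)), c(100, 10))
  expect_error(finger_base(valleys[1:3, ], 3), class = "hv_detection_error")
  expect_error(finger_base(valleys, 2), class = "hv_parameter_error")
})

test_that("landmarks on a clean synthetic hand hit the generator's marks", {
  s <- generate_subject(42)
  cap <- render_capture(s, 1, noise_zero())
  res <- process_capture(cap$image)

  # rotate ground-truth landmarks into the pose-normalized frame
  th <- res$pose$angle * pi / 180
  cen <- res$pose$center
  rot <- function(p) {
    dr <- p[, 1] - cen[1]; dc <- p[, 2] - cen[2]
    cbind(cos(th) * dr - sin(th) * dc + cen[1],
          sin(th) * dr + cos(th) * dc + cen[2])
  }
  tips_gt <- rot(cap$gt$landmarks$fingertips)
  derr <- sqrt(rowSums((res$landmarks$fingertips - tips_gt)^2))
  expect_true(all(derr <= 2))

  expect_equal(nrow(res$landmarks$valleys), 4L)
  val_gt <- rot(cap$gt$landmarks$valleys)
  verr <- sqrt(rowSums((as.matrix(res$landmarks$valleys[, c("row", "col")]) -
                          val_gt)^2))
  expect_true(all(verr <= 3))

  # bases lie inside the silhouette
  mask <- normalize_pose(cap$gt$silhouette)$mask
  for (k in 1:5) {
    b <- round(res$landmarks$finger_bases[k, ])
    expect_equal(mask[b[1], b[2]], 1)
  }
})

test_that("the feature vector has the documented layout and recovers anatomy", {
  s <- generate_subject(7)
  cap <- render_capture(s, 1, noise_zero())
  res <- process_capture(cap$image)
  f <- res$features
  expect_length(f, 62L)
  expect_named(f)
  expect_true(all(f >= 0))
  expect_true(startsWith(names(f)[1], "L1") && names(f)[62] == "L6")

  err <- abs(f - cap$gt$true_features)
  rel <- err / pmax(abs(cap$gt$true_features), 1)
  # per-capture: within 2 percent or the raster quantization floor
  expect_true(all(rel <= 0.02 | err <= 2))
})

test_that("captures of one subject with zero jitter give identical features", {
  p <- cohort_default_params()
  p$jitter_scale <- 0
  s <- generate_subject(13, p)
  r1 <- process_capture(render_capture(s, 1, noise_zero())$image)
  r2 <- process_capture(render_capture(s, 2, noise_zero())$image)
  expect_identical(r1$features, r2$features)
})

test_that("features scale with the image and survive in-plane rotation", {
  s <- generate_subject(99)
  cap <- render_capture(s, 1, noise_zero())
  mask <- largest_component(global_threshold(mean_filter(cap$image, 3), -60))

  lm1 <- detect_landmarks(mask)
  f1 <- measure_hand(mask, lm1)
  mask2 <- kronecker(mask, matrix(1L, 2, 2))
  # pixel-sized windows are defined at the capture resolution; a doubled
  # image needs them doubled
  cfg2 <- pipeline_config(curvature_k = 30, min_depth = 40, cluster_gap = 20)
  lm2 <- detect_landmarks(mask2, cfg2)
  f2 <- measure_hand(mask2, lm2)
  # doubled image doubles the raster quantization floor too
  expect_true(all(abs(f2 - 2 * f1) / pmax(2 * f1, 10) <= 0.04 |
                    abs(f2 - 2 * f1) <= 3))

  # +/-10 degree capture poses: features invariant after normalization
  nz <- noise_zero()
  nz$rot_range <- 10
  cap_r <- render_capture(s, 1, nz)
  res_r <- process_capture(cap_r$image)
  rel <- abs(res_r$features - cap_r$gt$true_features) /
    pmax(abs(cap_r$gt$true_features), 1)
  expect_true(all(rel <= 0.03 |
                    abs(res_r$features - cap_r$gt$true_features) <= 2.5))
})
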