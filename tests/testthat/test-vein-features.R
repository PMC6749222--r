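# ROI extraction, vein segmentation, thinning, pruning and minutiae.

fake_landmarks <- function(v2, v4) {
  list(valleys = data.frame(row = c(v2[1] - 5, v2[1], (v2[1] + v4[1]) / 2,
                                    v4[1]),
                            col = c(v2[2] - 30, v2[2], (v2[2] + v4[2]) / 2,
                                    v4[2])))
}

test_that("the ROI spans valley 2 to valley 4 with a 1.4 aspect", {
  img <- matrix(100L, 480, 640)
  roi <- extract_roi(img, fake_landmarks(c(200, 300), c(200, 400)))
  expect_equal(roi$spec$width, 100L)
  expect_equal(roi$spec$height, 140L)
  expect_lte(abs(roi$spec$height - 1.4 * roi$spec$width), 1)
  expect_equal(roi$spec$rotation, 0)

  # axis-aligned: the crop equals a direct slice
  set.seed(21)
  img[] <- sample(0:255, length(img), replace = TRUE)
  roi <- extract_roi(img, fake_landmarks(c(200, 300), c(200, 400)))
  expect_equal(roi$image, img[201:340, 301:400])

  # near the frame edge the rectangle is clipped with a warning
  expect_warning(
    extract_roi(img, fake_landmarks(c(400, 300), c(400, 400))),
    class = "hv_roi_clipped_warning")
})

test_that("ROI coordinates round-trip to image coordinates", {
  img <- matrix(0L, 480, 640)
  roi <- extract_roi(img, fake_landmarks(c(180, 280), c(210, 380)))
  pts <- cbind(c(1, 50, 100), c(1, 30, 60))
  back <- roi_to_image_coords(pts, roi$spec)
  # corner (1,1) maps near valley 2; all points inside the frame
  expect_lt(sqrt(sum((back[1, ] - c(180, 280))^2)), 3)
  expect_true(all(back[, 1] >= 1 & back[, 1] <= 480))
})

test_that("vein segmentation finds dark bands and rejects flat regions", {
  set.seed(22)
  roi <- matrix(180L, 120, 80)
  roi[, 38:43] <- 150L                     # straight dark band
  roi <- roi + matrix(sample(-2:2, length(roi), replace = TRUE), 120, 80)
  vm <- segment_veins(roi)
  expect_gte(mean(vm[, 38:43]), 0.95)          # band detected
  lab <- label_components(vm)
  main <- which.max(tabulate(lab[lab > 0]))
  # a single component covers (nearly all of) the band
  expect_gte(sum(lab[, 38:43] == main) / (6 * nrow(vm)), 0.95)

  expect_warning(vm0 <- segment_veins(matrix(170L, 60, 40)),
                 class = "hv_empty_roi_warning")
  expect_equal(sum(vm0), 0)

  # salt-and-pepper only: any surviving fragments are tiny
  set.seed(23)
  sp <- matrix(180L, 80, 60)
  sp[sample(length(sp), 150)] <- 60L
  vm2 <- suppressWarnings(segment_veins(sp))
  if (any(vm2 == 1)) {
    lab2 <- label_components(vm2)
    expect_true(all(tabulate(lab2[lab2 > 0]) < 5))
  }
})

test_that("Zhang-Suen thinning produces 1-px skeletons and keeps topology", {
  expect_equal(zhang_suen_thin(matrix(0L, 10, 10)), matrix(0L, 10, 10))

  bar <- matrix(0L, 9, 30)
  bar[4:6, 3:28] <- 1L
  sk <- zhang_suen_thin(bar)
  expect_true(all(colSums(sk[, 5:26]) == 1))          # 1 px wide
  ext <- range(which(colSums(sk) > 0))
  expect_lte(abs(ext[1] - 3), 2)
  expect_lte(abs(ext[2] - 28), 2)
  expect_equal(zhang_suen_thin(sk), sk)               # idempotent

  set.seed(24)
  for (i in 1:8) {
    blob <- random_blob(i * 100)
    sk <- zhang_suen_thin(blob)
    # no 2x2 object block anywhere
    if (any(sk == 1)) {
      blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
        sk[-nrow(sk), -1] & sk[-1, -1]
      expect_false(any(blocks))
    }
    expect_equal(max(label_components(sk)), max(label_components(blob)))
  }
})

test_that("replicate padding keeps skeletons of frame-cut objects at the edge", {
  band <- matrix(0L, 40, 21)
  band[1:40, 9:14] <- 1L     # vertical band crossing both frame edges
  sk <- zhang_suen_thin(band, pad = 10)
  expect_true(any(sk[1, ] == 1))
  expect_true(any(sk[40, ] == 1))
  # plain thinning retracts from the cut edges
  sk0 <- zhang_suen_thin(band)
  expect_false(any(sk0[1, ] == 1))
})

test_that("connection numbers classify skeleton pixels", {
  m <- matrix(0L, 5, 5); m[3, 3] <- 1L
  expect_equal(connection_number(m, c(3, 3)), 0L)

  line <- matrix(0L, 5, 7); line[3, 2:6] <- 1L
  expect_equal(connection_number(line, c(3, 2)), 1L)
  expect_equal(connection_number(line, c(3, 4)), 2L)

  tj <- matrix(0L, 7, 7)
  tj[4, 2:6] <- 1L
  tj[5:6, 4] <- 1L
  expect_equal(connection_number(tj, c(4, 4)), 3L)

  expect_error(connection_number(line, c(1, 1)), class = "hv_parameter_error")
})

test_that("pruning removes short spurs, isolated pixels, keeps long arms", {
  base <- matrix(0L, 15, 40)
  base[8, 2:39] <- 1L
  spur <- base
  spur[7, 20] <- 1L; spur[6, 21] <- 1L; spur[5, 22] <- 1L  # 3-px spur
  pr <- prune_skeleton(spur, max_spur = 10, border_band = 1)
  expect_equal(sum(pr[5:7, 20:22]), 0)       # spur gone
  expect_true(all(pr[8, 3:38] == 1))          # main line intact

  iso <- matrix(0L, 10, 10)
  iso[cbind(c(2, 5, 8), c(2, 6, 3))] <- 1L
  expect_equal(sum(prune_skeleton(iso, 10, 1)), 0)

  long <- base
  for (i in 1:12) long[8 - i, 14 + i] <- 1L   # 12-px diagonal arm
  pr2 <- prune_skeleton(long, max_spur = 10, border_band = 1)
  expect_gte(sum(pr2) , sum(base) + 8)        # arm survives
})

test_that("minutiae extraction finds branchings and edge endings", {
  y <- matrix(0L, 30, 21)
  y[15:30, 11] <- 1L                          # stem to the bottom edge
  for (i in 1:14) {
    y[15 - i, 11 - ceiling(i / 2)] <- 1L      # arm to the top-left
    y[15 - i, 11 + ceiling(i / 2)] <- 1L      # arm to the top-right
  }
  mm <- extract_minutiae(y, border_band = 3, ending_edges = "all")
  expect_equal(sum(mm$points$kind == "branching"), 1L)
  b <- mm$points[mm$points$kind == "branching", ]
  expect_lte(abs(b$row - 15) + abs(b$col - 11), 4)
  expect_gte(sum(mm$points$kind == "ending"), 2L)
  expect_true(all(mm$points$row[mm$points$kind == "ending"] %in%
                    c(1:3, 28:30)))

  # an interior line away from every edge yields nothing
  interior <- matrix(0L, 30, 30)
  interior[15, 8:22] <- 1L
  mm2 <- extract_minutiae(interior, border_band = 3)
  expect_equal(nrow(mm2$points), 0L)

  # translation equivariance
  shifted <- matrix(0L, 30, 30)
  shifted[19, 12:26] <- 1L
  y2 <- matrix(0L, 40, 31)
  y2[5 + seq_len(30) - 1, 4 + seq_len(21) - 1] <- y[, ]
  mm3 <- extract_minutiae(y2, border_band = 3, ending_edges = "all")
  b3 <- mm3$points[mm3$points$kind == "branching", ]
  expect_equal(c(b3$row - 4, b3$col - 3), c(b$row, b$col))
})

test_that("minutiae_set validates its contents", {
  ok <- data.frame(row = c(2, 5), col = c(3, 7),
                   kind = c("branching", "ending"))
  m <- minutiae_set(ok, c(10, 10))
  expect_s3_class(m, "minutiae_set")
  expect_error(minutiae_set(transform(ok, row = c(2, 12)), c(10, 10)),
               class = "hv_parameter_error")
  expect_error(minutiae_set(ok[c(1, 1), ], c(10, 10)),
               class = "hv_parameter_error")
  expect_error(minutiae_set(transform(ok, kind = c("x", "y")), c(10, 10)),
               class = "hv_parameter_error")
})
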