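# The synthetic subject / capture generator and its ground truth.

test_that("subjects are deterministic in their seed", {
  a <- generate_subject(17)
  b <- generate_subject(17)
  expect_identical(a[setdiff(names(a), "params")],
                   b[setdiff(names(b), "params")])
  c2 <- generate_subject(18)
  expect_false(identical(a$finger_lengths, c2$finger_lengths))
})

test_that("subject anatomy respects the documented invariants", {
  for (seed in c(1, 23, 456)) {
    s <- generate_subject(seed)
    expect_true(all(s$finger_lengths > 0))
    expect_true(all(s$finger_base_widths > 0))
    expect_gt(s$palm_width, 0)
    expect_lt(s$jitter_scale, 0.1)
    tree <- s$vein_tree
    expect_gte(sum(tree$kind == "branching"), 1L)
    expect_gte(sum(tree$kind == "ending"), 2L)
  }
  bad <- cohort_default_params()
  bad$finger_length_sd <- c(0, 1, 1, 1, 1)
  expect_error(generate_subject(1, bad), class = "hv_parameter_error")
})

test_that("zero jitter and zero noise give bit-identical captures", {
  p <- cohort_default_params()
  p$jitter_scale <- 0
  s <- generate_subject(31, p)
  c1 <- render_capture(s, 1, noise_zero())
  c2 <- render_capture(s, 2, noise_zero())
  expect_identical(c1$image, c2$image)
  expect_identical(c1$gt$true_features, c2$gt$true_features)
  expect_identical(c1$gt$true_minutiae$points, c2$gt$true_minutiae$points)

  # and the same capture re-rendered is bit-identical too
  s2 <- generate_subject(31, p)
  c3 <- render_capture(s2, 1, noise_zero())
  expect_identical(c1$image, c3$image)
})

test_that("the rendered frame obeys the acquisition model", {
  s <- generate_subject(8)
  cap <- render_capture(s, 1, noise_default())
  img <- cap$image
  expect_equal(dim(img), c(480L, 640L))
  expect_true(all(img >= 0 & img <= 255))
  sil <- cap$gt$silhouette
  expect_lte(stats::median(img[sil == 0]), 30)   # dark matte background
  expect_gte(stats::median(img[sil == 1]), 140)  # bright hand
  # silhouette is one 8-connected component
  expect_equal(max(label_components(sil)), 1L)
})

test_that("the noise-free silhouette is the analytic mask; noisy segmentation stays close", {
  s <- generate_subject(64)
  cap0 <- render_capture(s, 1, noise_zero())
  seg0 <- largest_component(global_threshold(cap0$image, -60))
  iou0 <- sum(seg0 & cap0$gt$silhouette) / sum(seg0 | cap0$gt$silhouette)
  expect_gte(iou0, 0.995)

  nz <- noise_default()
  nz$rot_range <- 0; nz$trans_range <- 0
  cap <- render_capture(s, 2, nz)
  seg <- largest_component(global_threshold(mean_filter(cap$image, 3), -60))
  iou <- sum(seg & cap$gt$silhouette) / sum(seg | cap$gt$silhouette)
  expect_gte(iou, 0.98)
})

test_that("vein ground truth reflects the generative tree", {
  s <- generate_subject(42)
  n_branch_tree <- sum(s$vein_tree$kind == "branching")
  cap <- render_capture(s, 1, noise_zero())
  gtm <- cap$gt$true_minutiae$points
  expect_equal(sum(gtm$kind == "branching"), n_branch_tree)
  expect_gte(sum(gtm$kind == "ending"), 2L)
  # every ground-truth minutia sits on rendered vein-dark pixels
  dark <- which(cap$image < 170 & cap$image > 100, arr.ind = TRUE)
  for (i in seq_len(nrow(gtm))) {
    d <- sqrt((dark[, 1] - gtm$row[i])^2 + (dark[, 2] - gtm$col[i])^2)
    expect_lte(min(d), 2)
  }
})

test_that("a hand pushed out of frame raises a render error", {
  s <- generate_subject(3)
  shifted <- noise_default()
  shifted$trans_range <- 400   # translation can push the hand off-frame
  hit <- FALSE
  for (ci in 1:6) {
    r <- tryCatch(render_capture(s, ci, shifted), hv_render_error = function(e) e)
    if (inherits(r, "hv_render_error")) { hit <- TRUE; break }
  }
  expect_true(hit)
})

test_that("a 100-subject cohort has pairwise distinct finger lengths", {
  set.seed(77)
  seeds <- sample.int(1e6, 100)
  lens <- t(vapply(seeds, function(sd) generate_subject(sd)$finger_lengths,
                   numeric(5)))
  expect_equal(anyDuplicated(round(lens, 6)), 0L)
})

test_that("genuine feature distances sit below impostor distances", {
  # rank-sum separation on a 20-subject cohort of ground-truth features
  set.seed(99)
  seeds <- sample.int(1e6, 20)
  feats <- list()
  for (i in seq_along(seeds)) {
    s <- generate_subject(seeds[i])
    feats[[i]] <- lapply(1:2, function(ci) {
      render_capture(s, ci, noise_zero())$gt$true_features
    })
  }
  genuine <- vapply(feats, function(f) {
    euclidean_distance(f[[1]], f[[2]])
  }, numeric(1))
  imp <- c()
  for (i in 1:10) {
    imp <- c(imp, euclidean_distance(feats[[i]][[1]], feats[[i + 10]][[1]]))
  }
  expect_lt(stats::wilcox.test(genuine, imp, alternative = "less")$p.value,
            1e-4)
})

test_that("generate_dataset writes the manifest, images and ground truth", {
  out <- file.path(tempdir(), "hv_ds_small")
  unlink(out, recursive = TRUE)
  m <- generate_dataset(2, 3, seed = 5, out_dir = out)
  expect_equal(nrow(m), 6L)
  expect_equal(sum(m$is_enrollment), 4L)
  expect_equal(as.vector(table(m$subject_id[m$is_enrollment])), c(2L, 2L))
  expect_true(all(file.exists(file.path(out, m$path))))
  expect_true(all(file.exists(file.path(out, m$gt_path))))

  # images survive the PNG round trip bit-exactly
  img <- read_gray_png(file.path(out, m$path[1]))
  expect_true(all(img >= 0 & img <= 255))

  # regeneration with the same seed is byte-identical
  out2 <- file.path(tempdir(), "hv_ds_small2")
  unlink(out2, recursive = TRUE)
  generate_dataset(2, 3, seed = 5, out_dir = out2)
  f1 <- readBin(file.path(out, "manifest.csv"), "raw", 1e6)
  f2 <- readBin(file.path(out2, "manifest.csv"), "raw", 1e6)
  expect_identical(f1, f2)
  i1 <- readBin(file.path(out, m$path[1]), "raw", 1e7)
  i2 <- readBin(file.path(out2, m$path[1]), "raw", 1e7)
  expect_identical(i1, i2)
  unlink(c(out, out2), recursive = TRUE)

  expect_error(generate_dataset(1, 3, 1, tempdir()),
               class = "hv_parameter_error")
  expect_error(generate_dataset(2, 2, 1, tempdir()),
               class = "hv_parameter_error")
})

test_that("the study-scale dataset has 280 manifest rows", {
  out <- file.path(tempdir(), "hv_ds_full")
  unlink(out, recursive = TRUE)
  m <- generate_dataset(40, 7, seed = 11, out_dir = out)
  expect_equal(nrow(m), 280L)
  expect_equal(length(unique(m$subject_id)), 40L)
  expect_equal(sum(m$is_enrollment), 80L)
  expect_equal(length(list.files(out, pattern = "\\.png$")), 280L)
  unlink(out, recursive = TRUE)
})
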