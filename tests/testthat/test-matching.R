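# Templates, the four distance metrics, normalization and fusion.

mk_min <- function(pts, frame = c(100, 80)) {
  minutiae_set(data.frame(row = pts[, 1], col = pts[, 2],
                          kind = rep("branching", nrow(pts))), frame)
}

test_that("templates hold per-feature means and floored RMS spreads", {
  m <- mk_min(cbind(c(10, 20), c(10, 30)))
  f1 <- c(a = 10, b = 5); f2 <- c(a = 14, b = 5)
  t1 <- build_template(list(f1, f2), list(m, m), sigma_floor = 0.5)
  expect_equal(unname(t1$feature_means), c(12, 5))
  expect_equal(unname(t1$feature_sigmas), c(2, 0.5))  # zero spread floored
  expect_equal(t1$n_enroll, 2L)

  # identical captures: all sigmas at the floor
  t2 <- build_template(list(f1, f1, f1), list(m, m), sigma_floor = 0.5)
  expect_true(all(t2$feature_sigmas == 0.5))

  # permutation invariance
  t3 <- build_template(list(f2, f1), list(m, m), sigma_floor = 0.5)
  expect_equal(t1$feature_means, t3$feature_means)
  expect_equal(t1$feature_sigmas, t3$feature_sigmas)

  expect_error(build_template(list(f1), list(m)),
               class = "hv_enrollment_error")
})

test_that("Euclidean distance matches its definition", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(62); t <- stats::rnorm(62)
    expect_equal(euclidean_distance(x, t), sqrt(sum((x - t)^2)))
  }
  expect_error(euclidean_distance(1:3, 1:4), class = "hv_parameter_error")
})

test_that("Hamming distance counts strict sigma exceedances", {
  tmpl <- list(feature_means = c(0, 0, 0), feature_sigmas = c(1, 1, 1))
  expect_equal(hamming_distance(c(0, 0, 0), tmpl), 0L)
  # exactly at sigma everywhere: strict inequality, nothing counts
  expect_equal(hamming_distance(c(1, -1, 1), tmpl), 0L)
  expect_equal(hamming_distance(c(2, 0.5, -3), tmpl), 2L)

  # bounded by the feature count
  tmpl62 <- list(feature_means = rep(0, 62), feature_sigmas = rep(0.5, 62))
  expect_equal(hamming_distance(rep(100, 62), tmpl62), 62L)
  expect_error(hamming_distance(1:3, tmpl62), class = "hv_parameter_error")
})

test_that("Hausdorff distances match exhaustive enumeration", {
  a <- mk_min(cbind(0, 0) + 1)          # {(1,1)}
  b <- mk_min(rbind(c(1, 1), c(1, 11))) # {(1,1),(1,11)}
  expect_equal(hausdorff_oriented(a, b), 0)
  expect_equal(hausdorff_oriented(b, a), 10)
  expect_equal(hausdorff(a, b), 10)
  expect_equal(hausdorff(b, a), 10)
  expect_equal(hausdorff(a, a), 0)

  set.seed(32)
  for (i in 1:20) {
    pa <- random_point_set(sample(1:20, 1))
    pb <- random_point_set(sample(1:20, 1))
    expect_equal(hausdorff_oriented(pa, pb), o_hausdorff_oriented(pa, pb))
    expect_equal(hausdorff(pa, pb), o_hausdorff(pa, pb))
    expect_equal(hausdorff(pa, pb), hausdorff(pb, pa))
  }

  # independent cross-check against a reference implementation
  skip_if_not_installed("pracma")
  set.seed(33)
  pa <- random_point_set(12); pb <- random_point_set(9)
  expect_equal(hausdorff(pa, pb), pracma::hausdorff_dist(pa, pb))

  empty <- mk_min(cbind(numeric(0), numeric(0)))
  expect_error(hausdorff(empty, a), class = "hv_empty_set_error")
})

test_that("modified Hausdorff suppresses isolated outliers", {
  a <- mk_min(rbind(c(1, 1)))
  b <- mk_min(rbind(c(1, 1), c(1, 11)))
  # directed averages: d(a,b)=0, d(b,a)=5; score is their max
  expect_equal(mhv(a, b), 5)
  expect_equal(mhv(a, a), 0)

  set.seed(34)
  for (i in 1:20) {
    pa <- random_point_set(sample(2:20, 1))
    pb <- random_point_set(sample(2:20, 1))
    expect_equal(mhv(pa, pb), o_mhv(pa, pb))
  }

  # one distant outlier: HV jumps to >= D, the MHV rise is bounded by D/N
  base <- random_point_set(10)
  with_outlier <- rbind(base, c(500, 500))
  d_out <- min(sqrt((base[, 1] - 500)^2 + (base[, 2] - 500)^2))
  expect_gte(hausdorff(with_outlier, base), d_out)
  expect_lte(mhv(with_outlier, base) - mhv(base, base), d_out / 11 + 1e-9)
})

test_that("min-max normalization maps the batch onto [0,1]", {
  expect_equal(min_max_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- stats::runif(50, 3, 9)
  n1 <- min_max_normalize(x)
  expect_equal(min(n1), 0); expect_equal(max(n1), 1)
  expect_equal(min_max_normalize(5 + 3 * x), n1)  # affine invariance
  expect_error(min_max_normalize(rep(1, 5)),
               class = "hv_degenerate_batch_error")
  expect_error(min_max_normalize(3), class = "hv_degenerate_batch_error")
})

test_that("fusion averages the modalities and accepts at the threshold", {
  d <- fuse_and_decide(0.2, 0.4, 0.5)
  expect_equal(d$fused, 0.3)
  expect_true(d$accept)
  expect_false(fuse_and_decide(1, 1, 0.5)$accept)
  expect_true(fuse_and_decide(0.5, 0.5, 0.5)$accept)   # boundary accepts
  expect_error(fuse_and_decide(-0.1, 0.5), class = "hv_parameter_error")
  expect_error(fuse_and_decide(0.5, 1.2), class = "hv_parameter_error")
})

test_that("all metrics are non-negative and vanish on identical inputs", {
  set.seed(35)
  x <- stats::runif(62, 0, 200)
  tmpl <- list(feature_means = x, feature_sigmas = rep(1, 62))
  expect_equal(euclidean_distance(x, x), 0)
  expect_equal(hamming_distance(x, tmpl), 0L)
  p <- random_point_set(8)
  expect_equal(hausdorff(p, p), 0)
  expect_equal(mhv(p, p), 0)
})

test_that("score_pair wires the four metrics together", {
  set.seed(36)
  f <- stats::runif(62, 10, 150)
  m <- mk_min(random_point_set(6, 60))
  tmpl <- build_template(list(f, f + 1), list(m, m))
  sc <- score_pair(f, m, tmpl, align = FALSE)
  expect_named(sc, c("euclidean", "hamming", "hv", "mhv"))
  expect_equal(sc$hv, 0)
  expect_equal(sc$mhv, 0)
  expect_gte(sc$euclidean, 0)
})
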