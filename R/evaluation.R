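# FMR/FNMR threshold sweeps and the equal error rate.

#' Sweep false match / false non-match rates over a threshold grid
#'
#' At each accept threshold t (distance polarity): FMR is the fraction of
#' impostor comparisons with fused score <= t, FNMR the fraction of genuine
#' comparisons with score > t. FMR is non-decreasing and FNMR non-increasing
#' in t; both are asserted on every call.
#'
#' @param scores data.frame with a numeric score column and a logical
#'   `genuine` column.
#' @param thresholds Ascending grid in [0, 1]; default 0 to 1 in steps of
#'   0.005.
#' @param score_col Name of the score column (default "fused").
#' @return Object of class `error_curves`: list with `thresholds`, `fmr`,
#'   `fnmr`, `eer`, `eer_threshold`, `n_genuine`, `n_impostor`.
#' @export
sweep_errors <- function(scores, thresholds = seq(0, 1, by = 0.005),
                         score_col = "fused") {
  if (!score_col %in% names(scores) || !"genuine" %in% names(scores)) {
    hv_stop("scores must have the score column and a `genuine` flag",
            "evaluation")
  }
  g <- scores[[score_col]][scores$genuine]
  i <- scores[[score_col]][!scores$genuine]
  if (length(g) == 0L || length(i) == 0L) {
    hv_stop("need at least one genuine and one impostor comparison",
            "evaluation")
  }
  thresholds <- sort(thresholds)
  fmr <- vapply(thresholds, function(t) mean(i <= t), numeric(1))
  fnmr <- vapply(thresholds, function(t) mean(g > t), numeric(1))
  stopifnot(all(diff(fmr) >= 0), all(diff(fnmr) <= 0))
  curves <- structure(list(thresholds = thresholds, fmr = fmr, fnmr = fnmr,
                           eer = NA_real_, eer_threshold = NA_real_,
                           n_genuine = length(g), n_impostor = length(i)),
                      class = "error_curves")
  ee <- compute_eer(curves)
  curves$eer <- ee$eer
  curves$eer_threshold <- ee$eer_threshold
  curves
}

#' Equal error rate of an FMR/FNMR curve pair
#'
#' The operating point where the (linearly interpolated) FMR and FNMR curves
#' cross. If the curves touch over an interval, the interval's midpoint
#' threshold is reported.
#'
#' @param curves An `error_curves` object from [sweep_errors()].
#' @return List with `eer` and `eer_threshold`.
#' @export
compute_eer <- function(curves) {
  t <- curves$thresholds
  d <- curves$fmr - curves$fnmr
  if (d[1] >= 0) {
    return(list(eer = (curves$fmr[1] + curves$fnmr[1]) / 2, eer_threshold = t[1]))
  }
  k <- which(d >= 0)[1]
  if (is.na(k)) {
    n <- length(t)
    return(list(eer = (curves$fmr[n] + curves$fnmr[n]) / 2, eer_threshold = t[n]))
  }
  if (d[k] == 0) {
    # possibly a whole interval where the curves touch
    j <- k
    while (j < length(t) && d[j + 1] == 0 &&
           curves$fmr[j + 1] == curves$fmr[k]) j <- j + 1
    return(list(eer = curves$fmr[k], eer_threshold = (t[k] + t[j]) / 2))
  }
  # linear interpolation of both curves on [t[k-1], t[k]]
  f1 <- curves$fmr[k - 1]; f2 <- curves$fmr[k]
  n1 <- curves$fnmr[k - 1]; n2 <- curves$fnmr[k]
  s <- (n1 - f1) / ((f2 - f1) - (n2 - n1))
  list(eer = f1 + s * (f2 - f1),
       eer_threshold = t[k - 1] + s * (t[k] - t[k - 1]))
}

#' @export
print.error_curves <- function(x, ...) {
  cat(sprintf("<error_curves: EER %.3f at threshold %.3f (%d genuine, %d impostor)>\n",
              x$eer, x$eer_threshold, x$n_genuine, x$n_impostor))
  invisible(x)
}

#' Evaluate a dataset manifest end to end
#'
#' Processes every capture, enrolls the flagged captures into per-subject
#' templates, scores every non-enrollment capture against every template
#' (genuine = same subject), min-max-normalizes each metric over the whole
#' comparison batch and sweeps error curves for five systems: hand geometry
#' under Hamming and Euclidean, veins under non-oriented Hausdorff and
#' modified Hausdorff, and the fused system (arithmetic mean of normalized
#' Hamming and modified Hausdorff).
#'
#' Captures on which extraction fails, and subjects without enough usable
#' enrollment captures, are skipped with a warning.
#'
#' @param manifest data.frame (or path to the manifest CSV) with columns
#'   `subject_id`, `capture_idx`, `path`, `is_enrollment`; paths are
#'   resolved relative to the manifest file when a path is given.
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return List with `curves` (named list of `error_curves`: `fused`,
#'   `geometry_hamming`, `geometry_euclidean`, `vein_hv`, `vein_mhv`) and
#'   `scores` (the full comparison table).
#' @export
evaluate_dataset <- function(manifest, config = pipeline_config()) {
  base_dir <- "."
  if (is.character(manifest)) {
    base_dir <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (nrow(manifest) == 0L) hv_stop("manifest is empty", "evaluation")
  manifest <- manifest[order(manifest$subject_id, manifest$capture_idx), ]
  extracted <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$path[i]
    if (!file.exists(path)) path <- file.path(base_dir, manifest$path[i])
    extracted[[i]] <- tryCatch({
      img <- read_gray_png(path)
      process_capture(img, config)
    }, hv_error = function(e) {
      hv_warn(sprintf("capture %s/%s failed: %s", manifest$subject_id[i],
                      manifest$capture_idx[i], conditionMessage(e)),
              "capture_failed")
      NULL
    })
  }
  ok <- !vapply(extracted, is.null, logical(1))
  templates <- list()
  for (sid in unique(manifest$subject_id)) {
    sel <- which(manifest$subject_id == sid & manifest$is_enrollment & ok)
    if (length(sel) < 2L) {
      hv_warn(sprintf("subject %s lacks usable enrollment captures; skipped",
                      sid), "enrollment_skipped")
      next
    }
    templates[[sid]] <- build_template(
      lapply(sel, function(i) extracted[[i]]$features),
      lapply(sel, function(i) extracted[[i]]$minutiae),
      subject_id = sid, sigma_floor = config$sigma_floor)
  }
  if (length(templates) == 0L) {
    hv_stop("no subject could be enrolled", "evaluation")
  }
  probes <- which(!manifest$is_enrollment & ok)
  if (length(probes) == 0L) hv_stop("no probe captures", "evaluation")
  rows <- list()
  for (i in probes) {
    for (sid in names(templates)) {
      sc <- score_pair(extracted[[i]]$features, extracted[[i]]$minutiae,
                       templates[[sid]], align = config$align_minutiae)
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = paste0(manifest$subject_id[i], "_", manifest$capture_idx[i]),
        gallery_id = sid,
        euclidean_raw = sc$euclidean, hamming_raw = sc$hamming,
        hv_raw = sc$hv, mhv_raw = sc$mhv,
        genuine = manifest$subject_id[i] == sid,
        stringsAsFactors = FALSE)
    }
  }
  scores <- do.call(rbind, rows)
  scores <- scores[order(scores$probe_id, scores$gallery_id), ]
  rownames(scores) <- NULL
  for (m in c("euclidean", "hamming", "hv", "mhv")) {
    scores[[paste0(m, "_norm")]] <- min_max_normalize(scores[[paste0(m, "_raw")]])
  }
  scores$fused <- (scores$hamming_norm + scores$mhv_norm) / 2
  grid <- seq(0, 1, by = config$grid_step)
  curves <- list(
    fused = sweep_errors(scores, grid, "fused"),
    geometry_hamming = sweep_errors(scores, grid, "hamming_norm"),
    geometry_euclidean = sweep_errors(scores, grid, "euclidean_norm"),
    vein_hv = sweep_errors(scores, grid, "hv_norm"),
    vein_mhv = sweep_errors(scores, grid, "mhv_norm"))
  list(curves = curves, scores = scores)
}
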