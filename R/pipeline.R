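# End-to-end extraction: raw frame -> hand features + vein minutiae.

#' Process a capture through both extraction pipelines
#'
#' Stages: averaging filter and global mean threshold to segment the hand;
#' pose normalization to fingers-up; landmark detection (contour, hull,
#' valleys, fingertips, bases); the 62-feature geometry vector; ROI cut and
#' rotation; vein segmentation; Zhang-Suen thinning with spur pruning; and
#' minutiae extraction.
#'
#' @param img Gray image matrix (8-bit intensities).
#' @param config Pipeline configuration, see [pipeline_config()].
#' @return List with `features` (named 62-vector), `minutiae`
#'   ([minutiae_set()] in ROI coordinates), `landmarks`, `roi_spec`, `pose`
#'   (list with `angle`, `center`) and `vein_mask`.
#' @export
process_capture <- function(img, config = pipeline_config()) {
  assert_gray(img)
  log_stage(config, "preprocessing", "averaging filter + global threshold")
  sm <- mean_filter(img, config$mean_core)
  bw <- global_threshold(sm, config$hand_tg)
  log_stage(config, "segmentation", "largest component + pose normalization")
  mask <- largest_component(bw)
  pose <- normalize_pose(mask, gray = img)
  log_stage(config, "extraction", "hand landmarks and geometry features")
  landmarks <- detect_landmarks(pose$mask, config)
  features <- measure_hand(pose$mask, landmarks)
  log_stage(config, "extraction", "vein ROI, skeleton and minutiae")
  roi <- extract_roi(pose$gray, landmarks)
  vmask <- segment_veins(roi$image, config)
  skel <- zhang_suen_thin(vmask, pad = 10L)
  skel <- prune_skeleton(skel, config$max_spur, config$border_band,
                         protect_edges = if (config$ending_edges == "top") "tb" else "all")
  minutiae <- extract_minutiae(skel, border_band = config$border_band,
                               branch_min_cn = config$branch_min_cn,
                               ending_edges = config$ending_edges)
  list(features = features, minutiae = minutiae, landmarks = landmarks,
       roi_spec = roi$spec, pose = list(angle = pose$angle,
                                        center = pose$center),
       vein_mask = vmask)
}

#' Minutiae of a processed capture in original image coordinates
#'
#' Undoes the ROI mapping and the pose rotation, so minutiae can be compared
#' across captures or against ground truth.
#'
#' @param result Output of [process_capture()].
#' @param image_dim c(height, width) of the original frame.
#' @return n x 2 matrix of (row, col) in the original frame.
#' @export
minutiae_in_image_coords <- function(result, image_dim) {
  pts <- minutiae_coords(result$minutiae)
  if (nrow(pts) == 0L) return(cbind(row = numeric(0), col = numeric(0)))
  p <- roi_to_image_coords(pts, result$roi_spec)
  # the ROI lives in the pose-normalized frame; rotate back
  ang <- -result$pose$angle
  cen <- result$pose$center
  th <- ang * pi / 180
  co <- cos(th); si <- sin(th)
  dr <- p[, 1] - cen[1]; dc <- p[, 2] - cen[2]
  cbind(row = co * dr - si * dc + cen[1],
        col = si * dr + co * dc + cen[2])
}
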