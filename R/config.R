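# Pipeline configuration: every tunable of the two extraction pipelines and
# the matcher, validated against its documented range.

#' Pipeline configuration
#'
#' Collects all tunables with their defaults. Values without a stated source
#' were calibrated once on the synthetic cohort and are exposed here rather
#' than hard-coded.
#'
#' @param mean_core Averaging-core size for hand preprocessing (odd, >= 3).
#' @param hand_tg Constant subtracted from the global mean intensity when
#'   segmenting the hand. On a dark-background scene the mean sits close to
#'   the background level, so the threshold must lie above it: the default
#'   is negative.
#' @param min_depth Minimum convexity-defect depth (px) for a finger valley.
#' @param cluster_gap Hull-vertex gap (px) separating fingertip clusters.
#' @param curvature_k Contour offset (points) for the fingertip curvature
#'   vectors.
#' @param vein_median_large Window of the texture-suppression median (px).
#' @param vein_surrounding Window of the local mean threshold (px).
#' @param vein_tg Offset of the local threshold; negative values demand that
#'   the (inverted) vein exceed its local mean by `|vein_tg|` counts.
#' @param vein_median_small Window of the speckle-removal median (px).
#' @param closing_radius Disk radius of the gap-closing dilation/erosion.
#' @param max_spur Longest skeleton spur (px) still pruned.
#' @param border_band Frame band (px) where skeleton endings are vein exits.
#' @param branch_min_cn Minimum connection number of a branching minutia
#'   (3 or 4).
#' @param ending_edges "all" or "top": which frame edges yield endings.
#' @param sigma_floor Lower bound on the per-feature RMS spread (px).
#' @param threshold Accept threshold on the fused score (distance polarity:
#'   accept when fused <= threshold).
#' @param grid_step Threshold grid step of the FMR/FNMR sweep.
#' @param align_minutiae Centroid-align minutiae sets before point-set
#'   matching (translation registration).
#' @param n_enroll Enrollment captures per subject.
#' @param verbose Emit per-stage log messages.
#' @return Named list of class `hv_config`.
#' @export
pipeline_config <- function(mean_core = 3L,
                            hand_tg = -60,
                            min_depth = 20,
                            cluster_gap = 10,
                            curvature_k = 15L,
                            vein_median_large = 11L,
                            vein_surrounding = 21L,
                            vein_tg = -3,
                            vein_median_small = 3L,
                            closing_radius = 1L,
                            max_spur = 25L,
                            border_band = 3L,
                            branch_min_cn = 3L,
                            ending_edges = "top",
                            sigma_floor = 0.5,
                            threshold = 0.5,
                            grid_step = 0.005,
                            align_minutiae = FALSE,
                            n_enroll = 2L,
                            verbose = FALSE) {
  cfg <- list(mean_core = as.integer(mean_core), hand_tg = hand_tg,
              min_depth = min_depth, cluster_gap = cluster_gap,
              curvature_k = as.integer(curvature_k),
              vein_median_large = as.integer(vein_median_large),
              vein_surrounding = as.integer(vein_surrounding),
              vein_tg = vein_tg,
              vein_median_small = as.integer(vein_median_small),
              closing_radius = as.integer(closing_radius),
              max_spur = as.integer(max_spur),
              border_band = as.integer(border_band),
              branch_min_cn = as.integer(branch_min_cn),
              ending_edges = ending_edges, sigma_floor = sigma_floor,
              threshold = threshold, grid_step = grid_step,
              align_minutiae = isTRUE(align_minutiae),
              n_enroll = as.integer(n_enroll), verbose = isTRUE(verbose))
  validate_config(cfg)
  structure(cfg, class = c("hv_config", "list"))
}

validate_config <- function(cfg) {
  assert_odd_window(cfg$mean_core, "mean_core")
  assert_odd_window(cfg$vein_median_large, "vein_median_large")
  assert_odd_window(cfg$vein_surrounding, "vein_surrounding")
  assert_odd_window(cfg$vein_median_small, "vein_median_small")
  chk <- function(ok, what) if (!ok) hv_stop(paste("invalid config:", what),
                                             "parameter")
  chk(cfg$min_depth > 0, "min_depth must be positive")
  chk(cfg$cluster_gap > 0, "cluster_gap must be positive")
  chk(cfg$curvature_k >= 3, "curvature_k must be >= 3")
  chk(cfg$closing_radius >= 1, "closing_radius must be >= 1")
  chk(cfg$max_spur >= 1, "max_spur must be >= 1")
  chk(cfg$border_band >= 1, "border_band must be >= 1")
  chk(cfg$branch_min_cn %in% 3:4, "branch_min_cn must be 3 or 4")
  chk(cfg$ending_edges %in% c("all", "top"), "ending_edges must be all|top")
  chk(cfg$sigma_floor > 0, "sigma_floor must be positive")
  chk(cfg$threshold >= 0 && cfg$threshold <= 1, "threshold must be in [0,1]")
  chk(cfg$grid_step > 0 && cfg$grid_step <= 0.5, "grid_step out of range")
  chk(cfg$n_enroll >= 2, "n_enroll must be >= 2")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#'
#' @param path Path to a YAML file of `key: value` pairs.
#' @return Validated configuration, see [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) hv_stop(paste("config file not found:", path), "io")
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    hv_stop(paste("unknown config keys:", paste(bad, collapse = ", ")),
            "parameter")
  }
  do.call(pipeline_config, vals)
}

log_stage <- function(cfg, stage, msg) {
  if (isTRUE(cfg$verbose)) message(sprintf("[%s] %s", stage, msg))
  invisible(NULL)
}
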