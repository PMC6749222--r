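# Disk formats: 8-bit grayscale PNG for images, JSON for templates,
# minutiae and ground truth, CSV for feature rows and score tables.

#' Read and write 8-bit grayscale PNG images
#'
#' @param path File path.
#' @return `read_gray_png()` returns an integer gray matrix (0..255); color
#'   PNGs are reduced to their first channel.
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) hv_stop(paste("image not found:", path), "io")
  x <- tryCatch(png::readPNG(path), error = function(e) {
    hv_stop(paste("cannot read PNG:", path, "-", conditionMessage(e)), "io")
  })
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' @param img Gray matrix with intensities 0..255.
#' @rdname read_gray_png
#' @export
write_gray_png <- function(img, path) {
  assert_gray(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

minutiae_to_list <- function(m) {
  list(frame = list(h = m$frame[1], w = m$frame[2]),
       points = lapply(seq_len(nrow(m$points)), function(i) {
         list(r = m$points$row[i], c = m$points$col[i],
              kind = m$points$kind[i])
       }))
}

minutiae_from_list <- function(x) {
  pts <- if (length(x$points) == 0L) {
    data.frame(row = numeric(0), col = numeric(0), kind = character(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(row = vapply(x$points, function(p) as.numeric(p$r), 0),
               col = vapply(x$points, function(p) as.numeric(p$c), 0),
               kind = vapply(x$points, function(p) as.character(p$kind), ""),
               stringsAsFactors = FALSE)
  }
  minutiae_set(pts, c(as.integer(x$frame$h), as.integer(x$frame$w)))
}

#' Write and read a subject template as JSON
#'
#' One JSON document per subject: feature means and RMS spreads, the
#' reference minutiae set and the enrollment count.
#'
#' @param template An `hv_template` from [build_template()].
#' @param path File path.
#' @return `read_template()` returns the `hv_template`.
#' @export
write_template <- function(template, path) {
  doc <- list(subject_id = template$subject_id,
              n_enroll = template$n_enroll,
              feature_means = as.numeric(template$feature_means),
              feature_sigmas = as.numeric(template$feature_sigmas),
              feature_names = names(template$feature_means),
              reference_minutiae = minutiae_to_list(template$reference_minutiae))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  if (!file.exists(path)) hv_stop(paste("template not found:", path), "io")
  doc <- jsonlite::read_json(path)
  means <- vapply(doc$feature_means, as.numeric, 0)
  sigmas <- vapply(doc$feature_sigmas, as.numeric, 0)
  names(means) <- names(sigmas) <- unlist(doc$feature_names)
  structure(list(subject_id = doc$subject_id,
                 feature_means = means, feature_sigmas = sigmas,
                 reference_minutiae = minutiae_from_list(doc$reference_minutiae),
                 n_enroll = as.integer(doc$n_enroll)),
            class = "hv_template")
}

write_ground_truth <- function(gt, path) {
  doc <- list(true_features = as.list(gt$true_features),
              true_minutiae = minutiae_to_list(gt$true_minutiae),
              pose = gt$pose,
              landmarks = list(
                fingertips = unname(apply(gt$landmarks$fingertips, 1, as.list)),
                valleys = unname(apply(gt$landmarks$valleys, 1, as.list))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_ground_truth <- function(path) {
  if (!file.exists(path)) hv_stop(paste("ground truth not found:", path), "io")
  doc <- jsonlite::read_json(path)
  feats <- vapply(doc$true_features, as.numeric, 0)
  list(true_features = feats,
       true_minutiae = minutiae_from_list(doc$true_minutiae),
       pose = doc$pose)
}
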