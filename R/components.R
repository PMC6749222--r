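# Connected-component labeling (8-connected by default) via breadth-first
# flood fill with a vectorized frontier. Kept in-package because the skeleton
# topology invariants require 8-connectivity specifically.

NB8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
             dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
NB4 <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))

#' Label connected components of a binary image
#'
#' @param mask Binary image matrix.
#' @param connectivity 8 (default) or 4.
#' @return Integer matrix of the same shape; 0 = background, components are
#'   numbered 1, 2, ... in scan order.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_binary(mask)
  if (!connectivity %in% c(4L, 8L)) {
    hv_stop("`connectivity` must be 4 or 8", "parameter")
  }
  nb <- if (connectivity == 8L) NB8 else NB4
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  todo <- which(mask == 1)
  cur <- 0L
  for (seed in todo) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    lab[seed] <- cur
    frontier <- seed
    while (length(frontier) > 0L) {
      r <- (frontier - 1L) %% n + 1L
      c <- (frontier - 1L) %/% n + 1L
      nr <- rep(r, nrow(nb)) + rep(nb[, "dr"], each = length(r))
      nc <- rep(c, nrow(nb)) + rep(nb[, "dc"], each = length(r))
      ok <- nr >= 1L & nr <= n & nc >= 1L & nc <= m
      idx <- unique((nc[ok] - 1L) * n + nr[ok])
      idx <- idx[mask[idx] == 1 & lab[idx] == 0L]
      lab[idx] <- cur
      frontier <- idx
    }
  }
  lab
}

#' Keep only the largest connected component
#'
#' @param mask Binary image matrix with at least one object pixel.
#' @param connectivity 8 (default) or 4.
#' @return Binary image matrix containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 8L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    hv_stop("mask contains no foreground pixels", "segmentation")
  }
  sizes <- tabulate(lab[lab > 0L])
  (lab == which.max(sizes)) * 1L
}

count_components <- function(mask, connectivity = 8L) {
  max(label_components(mask, connectivity))
}
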