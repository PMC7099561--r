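# Probability-map refinement: binarise, keep the largest 8-connected
# region, fill interior holes. Foreground uses 8-connectivity and holes
# (background) 4-connectivity, the standard dual pairing.

#' Binarise a probability map
#'
#' A pixel is foreground iff its probability is `>= threshold`, so
#' threshold 0 yields an all-foreground mask.
#'
#' @param p Matrix of probabilities in \[0, 1\].
#' @param threshold Scalar in \[0, 1\].
#' @return Integer 0/1 mask of the same size.
#' @export
#' @examples
#' binarize(matrix(c(0.3, 0.5), 1), 0.44)
binarize <- function(p, threshold) {
  if (length(threshold) != 1 || threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single value in [0, 1].")
  }
  matrix(as.integer(p >= threshold), nrow(p), ncol(p))
}

#' Keep only the largest connected foreground region
#'
#' Labels the foreground with 8-connectivity and clears everything but the
#' component of maximal pixel count. Ties go to the component containing
#' the smallest pixel in row-major (row, then column) order. An empty mask
#' is returned unchanged.
#'
#' @param m Binary 0/1 mask.
#' @return Binary mask with at most one foreground component.
#' @export
largest_connected_region <- function(m) {
  assert_mask(m)
  storage.mode(m) <- "integer"
  lab <- cpp_label_components(m, eight = TRUE)
  if (max(lab) == 0L) return(m)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # row-major rank of each pixel, minimised per tied component
    rm_rank <- (row(m) - 1L) * ncol(m) + col(m)
    first <- vapply(best, function(l) min(rm_rank[lab == l]), numeric(1))
    best <- best[which.min(first)]
  }
  matrix(as.integer(lab == best), nrow(m), ncol(m))
}

#' Fill interior holes of a binary mask
#'
#' Background regions (4-connectivity) not reachable from the image border
#' become foreground; border-connected background is untouched.
#'
#' @param m Binary 0/1 mask.
#' @return Binary mask with no interior holes.
#' @export
fill_holes <- function(m) {
  assert_mask(m)
  storage.mode(m) <- "integer"
  cpp_fill_holes(m)
}

#' Refine a probability map into the final sFAZ mask
#'
#' The composition `fill_holes(largest_connected_region(binarize(p, t)))`:
#' the output is always a single hole-free foreground component, or empty
#' when binarisation produced nothing. Applying the morphology stage twice
#' changes nothing (idempotent).
#'
#' @inheritParams binarize
#' @return Refined binary mask.
#' @export
refine <- function(p, threshold = 0.44) {
  fill_holes(largest_connected_region(binarize(p, threshold)))
}
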