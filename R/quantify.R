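#' Physical sFAZ area of a segmentation mask
#'
#' Converts a refined binary mask into physical area:
#' `area = N * scan_mm^2 / (H * W)` where `N` is the number of foreground
#' pixels and `H x W` the image size, i.e. each pixel contributes an equal
#' share of the `scan_mm x scan_mm` field of view.
#'
#' @param mask Binary 0/1 mask with at least one pixel.
#' @param scan_mm Physical scan width in mm (> 0); 3 for the emulated
#'   device's macular scans.
#' @return A one-row tibble: `n_pixels`, `area_mm2`, `scan_mm`, `H`, `W`.
#' @export
#' @examples
#' m <- matrix(0L, 64, 64); m[20:40, 20:40] <- 1L
#' compute_area(m, scan_mm = 3)
compute_area <- function(mask, scan_mm) {
  assert_mask(mask)
  if (length(mask) == 0) abort("Empty image: mask has no pixels.")
  if (length(scan_mm) != 1 || scan_mm <= 0) {
    abort("`scan_mm` must be a single positive value.")
  }
  n <- sum(mask == 1L)
  tibble::tibble(
    n_pixels = as.integer(n),
    area_mm2 = n * scan_mm^2 / (nrow(mask) * ncol(mask)),
    scan_mm = scan_mm,
    H = nrow(mask),
    W = ncol(mask)
  )
}
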