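# Resizing, per-image min-max normalisation and rigid augmentation.

# Separable linear interpolation matrix mapping n_in samples to n_out,
# half-pixel-centre convention, border clamped. Rows sum to 1, and the
# matrix is the identity when n_in == n_out.
interp_matrix <- function(n_in, n_out) {
  p <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  p <- pmin(pmax(p, 0), n_in - 1)
  i0 <- pmin(floor(p), n_in - 1)
  i1 <- pmin(i0 + 1, n_in - 1)
  w <- p - i0
  A <- matrix(0, n_out, n_in)
  A[cbind(seq_len(n_out), i0 + 1)] <- A[cbind(seq_len(n_out), i0 + 1)] + (1 - w)
  A[cbind(seq_len(n_out), i1 + 1)] <- A[cbind(seq_len(n_out), i1 + 1)] + w
  A
}

nearest_index <- function(n_in, n_out) {
  idx <- floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1
  pmin(pmax(idx, 1), n_in)
}

#' Resize an image or mask to the network's standard square resolution
#'
#' Intensity images are resampled bilinearly; binary masks use
#' nearest-neighbour so the output stays binary. A same-size resize is the
#' exact identity.
#'
#' @param image Numeric intensity matrix, or a 0/1 (or 0/255) mask when
#'   `kind = "mask"`.
#' @param target Side length of the square output (default 704, the
#'   resolution the full-scale network consumes). Must be >= 32.
#' @param kind `"image"` (bilinear) or `"mask"` (nearest-neighbour).
#' @return A `target x target` matrix; integer-valued for masks.
#' @export
#' @examples
#' resize_to_standard(matrix(1:16, 4, 4) * 10, target = 32)[1:2, 1:2]
resize_to_standard <- function(image, target = 704,
                               kind = c("image", "mask")) {
  kind <- match.arg(kind)
  if (length(target) != 1 || target < 32) {
    abort("`target` must be a single integer >= 32 (square output only).")
  }
  target <- as.integer(target)
  H <- nrow(image); W <- ncol(image)
  if (kind == "mask") {
    out <- image[nearest_index(H, target), nearest_index(W, target),
                 drop = FALSE]
    storage.mode(out) <- "integer"
    return(out)
  }
  if (H == target && W == target) return(image)
  A <- interp_matrix(H, target)
  B <- interp_matrix(W, target)
  A %*% image %*% t(B)
}

#' Min-max normalisation of an intensity image
#'
#' Rescales an image X to `(X - X_min) / (X_max - X_min)` where `X_min` and
#' `X_max` are the per-image extremes, so every non-constant image spans
#' exactly \[0, 1\]. Constant images map to all zeros.
#'
#' @param image Numeric intensity matrix.
#' @return Numeric matrix of the same size with values in \[0, 1\].
#' @export
#' @examples
#' normalize_minmax(matrix(c(50, 100, 150, 150), 2))
normalize_minmax <- function(image) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) return(matrix(0, nrow(image), ncol(image)))
  (image - lo) / (hi - lo)
}

rot90cw <- function(m) t(m[rev(seq_len(nrow(m))), , drop = FALSE])

apply_rigid <- function(m, transform) {
  switch(transform,
    identity = m,
    rot90 = rot90cw(m),
    rot180 = rot90cw(rot90cw(m)),
    rot270 = rot90cw(rot90cw(rot90cw(m))),
    flip_h = m[, rev(seq_len(ncol(m))), drop = FALSE],
    flip_v = m[rev(seq_len(nrow(m))), , drop = FALSE],
    abort(sprintf("Unknown rigid transform '%s'.", transform))
  )
}

rigid_transforms <- function() {
  c("identity", "rot90", "rot180", "rot270", "flip_h", "flip_v")
}

#' Rigid augmentation of an image/mask pair
#'
#' Expands one sample into the six rigid variants used to enlarge the
#' training set (identity, the three quarter-turn rotations, and the
#' horizontal and vertical flips), applying each transform identically to
#' the image and its mask. 405 source images become 2430 augmented pairs.
#'
#' @param image Square numeric matrix.
#' @param mask Binary mask of the same size.
#' @return A named list of 6 `list(image, mask, transform)` entries.
#' @export
#' @examples
#' a <- augment_rigid(matrix(1:16, 4, 4), matrix(0L, 4, 4))
#' names(a)
augment_rigid <- function(image, mask) {
  if (nrow(image) != ncol(image)) {
    abort("Augmentation requires square inputs (rotations preserve shape).")
  }
  assert_same_dim(image, mask, "image and mask")
  out <- lapply(rigid_transforms(), function(tr) {
    list(image = apply_rigid(image, tr),
         mask = apply_rigid(mask, tr),
         transform = tr)
  })
  names(out) <- rigid_transforms()
  out
}
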