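# Readers/writers for images, masks, probability maps and the cohort
# manifest. Images and masks travel as 8-bit grayscale PNG (masks 0/255 on
# disk, 0/1 in memory); probability maps as 16-bit grayscale TIFF so values
# near the binarisation threshold are not quantised away.

#' Image, mask and probability-map I/O
#'
#' @param image Integer intensity matrix in \[0, 255\].
#' @param mask Binary 0/1 matrix.
#' @param p Probability matrix in \[0, 1\].
#' @param path File path.
#' @return Readers return the in-memory representation (intensity matrix,
#'   0/1 mask, probability matrix); writers return the path invisibly.
#' @name faz_io
NULL

#' @rdname faz_io
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname faz_io
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(round(x * 255)), nrow(x), ncol(x))
}

#' @rdname faz_io
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' @rdname faz_io
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  v <- round(x * 255)
  if (!all(v %in% c(0, 255))) {
    abort(sprintf("Mask '%s' is not binary (0/255).", path))
  }
  matrix(as.integer(v == 255), nrow(x), ncol(x))
}

#' @rdname faz_io
#' @export
write_probmap <- function(p, path) {
  tiff::writeTIFF(clip01(p), path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname faz_io
#' @export
read_probmap <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

manifest_columns <- c("subject_id", "myopia_class", "group_id",
                      "brightness", "contrast", "image_path", "mask_path")

#' Load and validate a cohort manifest
#'
#' Reads a `manifest.csv` (one row per exported image), checks the required
#' columns, that every `group_id` is a registered B/C group with matching
#' brightness/contrast, that all referenced files exist, and that every
#' mask decodes to a strictly binary image.
#'
#' @param path Path to the CSV.
#' @return A validated tibble (columns `subject_id`, `myopia_class`,
#'   `group_id`, `brightness`, `contrast`, `image_path`, `mask_path`, and
#'   `scan_mm` when present).
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest '%s' not found.", path))
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  missing <- setdiff(manifest_columns, names(m))
  if (length(missing)) {
    abort(sprintf("Manifest is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, basename(p)))
  m$image_path <- resolve(m$image_path)
  m$mask_path <- resolve(m$mask_path)
  bc <- bc_settings()
  for (i in seq_len(nrow(m))) {
    g <- m$group_id[i]
    j <- match(g, bc$group_id)
    if (is.na(j)) {
      abort(sprintf("Manifest row %d: unknown group_id %s.", i, g))
    }
    if (m$brightness[i] != bc$brightness[j] ||
        m$contrast[i] != bc$contrast[j]) {
      abort(sprintf("Manifest row %d: B/C (%s/%s) does not match group %d.",
                    i, m$brightness[i], m$contrast[i], g))
    }
    if (!file.exists(m$image_path[i])) {
      abort(sprintf("Manifest row %d: image file missing: %s", i,
                    m$image_path[i]))
    }
  }
  for (mp in unique(m$mask_path)) {
    if (!file.exists(mp)) abort(sprintf("Mask file missing: %s", mp))
    read_mask_png(mp)  # errors if not binary
  }
  m
}

#' @rdname load_manifest
#' @param manifest Manifest tibble.
#' @export
save_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read the samples referenced by a manifest into memory
#'
#' @param manifest A [load_manifest()] tibble.
#' @return List of `list(image, gt, subject_id, bc)` samples.
#' @export
load_samples <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_image_png(manifest$image_path[i]),
         gt = read_mask_png(manifest$mask_path[i]),
         subject_id = manifest$subject_id[i],
         bc = bc_setting(manifest$group_id[i]))
  })
}
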