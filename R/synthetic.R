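#' The nine brightness/contrast rendering settings
#'
#' The export viewer of the OCTA device renders the superficial-layer en-face
#' image under a brightness/contrast (B/C) pair. The study protocol exports
#' each eye under nine settings: the default 130/20 plus four brightness
#' variations at fixed contrast and four contrast variations at fixed
#' brightness. Higher values of either parameter give darker images.
#'
#' @return A tibble with columns `group_id` (1-9), `brightness`, `contrast`.
#' @export
#' @examples
#' bc_settings()
bc_settings <- function() {
  tibble::tibble(
    group_id   = 1:9,
    brightness = c(130L, 90L, 110L, 150L, 170L, 130L, 130L, 130L, 130L),
    contrast   = c(20L, 20L, 20L, 20L, 20L, 0L, 10L, 30L, 40L)
  )
}

#' @rdname bc_settings
#' @param group_id Integer group id in 1-9.
#' @export
bc_setting <- function(group_id) {
  tab <- bc_settings()
  row <- tab[tab$group_id == group_id, ]
  if (nrow(row) != 1) {
    abort(sprintf("Unknown B/C group id: %s (must be 1-9).",
                  paste(group_id, collapse = ", ")))
  }
  as.list(row)
}

#' Specification of one synthetic subject
#'
#' Describes the anatomy of one simulated eye: the foveal avascular zone
#' (FAZ) as a star-convex region whose boundary radius is a circle of radius
#' `faz_radius_mm` modulated by low-order angular harmonics, plus the
#' capillary plexus density. The FAZ boundary radius at polar angle `theta`
#' (about `faz_center`) is
#' `faz_radius_mm * (1 + sum_i a_i * cos((i + 1) * theta + phi_i))`,
#' where `(a_i, phi_i)` is the i-th entry of `boundary_harmonics`.
#'
#' @param subject_id Character id.
#' @param myopia_class `"high"` or `"low"` (spherical equivalent <= -6 D
#'   defines high myopia in the emulated protocol).
#' @param faz_center Length-2 numeric, fractional (row, col) image
#'   coordinates of the FAZ centre.
#' @param faz_radius_mm Mean FAZ boundary radius in mm, in \[0.15, 0.5\].
#' @param boundary_harmonics List of `c(amplitude, phase)` pairs; the i-th
#'   pair modulates angular order `i + 1`. Amplitudes must sum to < 0.5 so
#'   the region stays star-convex about the centre.
#' @param vessel_density Capillary coverage parameter in (0, 1\].
#' @param rng_seed Integer seed driving the stochastic parts of rendering.
#' @return An object of class `faz_subject_spec`.
#' @export
#' @examples
#' subject_spec("s01", "low", faz_radius_mm = 0.3)
subject_spec <- function(subject_id,
                         myopia_class = c("low", "high"),
                         faz_center = c(0.5, 0.5),
                         faz_radius_mm = 0.3,
                         boundary_harmonics = list(),
                         vessel_density = 0.6,
                         rng_seed = 1L) {
  myopia_class <- match.arg(myopia_class)
  if (faz_radius_mm < 0.15 || faz_radius_mm > 0.5) {
    abort("`faz_radius_mm` must lie in [0.15, 0.5].")
  }
  amps <- vapply(boundary_harmonics, function(h) abs(h[[1]]), numeric(1))
  if (length(amps) && sum(amps) >= 0.5) {
    abort("Boundary harmonic amplitudes too large: region not star-convex.")
  }
  if (vessel_density < 0 || vessel_density > 1) {
    abort("`vessel_density` must lie in [0, 1].")
  }
  structure(
    list(subject_id = as.character(subject_id),
         myopia_class = myopia_class,
         faz_center = as.numeric(faz_center),
         faz_radius_mm = faz_radius_mm,
         boundary_harmonics = boundary_harmonics,
         vessel_density = vessel_density,
         rng_seed = as.integer(rng_seed)),
    class = "faz_subject_spec"
  )
}

# FAZ boundary radius (in pixels) at polar angles `theta`.
faz_radius_px <- function(spec, theta, px_per_mm) {
  r <- rep(1, length(theta))
  hs <- spec$boundary_harmonics
  for (i in seq_along(hs)) {
    r <- r + hs[[i]][[1]] * cos((i + 1) * theta + hs[[i]][[2]])
  }
  spec$faz_radius_mm * px_per_mm * r
}

#' Generate the ground-truth FAZ mask for one subject
#'
#' Rasterises the star-convex FAZ boundary of a [subject_spec()] into a
#' binary mask. The construction guarantees a single 8-connected,
#' hole-free foreground region. No randomness is involved: the mask is a
#' deterministic function of the subject's geometry.
#'
#' @param spec A [subject_spec()].
#' @param size Integer length-2 `(H, W)`, both >= 64.
#' @param scan_mm Physical scan width in mm (default 3).
#' @return An `H x W` integer matrix with values 0/1 (1 = FAZ).
#' @export
#' @examples
#' m <- generate_faz_mask(subject_spec("s", faz_radius_mm = 0.3), c(64, 64))
#' sum(m) / (64 * 64)
generate_faz_mask <- function(spec, size, scan_mm = 3) {
  H <- as.integer(size[[1]]); W <- as.integer(size[[2]])
  if (H < 64 || W < 64) abort("Mask size must be at least 64 x 64.")
  px_per_mm <- W / scan_mm
  th_grid <- seq(0, 2 * pi, length.out = 721)
  r_grid <- faz_radius_px(spec, th_grid, px_per_mm)
  if (any(r_grid <= 0)) {
    abort("Perturbed FAZ boundary self-intersects (radius <= 0).")
  }
  cr <- spec$faz_center[[1]] * H
  cc <- spec$faz_center[[2]] * W
  rmax <- max(r_grid)
  if (cr - rmax < 1 || cr + rmax > H || cc - rmax < 1 || cc + rmax > W) {
    abort("FAZ boundary exits the image.")
  }
  rows <- matrix(seq_len(H) - cr, H, W)
  cols <- matrix(rep(seq_len(W) - cc, each = H), H, W)
  d <- sqrt(rows^2 + cols^2)
  theta <- atan2(cols, rows)
  mask <- matrix(0L, H, W)
  mask[d <= faz_radius_px(spec, theta, px_per_mm)] <- 1L
  mask
}

# Eroded FAZ interior: same boundary with the radius shrunk by `margin_px`.
faz_interior <- function(spec, size, scan_mm, margin_px) {
  H <- as.integer(size[[1]]); W <- as.integer(size[[2]])
  px_per_mm <- W / scan_mm
  cr <- spec$faz_center[[1]] * H
  cc <- spec$faz_center[[2]] * W
  rows <- matrix(seq_len(H) - cr, H, W)
  cols <- matrix(rep(seq_len(W) - cc, each = H), H, W)
  d <- sqrt(rows^2 + cols^2)
  theta <- atan2(cols, rows)
  r <- pmax(faz_radius_px(spec, theta, px_per_mm) - margin_px, 0)
  out <- matrix(0L, H, W)
  out[d <= r] <- 1L
  out
}

#' Render the baseline (Group 1) vessel image for one subject
#'
#' Draws a bright curvilinear capillary plexus on a dark background using
#' seeded biased random walks with a soft (blurred) stroke profile.
#' Capillaries cover the field outside the FAZ and terminate at its rim, so
#' the eroded FAZ interior contains background and noise only. The output
#' corresponds to the device's default 130/20 rendering (Group 1).
#'
#' @param spec A [subject_spec()].
#' @param faz Binary FAZ mask from [generate_faz_mask()], same size.
#' @param size Integer `(H, W)`.
#' @param scan_mm Physical scan width in mm.
#' @return An `H x W` matrix of integer intensities in \[0, 255\].
#' @export
generate_vessel_image <- function(spec, faz, size, scan_mm = 3) {
  H <- as.integer(size[[1]]); W <- as.integer(size[[2]])
  assert_mask(faz, "faz")
  if (!identical(dim(faz), c(H, W))) abort("`faz` does not match `size`.")
  interior <- faz_interior(spec, size, scan_mm,
                           margin_px = max(1, round(1.5 * W / 128)))
  with_seed(spec$rng_seed, {
    canvas <- matrix(0, H, W)
    n_walk <- round(spec$vessel_density * H * W / 55)
    n_steps <- round(2.2 * W)
    for (w in seq_len(n_walk)) {
      # start anywhere outside the FAZ
      repeat {
        r0 <- runif(1, 2, H - 1); c0 <- runif(1, 2, W - 1)
        if (faz[round(r0), round(c0)] == 0L) break
      }
      dir0 <- runif(1, 0, 2 * pi)
      turns <- rnorm(n_steps, 0, 0.25)
      dirs <- dir0 + cumsum(turns)
      rr <- r0 + cumsum(sin(dirs))
      cc <- c0 + cumsum(cos(dirs))
      keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      rr <- rr[keep]; cc <- cc[keep]
      if (!length(rr)) next
      ri <- round(rr); ci <- round(cc)
      inside <- interior[cbind(ri, ci)] == 1L
      stop_at <- if (any(inside)) which(inside)[1] - 1L else length(ri)
      if (stop_at < 1) next
      idx <- cbind(ri[seq_len(stop_at)], ci[seq_len(stop_at)])
      canvas[idx] <- canvas[idx] + 1
    }
    canvas <- pmin(canvas, 1)
    # soft stroke profile: one pass of a small separable blur
    canvas <- blur3(canvas)
    canvas[interior == 1L] <- 0
    img <- 20 + rnorm(H * W, 0, 6) + 200 * pmin(canvas, 1)
    matrix(as.integer(pmin(pmax(round(img), 0), 255)), H, W)
  })
}

# 3x3 binomial blur with edge replication, via shifted sums.
blur3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(H) + dr, 1), H)
    ci <- pmin(pmax(seq_len(W) + dc, 1), W)
    m[ri, ci, drop = FALSE]
  }
  k <- c(1, 2, 1) / 4
  out <- matrix(0, H, W)
  for (i in -1:1) for (j in -1:1) {
    out <- out + k[i + 2] * k[j + 2] * shift(x, i, j)
  }
  out
}

#' Apply a brightness/contrast rendering to a baseline image
#'
#' Emulates the device viewer's B/C behaviour with a monotone pointwise
#' affine-then-clip remap: `out = clip(gain(contrast) * (x - pivot(brightness)))`
#' with `gain(c) = (148 - c)/128` and `pivot(b) = 0.5 * (b - 130)`. The
#' default setting 130/20 (Group 1) is the exact identity; mean intensity is
#' non-increasing in brightness at fixed contrast and non-increasing in
#' contrast at fixed brightness (higher values of either give darker
#' images), and lowering the contrast raises the visibility of faint
#' strokes. The true viewer mapping is proprietary; only its direction of
#' effect is emulated.
#'
#' @param image Integer intensity matrix (the Group-1 baseline rendering).
#' @param bc One row of [bc_settings()] (or a list with `group_id`,
#'   `brightness`, `contrast`).
#' @return Remapped integer intensity matrix, same size.
#' @export
#' @examples
#' img <- matrix(0:255, 16, 16)
#' identical(apply_bc_transform(img, bc_setting(1)), img)
apply_bc_transform <- function(image, bc) {
  bc <- as.list(bc)
  ref <- bc_setting(bc$group_id)
  if (!identical(as.integer(ref$brightness), as.integer(bc$brightness)) ||
      !identical(as.integer(ref$contrast), as.integer(bc$contrast))) {
    abort("`bc` does not match the registered settings for its group id.")
  }
  gain <- (148 - bc$contrast) / 128
  pivot <- 0.5 * (bc$brightness - 130)
  out <- round(gain * (image - pivot))
  matrix(as.integer(pmin(pmax(out, 0), 255)), nrow(image), ncol(image))
}

#' Simulate a full multi-rendering OCTA cohort
#'
#' Draws `n_subjects` synthetic eyes (FAZ geometry, plexus density) and
#' renders each under all nine B/C settings, yielding `n_subjects * 9`
#' image/mask samples. The ground-truth mask is drawn once per subject and
#' shared pixel-for-pixel across its nine renderings, exactly as a manual
#' grader would delineate the FAZ once per eye.
#'
#' @param n_subjects Number of subjects (> 0). The emulated study uses 45.
#' @param n_high_myopia Number of subjects labelled high-myopic (the
#'   emulated study uses 12 of 45).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   `(n_subjects, n_high_myopia, seed, size)`.
#' @param size Image size `(H, W)`; default `c(128, 128)` (scaled down from
#'   the device's native export; use `c(704, 704)` for full scale).
#' @param scan_mm Physical scan width in mm (default 3).
#' @return An object of class `faz_cohort`: list with `samples` (list of
#'   `list(image, gt, subject_id, bc)`), `manifest` (tibble), `subjects`
#'   (tibble of subject parameters), `size`, `scan_mm`, `seed`.
#' @export
#' @examples
#' coh <- generate_cohort(2, 1, seed = 7, size = c(64, 64))
#' nrow(coh$manifest)
generate_cohort <- function(n_subjects, n_high_myopia, seed,
                            size = c(128, 128), scan_mm = 3) {
  if (n_subjects <= 0) abort("`n_subjects` must be positive.")
  if (n_high_myopia < 0 || n_high_myopia > n_subjects) {
    abort("`n_high_myopia` must be between 0 and `n_subjects`.")
  }
  specs <- with_seed(derive_seed(seed, "cohort"), {
    high <- sample(n_subjects, n_high_myopia)
    lapply(seq_len(n_subjects), function(i) {
      n_h <- sample(2:3, 1)
      harmonics <- lapply(seq_len(n_h), function(j) {
        c(runif(1, 0, 0.07), runif(1, 0, 2 * pi))
      })
      subject_spec(
        subject_id = sprintf("s%03d", i),
        myopia_class = if (i %in% high) "high" else "low",
        faz_center = 0.5 + runif(2, -0.03, 0.03),
        faz_radius_mm = runif(1, 0.18, 0.44),
        boundary_harmonics = harmonics,
        vessel_density = runif(1, 0.5, 0.7),
        rng_seed = derive_seed(seed, paste0("subject", i))
      )
    })
  })
  bcs <- bc_settings()
  samples <- list()
  for (spec in specs) {
    gt <- generate_faz_mask(spec, size, scan_mm)
    base <- generate_vessel_image(spec, gt, size, scan_mm)
    for (g in bcs$group_id) {
      bc <- bc_setting(g)
      samples[[length(samples) + 1]] <- list(
        image = apply_bc_transform(base, bc),
        gt = gt,
        subject_id = spec$subject_id,
        bc = bc
      )
    }
  }
  subjects <- tibble::tibble(
    subject_id = vapply(specs, `[[`, character(1), "subject_id"),
    myopia_class = vapply(specs, `[[`, character(1), "myopia_class"),
    faz_radius_mm = vapply(specs, `[[`, numeric(1), "faz_radius_mm"),
    vessel_density = vapply(specs, `[[`, numeric(1), "vessel_density")
  )
  manifest <- tibble::tibble(
    subject_id = vapply(samples, `[[`, character(1), "subject_id"),
    myopia_class = subjects$myopia_class[
      match(vapply(samples, `[[`, character(1), "subject_id"),
            subjects$subject_id)],
    group_id = vapply(samples, function(s) s$bc$group_id, integer(1)),
    brightness = vapply(samples, function(s) s$bc$brightness, integer(1)),
    contrast = vapply(samples, function(s) s$bc$contrast, integer(1)),
    image_path = NA_character_,
    mask_path = NA_character_
  )
  structure(
    list(samples = samples, manifest = manifest, subjects = subjects,
         size = c(as.integer(size[[1]]), as.integer(size[[2]])),
         scan_mm = scan_mm, seed = as.integer(seed)),
    class = "faz_cohort"
  )
}

#' @export
print.faz_cohort <- function(x, ...) {
  cat(sprintf(
    "<faz_cohort> %d subjects x 9 B/C renderings = %d samples (%dx%d px, %g mm scan)\n",
    nrow(x$subjects), length(x$samples), x$size[1], x$size[2], x$scan_mm))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes each image and per-subject ground-truth mask as 8-bit grayscale
#' PNG (masks encoded 0/255) plus a `manifest.csv` with one row per image.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble with `image_path`/`mask_path` filled in,
#'   invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- cohort$manifest
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    ip <- file.path(dir, sprintf("%s_g%d.png", s$subject_id, s$bc$group_id))
    mp <- file.path(dir, sprintf("%s_mask.png", s$subject_id))
    write_image_png(s$image, ip)
    if (!file.exists(mp)) write_mask_png(s$gt, mp)
    manifest$image_path[i] <- ip
    manifest$mask_path[i] <- mp
  }
  manifest$scan_mm <- cohort$scan_mm
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
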