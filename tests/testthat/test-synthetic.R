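# Synthetic OCTA cohort generator: FAZ geometry, vessel rendering, B/C
# remapping and cohort assembly.

test_that("unperturbed FAZ mask is a disc of the requested physical area", {
  sp <- subject_spec("s", faz_radius_mm = 0.3)
  m <- generate_faz_mask(sp, c(128, 128), scan_mm = 3)
  expected <- pi * (0.3 * 128 / 3)^2
  expect_lt(abs(sum(m) / expected - 1), 0.02)
})

test_that("FAZ masks are a single 8-connected hole-free region of ~pi r^2", {
  set.seed(42)
  for (i in 1:5) {
    sp <- subject_spec(
      paste0("s", i),
      faz_center = 0.5 + runif(2, -0.03, 0.03),
      faz_radius_mm = runif(1, 0.18, 0.44),
      boundary_harmonics = list(c(runif(1, 0, 0.07), runif(1, 0, 2 * pi)),
                                c(runif(1, 0, 0.07), runif(1, 0, 2 * pi))))
    m <- generate_faz_mask(sp, c(96, 96), scan_mm = 3)
    expect_equal(oracle_n_components(m), 1)
    expect_equal(oracle_n_holes(m), 0)
    expected <- pi * (sp$faz_radius_mm * 96 / 3)^2
    expect_lt(abs(sum(m) / expected - 1), 0.15)
  }
})

test_that("mask generation ignores the rendering seed", {
  a <- subject_spec("s", faz_radius_mm = 0.25, rng_seed = 1L)
  b <- subject_spec("s", faz_radius_mm = 0.25, rng_seed = 999L)
  expect_identical(generate_faz_mask(a, c(64, 64)),
                   generate_faz_mask(b, c(64, 64)))
})

test_that("invalid FAZ geometry is rejected", {
  expect_error(subject_spec("s", boundary_harmonics =
                              list(c(0.3, 0), c(0.3, 0))), "star-convex")
  # radius 0.5 mm = 1/6 of a 3 mm scan; off-centre pushes it off the edge
  sp <- subject_spec("s", faz_center = c(0.08, 0.5), faz_radius_mm = 0.5)
  expect_error(generate_faz_mask(sp, c(64, 64)), "exits the image")
  expect_error(generate_faz_mask(subject_spec("s"), c(32, 32)), "at least 64")
})

test_that("vessel rendering is seeded-deterministic and leaves the FAZ dark", {
  sp <- subject_spec("s", faz_radius_mm = 0.35, vessel_density = 0.6,
                     rng_seed = 5L)
  gt <- generate_faz_mask(sp, c(64, 64))
  img1 <- generate_vessel_image(sp, gt, c(64, 64))
  img2 <- generate_vessel_image(sp, gt, c(64, 64))
  expect_identical(img1, img2)
  interior <- fazseg:::faz_interior(sp, c(64, 64), 3, margin_px = 2)
  expect_gte(mean(img1[interior == 0]) - mean(img1[interior == 1]), 30)
})

test_that("zero vessel density gives background and noise only", {
  sp <- subject_spec("s", vessel_density = 0, rng_seed = 3L)
  gt <- generate_faz_mask(sp, c(64, 64))
  img <- generate_vessel_image(sp, gt, c(64, 64))
  # background level 20, noise sd 6: no pixel should approach stroke level
  expect_lt(max(img), 80)
})

test_that("B/C group 1 is the exact identity and the remap is monotone", {
  coh <- tiny_cohort()
  base <- coh$samples[[1]]$image
  expect_identical(apply_bc_transform(base, bc_setting(1)), base)
  # darker with increasing brightness at contrast 20 (groups 2,3,1,4,5)
  mb <- vapply(c(2, 3, 1, 4, 5),
               function(g) mean(apply_bc_transform(base, bc_setting(g))),
               numeric(1))
  expect_true(all(diff(mb) <= 0))
  # darker with increasing contrast at brightness 130 (groups 6,7,1,8,9)
  mc <- vapply(c(6, 7, 1, 8, 9),
               function(g) mean(apply_bc_transform(base, bc_setting(g))),
               numeric(1))
  expect_true(all(diff(mc) <= 0))
  # lower contrast makes faint strokes more visible
  faint20 <- sum(apply_bc_transform(base, bc_setting(1)) > 60)
  faint0 <- sum(apply_bc_transform(base, bc_setting(6)) > 60)
  expect_gte(faint0, faint20)
})

test_that("a constant image stays constant under every B/C remap", {
  flat <- matrix(100L, 64, 64)
  for (g in 1:9) {
    out <- apply_bc_transform(flat, bc_setting(g))
    expect_equal(length(unique(as.vector(out))), 1)
  }
})

test_that("unknown or inconsistent B/C settings are rejected", {
  img <- matrix(0L, 4, 4)
  expect_error(apply_bc_transform(img, list(group_id = 10, brightness = 130,
                                            contrast = 20)), "Unknown")
  expect_error(apply_bc_transform(img, list(group_id = 1, brightness = 90,
                                            contrast = 20)), "match")
})

test_that("cohorts have 9 renderings per subject sharing one GT", {
  coh <- generate_cohort(1, 0, seed = 2, size = c(64, 64))
  expect_length(coh$samples, 9)
  gts <- lapply(coh$samples, `[[`, "gt")
  for (g in gts[-1]) expect_identical(g, gts[[1]])

  coh5 <- generate_cohort(5, 2, seed = 4, size = c(64, 64))
  expect_length(coh5$samples, 45)
  expect_equal(nrow(coh5$manifest), 45)
  expect_equal(sum(coh5$subjects$myopia_class == "high"), 2)
  # per-subject GT identity across the nine renderings, pixelwise
  subj <- vapply(coh5$samples, `[[`, character(1), "subject_id")
  for (id in unique(subj)) {
    gts <- lapply(coh5$samples[subj == id], `[[`, "gt")
    for (g in gts[-1]) expect_identical(g, gts[[1]])
  }
})

test_that("cohort generation is deterministic under its seed", {
  a <- generate_cohort(2, 1, seed = 9, size = c(64, 64))
  b <- generate_cohort(2, 1, seed = 9, size = c(64, 64))
  expect_identical(a$samples[[5]]$image, b$samples[[5]]$image)
  expect_identical(a$subjects, b$subjects)
  expect_error(generate_cohort(0, 0, seed = 1), "positive")
})
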