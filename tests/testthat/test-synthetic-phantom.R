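# Phantom-section generation, artifact injection, dataset assembly.

test_that("noiseless uniformity section is exactly flat inside the disk", {
  img <- generate_section("uniformity", noise_sigma = 0, seed = 3)
  inner <- phantomiq:::disc_mask(256, 0.5, c(0, 0), 54)
  expect_true(all(img$pixels[inner] == img$geometry$background))
  expect_identical(img$labels, character(0))
})

test_that("generation is a pure function of (parameters, seed)", {
  a <- generate_section("high_contrast", noise_sigma = 20, seed = 7)
  b <- generate_section("high_contrast", noise_sigma = 20, seed = 7)
  expect_identical(a$pixels, b$pixels)
  c <- generate_section("high_contrast", noise_sigma = 20, seed = 8)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_section("uniformity", seed = 1))
  invisible(generate_wl_image(noise_sigma = 5, seed = 2))
  expect_identical(runif(1), before)
})

test_that("20 mm rod ROI mean is within the CLT bound of the nominal value", {
  img <- generate_section("high_contrast", noise_sigma = 20, seed = 7)
  rois <- locate_rois(img)
  rod <- rois[rois$role == "rod_20mm", ]
  px <- img$pixels[roi_mask(img, rod)]
  nominal <- img$geometry$rods$value[img$geometry$rods$role == "rod_20mm"]
  expect_lt(abs(mean(px) - nominal), 3 * 20 / sqrt(length(px)))
})

test_that("unknown kinds and invalid parameters are rejected by name", {
  expect_error(generate_section("banana"), "banana")
  expect_error(generate_section("uniformity", spacing_mm = 0), "spacing_mm")
  expect_error(generate_section("uniformity", size = 64), "128")
  expect_error(artifact_spec("vortex"), "vortex")
  expect_error(artifact_spec("rings", magnitude = -1), "non-negative")
})

test_that("zero-magnitude injection is the identity on pixels but still labels", {
  img <- generate_section("low_contrast", noise_sigma = 10, seed = 5)
  for (kind in c("rings", "scatter", "beam_hardening", "crescent")) {
    out <- inject_artifact(img, artifact_spec(kind, magnitude = 0))
    expect_identical(out$pixels, img$pixels)
    expect_identical(out$labels, kind)
  }
})

test_that("ring injection shifts each annulus mean by exactly its signed amplitude", {
  img <- generate_section("uniformity", noise_sigma = 0)
  spec <- artifact_spec("rings", magnitude = 25)
  out <- inject_artifact(img, spec)
  g <- phantomiq:::pixel_grid(256, 0.5)
  r <- sqrt(g$x^2 + g$y^2)
  ann_any <- matrix(FALSE, 256, 256)
  for (i in seq_along(spec$radii_mm)) {
    ann <- abs(r - spec$radii_mm[i]) <= spec$width_mm / 2
    ann_any <- ann_any | ann
    expected <- (if (i %% 2 == 1) 1 else -1) * 25
    expect_equal(mean(out$pixels[ann] - img$pixels[ann]), expected)
  }
  # locality: nothing outside the annuli moved
  expect_identical(out$pixels[!ann_any], img$pixels[!ann_any])
})

test_that("crescent injection is local and statistically near-invisible", {
  img <- generate_section("uniformity", noise_sigma = 0)
  spec <- artifact_spec("crescent")
  out <- inject_artifact(img, spec)
  lune <- phantomiq:::crescent_mask(256, 0.5, spec)
  # support = lune dilated by the truncated smoothing kernel
  support <- phantomiq:::erode_mask(!lune, ceiling(3 * spec$feather_mm / 0.5)) == FALSE
  expect_identical(out$pixels[!support], img$pixels[!support])
  expect_gt(max(out$pixels - img$pixels), 0)
  expect_lte(max(out$pixels - img$pixels), spec$magnitude)

  # whole-section first-order statistics stay within the noise of regular
  reg <- generate_section("high_contrast", noise_sigma = 15, seed = 11)
  cre <- inject_artifact(reg, spec)
  mask <- phantomiq:::section_texture_mask(reg)
  shift <- mean(cre$pixels[mask]) - mean(reg$pixels[mask])
  expect_lt(abs(shift), 15 / sqrt(sum(mask)) * 3)
})

test_that("scatter cupping amplitude strictly increases the uniformity metric", {
  img <- generate_section("uniformity", noise_sigma = 0)
  u <- vapply(c(0, 20, 40, 60), function(a) {
    out <- if (a == 0) img else inject_artifact(img, artifact_spec("scatter", magnitude = a))
    compute_uniformity_noise(out)$uniformity
  }, numeric(1))
  expect_true(all(diff(u) > 0))
})

test_that("beam hardening depresses the disk centre and streaks dense rods only", {
  hc <- generate_section("high_contrast", noise_sigma = 0)
  out <- inject_artifact(hc, artifact_spec("beam_hardening"))
  ctr <- phantomiq:::disc_mask(256, 0.5, c(0, 0), 5)
  expect_lt(mean(out$pixels[ctr]), mean(hc$pixels[ctr]))
  # uniformity section has no inserts but still shows the cupping signature
  un <- generate_section("uniformity", noise_sigma = 0)
  out_u <- inject_artifact(un, artifact_spec("beam_hardening"))
  expect_lt(mean(out_u$pixels[ctr]), mean(un$pixels[ctr]))
  # low-contrast rods are not dense: no streak pixels beyond the cupping
  lc <- generate_section("low_contrast", noise_sigma = 0)
  out_l <- inject_artifact(lc, artifact_spec("beam_hardening"))
  delta_l <- lc$pixels - out_l$pixels
  delta_h <- hc$pixels - out$pixels
  expect_lte(max(delta_l), 50)        # cupping only
  expect_gt(max(delta_h), 50)         # cupping + streaks
})

test_that("dataset generation counts, labels and determinism hold", {
  ds <- generate_dataset(n_per_class = 5, classes = list("regular", "rings"),
                         noise_sigma = 10, master_seed = 2)
  expect_equal(nrow(ds), 40)
  expect_equal(sum(vapply(ds$labels, function(l) "rings" %in% l, logical(1))), 20)
  ds2 <- generate_dataset(n_per_class = 5, classes = list("regular", "rings"),
                          noise_sigma = 10, master_seed = 2)
  expect_identical(
    lapply(ds$image, `[[`, "pixels"),
    lapply(ds2$image, `[[`, "pixels")
  )
  expect_error(
    generate_dataset(n_per_class = 2, classes = list("rings", c("rings"))),
    "Duplicate"
  )
  expect_error(generate_dataset(n_per_class = 1), "at least 2")
})

test_that("multi-artifact classes carry every applied label", {
  ds <- generate_dataset(
    n_per_class = 2, classes = list(c("rings", "beam_hardening")),
    section_kinds = "uniformity", noise_sigma = 5, master_seed = 1
  )
  for (l in ds$labels) expect_setequal(l, c("rings", "beam_hardening"))
  for (img in ds$image) expect_setequal(img$labels, c("rings", "beam_hardening"))
})

test_that("Winston-Lutz generator records exact truth and validates offsets", {
  wl <- generate_wl_image(bb_offset_mm = c(1, 0), spacing_mm = 0.25)
  expect_equal(wl$truth$offset_px, 4)
  expect_equal(unname(wl$truth$bb_center_px - wl$truth$field_center_px), c(0, 4))
  z <- generate_wl_image(bb_offset_mm = c(0, 0))
  expect_identical(z$truth$field_center_px, z$truth$bb_center_px)
  a <- generate_wl_image(noise_sigma = 4, seed = 9)
  b <- generate_wl_image(noise_sigma = 4, seed = 9)
  expect_identical(a$pixels, b$pixels)
  expect_error(generate_wl_image(bb_offset_mm = c(12, 0)), "outside")
})
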