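# Classical image-quality metrics: ROI layout, CNR, MTF, uniformity/noise.

test_that("ROI layout follows geometry and rescales with spacing", {
  img <- generate_section("high_contrast", noise_sigma = 0)
  rois <- locate_rois(img)
  expect_setequal(rois$role, c("rod_20mm", "rod_9mm", "rod_3mm", "background"))
  rods <- img$geometry$rods
  for (i in seq_len(nrow(rods))) {
    r <- rois[rois$role == rods$role[i], ]
    expect_equal(c(r$x_mm, r$y_mm), c(rods$x_mm[i], rods$y_mm[i]))
  }
  # halving the spacing doubles ROI pixel radii (mm layout unchanged)
  img2 <- generate_section("high_contrast", noise_sigma = 0, spacing_mm = 0.25,
                           size = 512)
  roi <- locate_rois(img)[1, ]
  roi2 <- locate_rois(img2)[1, ]
  expect_equal(sum(roi_mask(img2, roi2)) / sum(roi_mask(img, roi)), 4,
               tolerance = 0.05)
  # uniformity layout: centre + 4 peripherals
  un <- generate_section("uniformity", noise_sigma = 0)
  expect_setequal(locate_rois(un)$role,
                  c("center", "peripheral_N", "peripheral_E",
                    "peripheral_S", "peripheral_W"))
  img$geometry <- NULL
  expect_error(locate_rois(img), "geometry")
})

test_that("CNR matches its closed form and invariances", {
  expect_equal(cnr_value(1100, 1000, 20), 5.0)
  expect_equal(cnr_value(1000, 1000, 20), 0)
  expect_error(cnr_value(1100, 1000, 0), class = "phantomiq_degenerate_background")

  img <- generate_section("high_contrast", noise_sigma = 15, seed = 2)
  rois <- locate_rois(img)
  rod <- rois[rois$role == "rod_9mm", ]; bg <- rois[rois$role == "background", ]
  base <- compute_cnr(img, rod, bg)
  # additive offset and positive gain leave CNR unchanged
  off <- img; off$pixels <- img$pixels + 137
  gain <- img; gain$pixels <- img$pixels * 2.5
  expect_equal(compute_cnr(off, rod, bg), base)
  expect_equal(compute_cnr(gain, rod, bg), base)
})

test_that("compute_cnr equals a two-pass mean/sd oracle on random ROIs", {
  img <- generate_section("low_contrast", noise_sigma = 12, seed = 31)
  rois <- locate_rois(img)
  bg <- rois[rois$role == "background", ]
  for (role in c("rod_3mm", "rod_9mm", "rod_20mm")) {
    rod <- rois[rois$role == role, ]
    rv <- img$pixels[roi_mask(img, rod)]
    bv <- img$pixels[roi_mask(img, bg)]
    mr <- sum(rv) / length(rv)
    mb <- sum(bv) / length(bv)
    sb <- sqrt(sum((bv - mb)^2) / (length(bv) - 1))
    expect_equal(compute_cnr(img, rod, bg), abs(mr - mb) / sb, tolerance = 1e-12)
  }
})

test_that("unblurred bar template yields MTF 1 at every frequency", {
  sr <- generate_section("spatial_resolution", noise_sigma = 0)
  m <- compute_mtf(sr)
  expect_equal(m$curve$mtf, rep(1, 6))
  expect_true(is.na(m$mtf50))   # never crosses: undefined, not fabricated
  expect_true(is.na(m$mtf10))
})

test_that("MTF50 interpolates linearly between bracketing frequencies", {
  curve <- data.frame(freq_lpcm = c(2, 4), mtf = c(0.8, 0.4))
  expect_equal(mtf_crossing(curve, 0.5), 3.5)
  expect_true(is.na(mtf_crossing(data.frame(freq_lpcm = 2, mtf = 0.8), 0.5)))
  expect_true(is.na(mtf_crossing(curve, 0.9)))  # no extrapolation
})

test_that("Gaussian blur makes MTF non-increasing at every frequency", {
  sr <- generate_section("spatial_resolution", noise_sigma = 0)
  curves <- lapply(c(0.5, 1, 2), function(s) {
    b <- sr; b$pixels <- phantomiq:::gaussian_smooth(sr$pixels, s)
    compute_mtf(b)$curve$mtf
  })
  expect_true(all(curves[[2]] <= curves[[1]] + 1e-12))
  expect_true(all(curves[[3]] <= curves[[2]] + 1e-12))
  # a realistically blurred pattern crosses 50%: MTF50 defined and inside range
  b <- sr; b$pixels <- phantomiq:::gaussian_smooth(sr$pixels, 2)
  m <- compute_mtf(b)
  expect_true(is.finite(m$mtf50) && m$mtf50 > 2 && m$mtf50 < 8)
  expect_gte(m$mtf10, m$mtf50)
})

test_that("uniformity and noise have exact closed forms", {
  flat <- generate_section("uniformity", noise_sigma = 0)
  u <- compute_uniformity_noise(flat)
  expect_equal(u$uniformity, 0)
  expect_equal(u$noise, 0)

  # scatter dome of amplitude 60: uniformity equals the dome's
  # centre-vs-peripheral mean difference evaluated over the actual ROI masks
  domed <- inject_artifact(flat, artifact_spec("scatter", magnitude = 60))
  rois <- locate_rois(flat)
  g <- phantomiq:::pixel_grid(256, 0.5)
  dome <- 60 * (1 - (g$x^2 + g$y^2) / 55^2)
  ctr <- roi_mask(flat, rois[rois$role == "center", ])
  expected <- max(vapply(c("peripheral_N", "peripheral_E", "peripheral_S",
                           "peripheral_W"), function(role) {
    per <- roi_mask(flat, rois[rois$role == role, ])
    abs(mean(dome[per]) - mean(dome[ctr]))
  }, numeric(1)))
  expect_equal(compute_uniformity_noise(domed)$uniformity, expected,
               tolerance = 1e-12)

  # sample sd of the centre ROI estimates the generator sigma
  noisy <- generate_section("uniformity", noise_sigma = 20, seed = 4)
  n <- sum(ctr)
  expect_lt(abs(compute_uniformity_noise(noisy)$noise - 20),
            3 * 20 / sqrt(2 * (n - 1)))
})

test_that("compute_iq_metrics dispatches per section with stable names", {
  expect_setequal(compute_iq_metrics(generate_section("low_contrast", seed = 1))$metric,
                  c("CNR 3 mm", "CNR 9 mm", "CNR 20 mm"))
  expect_setequal(compute_iq_metrics(generate_section("uniformity", seed = 1))$metric,
                  c("uniformity", "noise"))
  expect_setequal(compute_iq_metrics(generate_section("spatial_resolution", seed = 1))$metric,
                  c("MTF50", "MTF10"))
})
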