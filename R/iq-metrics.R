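#' Automatic ROI layout from phantom geometry
#'
#' Derives the regions of interest for a section deterministically from its
#' geometry descriptor and pixel spacing: one ROI per contrast rod (shrunk by
#' a margin factor to avoid edge pixels) plus a background ROI; the six
#' line-pair group ROIs plus a uniform noise patch for the resolution section;
#' one centre and four peripheral ROIs for the uniformity section. An optional
#' global translation accommodates misaligned phantoms.
#'
#' @param img A [section_image][new_section_image] with geometry populated.
#' @param shift_mm Length-2 global translation (x, y) applied to every ROI.
#' @param rod_margin Shrink factor (< 1) applied to rod ROI diameters.
#'
#' @return A tibble with columns `role`, `shape` (`"disc"` or `"rect"`),
#'   `x_mm`, `y_mm`, `diameter_mm`, `width_mm`, `height_mm`, `freq_lpcm`.
#' @export
locate_rois <- function(img, shift_mm = c(0, 0), rod_margin = 0.7) {
  if (is.null(img$geometry)) rlang::abort("Image geometry is missing.")
  g <- img$geometry
  roi <- function(role, shape, x, y, diameter = NA_real_,
                  width = NA_real_, height = NA_real_, freq = NA_real_) {
    tibble::tibble(role = role, shape = shape,
                   x_mm = x + shift_mm[1], y_mm = y + shift_mm[2],
                   diameter_mm = diameter, width_mm = width, height_mm = height,
                   freq_lpcm = freq)
  }
  out <- switch(img$section_kind,
    high_contrast = ,
    low_contrast = dplyr::bind_rows(
      purrr::pmap(g$rods, function(role, diameter_mm, x_mm, y_mm, value) {
        roi(role, "disc", x_mm, y_mm, diameter = diameter_mm * rod_margin)
      }),
      roi("background", "disc", g$background_roi$x_mm, g$background_roi$y_mm,
          diameter = g$background_roi$diameter_mm)
    ),
    spatial_resolution = dplyr::bind_rows(
      purrr::pmap(g$bars, function(freq_lpcm, x_mm, y_mm, width_mm, height_mm) {
        roi(sprintf("lp_group(%g)", freq_lpcm), "rect", x_mm, y_mm,
            width = width_mm, height = height_mm, freq = freq_lpcm)
      }),
      roi("background", "rect", g$noise_patch$x_mm, g$noise_patch$y_mm,
          width = g$noise_patch$width_mm, height = g$noise_patch$height_mm)
    ),
    uniformity = {
      u <- g$uniformity_layout
      dplyr::bind_rows(
        roi("center", "disc", 0, 0, diameter = u$center_diameter_mm),
        roi("peripheral_N", "disc", 0, -u$peripheral_radius_mm,
            diameter = u$peripheral_diameter_mm),
        roi("peripheral_E", "disc", u$peripheral_radius_mm, 0,
            diameter = u$peripheral_diameter_mm),
        roi("peripheral_S", "disc", 0, u$peripheral_radius_mm,
            diameter = u$peripheral_diameter_mm),
        roi("peripheral_W", "disc", -u$peripheral_radius_mm, 0,
            diameter = u$peripheral_diameter_mm)
      )
    }
  )
  out
}

#' Pixel mask for one ROI row
#'
#' @param img A [section_image][new_section_image].
#' @param roi One row of the tibble returned by [locate_rois()].
#' @return Logical matrix the size of the image.
#' @export
roi_mask <- function(img, roi) {
  size <- nrow(img$pixels)
  m <- if (roi$shape == "disc") {
    disc_mask(size, img$spacing_mm, c(roi$x_mm, roi$y_mm), roi$diameter_mm / 2)
  } else {
    rect_mask(size, img$spacing_mm, c(roi$x_mm, roi$y_mm), roi$width_mm, roi$height_mm)
  }
  if (!any(m)) rlang::abort(sprintf("ROI '%s' lies outside the image.", roi$role))
  m
}

#' Contrast-to-noise ratio
#'
#' `cnr_value()` is the bare formula `|mean(rod) - mean(bg)| / sd(bg)`;
#' `compute_cnr()` evaluates it over a rod and a background ROI of an image.
#' CNR is invariant to a global additive offset and to a positive global gain.
#'
#' @param mean_rod,mean_bg ROI mean intensities.
#' @param sd_bg Background ROI standard deviation (> 0).
#' @return Dimensionless CNR.
#' @examples
#' cnr_value(1100, 1000, 20)  # 5
#' @export
cnr_value <- function(mean_rod, mean_bg, sd_bg) {
  if (sd_bg == 0) {
    rlang::abort("Degenerate background: sd(bg) is zero.",
                 class = "phantomiq_degenerate_background")
  }
  abs(mean_rod - mean_bg) / sd_bg
}

#' @rdname cnr_value
#' @param img A [section_image][new_section_image].
#' @param rod_roi,bg_roi Single rows of a [locate_rois()] tibble.
#' @export
compute_cnr <- function(img, rod_roi, bg_roi) {
  rod <- img$pixels[roi_mask(img, rod_roi)]
  bg <- img$pixels[roi_mask(img, bg_roi)]
  if (length(rod) < 9 || length(bg) < 9) {
    rlang::abort("Rod and background ROIs must contain at least 9 pixels each.")
  }
  cnr_value(mean(rod), mean(bg), stats::sd(bg))
}

#' Modulation transfer function by the standard-deviation method
#'
#' For each bar group of frequency f the noise-corrected modulation is
#' `M'(f) = sqrt(max(sd_group^2 - sd_noise^2, 0))` and
#' `MTF(f) = clip((pi * sqrt(2) / 4) * M'(f) / M0, 0, 1)` where `M0` is half
#' the bar/space peak-to-peak template amplitude. `sd_noise` is estimated from
#' the uniform noise patch of the same section. MTF50/MTF10 come from
#' [mtf_crossing()]; they are `NA` (undefined, never fabricated) when the
#' curve does not cross the level.
#'
#' @param img A spatial-resolution [section_image][new_section_image].
#' @param shift_mm Optional global ROI translation, as in [locate_rois()].
#'
#' @return A list with `curve` (tibble `freq_lpcm`, `mtf`), `mtf50`, `mtf10`
#'   (lp/cm or `NA`).
#' @export
compute_mtf <- function(img, shift_mm = c(0, 0)) {
  if (img$section_kind != "spatial_resolution") {
    rlang::abort("MTF requires a spatial_resolution section image.")
  }
  rois <- locate_rois(img, shift_mm = shift_mm)
  groups <- rois[!is.na(rois$freq_lpcm), ]
  if (nrow(groups) < 3) rlang::abort("At least 3 bar groups are required.")
  sd_noise <- stats::sd(img$pixels[roi_mask(img, rois[rois$role == "background", ])])
  m0 <- img$geometry$bar_amplitude
  k <- pi * sqrt(2) / 4
  mtf <- vapply(seq_len(nrow(groups)), function(i) {
    sd_g <- stats::sd(img$pixels[roi_mask(img, groups[i, ])])
    mprime <- sqrt(max(sd_g^2 - sd_noise^2, 0))
    min(max(k * mprime / m0, 0), 1)
  }, numeric(1))
  curve <- tibble::tibble(freq_lpcm = groups$freq_lpcm, mtf = mtf)
  curve <- curve[order(curve$freq_lpcm), ]
  list(curve = curve,
       mtf50 = mtf_crossing(curve, 0.5),
       mtf10 = mtf_crossing(curve, 0.1))
}

#' Frequency at which an MTF curve crosses a level
#'
#' Linear interpolation in frequency between the bracketing measured groups;
#' no extrapolation beyond the measured range. Returns `NA` when the curve
#' never crosses the level or has fewer than 2 finite points.
#'
#' @param curve Tibble/data frame with columns `freq_lpcm` and `mtf`.
#' @param level Modulation level in (0, 1), e.g. 0.5 for MTF50.
#' @return Frequency in lp/cm, or `NA`.
#' @examples
#' mtf_crossing(data.frame(freq_lpcm = c(2, 4), mtf = c(0.8, 0.4)), 0.5)  # 3.5
#' @export
mtf_crossing <- function(curve, level) {
  ok <- is.finite(curve$mtf) & is.finite(curve$freq_lpcm)
  f <- curve$freq_lpcm[ok]; m <- curve$mtf[ok]
  o <- order(f); f <- f[o]; m <- m[o]
  if (length(f) < 2) return(NA_real_)
  for (i in seq_len(length(f) - 1)) {
    if ((m[i] - level) * (m[i + 1] - level) <= 0 && m[i] != m[i + 1]) {
      return(f[i] + (m[i] - level) / (m[i] - m[i + 1]) * (f[i + 1] - f[i]))
    }
  }
  NA_real_
}

#' Uniformity and noise of the uniformity section
#'
#' Noise is the standard deviation in the central ROI; uniformity is the
#' worst-case absolute difference between each peripheral ROI mean and the
#' central ROI mean (intensity units; 0 on a perfectly flat disk).
#'
#' @param img A uniformity [section_image][new_section_image].
#' @param shift_mm Optional global ROI translation.
#' @return Named list with `uniformity` and `noise`.
#' @export
compute_uniformity_noise <- function(img, shift_mm = c(0, 0)) {
  if (img$section_kind != "uniformity") {
    rlang::abort("Uniformity/noise require a uniformity section image.")
  }
  rois <- locate_rois(img, shift_mm = shift_mm)
  center <- img$pixels[roi_mask(img, rois[rois$role == "center", ])]
  periph <- rois[startsWith(rois$role, "peripheral"), ]
  devs <- vapply(seq_len(nrow(periph)), function(i) {
    abs(mean(img$pixels[roi_mask(img, periph[i, ])]) - mean(center))
  }, numeric(1))
  list(uniformity = max(devs), noise = stats::sd(center))
}

#' Classical image-quality metrics for one section image
#'
#' Dispatches on the section kind: CNR per rod for the contrast sections,
#' MTF50/MTF10 for the spatial-resolution section, uniformity and noise for
#' the uniformity section.
#'
#' @param img A [section_image][new_section_image].
#' @param shift_mm Optional global ROI translation.
#' @return A long tibble with columns `section_kind`, `metric`, `value`.
#' @examples
#' compute_iq_metrics(generate_section("uniformity", noise_sigma = 0))
#' @export
compute_iq_metrics <- function(img, shift_mm = c(0, 0)) {
  rows <- switch(img$section_kind,
    high_contrast = ,
    low_contrast = {
      rois <- locate_rois(img, shift_mm = shift_mm)
      bg <- rois[rois$role == "background", ]
      rods <- rois[startsWith(rois$role, "rod_"), ]
      tibble::tibble(
        metric = sub("rod_(\\d+)mm", "CNR \\1 mm", rods$role),
        value = vapply(seq_len(nrow(rods)), function(i) {
          compute_cnr(img, rods[i, ], bg)
        }, numeric(1))
      )
    },
    spatial_resolution = {
      m <- compute_mtf(img, shift_mm = shift_mm)
      tibble::tibble(metric = c("MTF50", "MTF10"), value = c(m$mtf50, m$mtf10))
    },
    uniformity = {
      u <- compute_uniformity_noise(img, shift_mm = shift_mm)
      tibble::tibble(metric = c("uniformity", "noise"),
                     value = c(u$uniformity, u$noise))
    }
  )
  tibble::tibble(section_kind = img$section_kind, rows)
}

#' Classical metrics for every image of a dataset
#'
#' @param dataset A dataset tibble from [generate_dataset()].
#' @return A long tibble `id`, `section_kind`, `metric`, `value`.
#' @export
iq_metrics <- function(dataset) {
  purrr::map2_dfr(dataset$id, dataset$image, function(id, img) {
    tibble::tibble(id = id, compute_iq_metrics(img))
  })
}
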