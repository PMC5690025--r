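#' Phantom section image
#'
#' A `section_image` bundles a square pixel raster (CT-number-like arbitrary
#' units) with its pixel spacing, section kind, a geometry descriptor (insert
#' positions, sizes and nominal values in mm) and the set of artifact labels
#' present. Images are generated by [generate_section()] and perturbed by
#' [inject_artifact()].
#'
#' @param pixels Numeric matrix (square, at least 128 x 128).
#' @param spacing_mm Isotropic pixel size in mm (> 0).
#' @param section_kind One of `"high_contrast"`, `"low_contrast"`,
#'   `"spatial_resolution"`, `"uniformity"`.
#' @param geometry Geometry descriptor list (see [generate_section()]).
#' @param labels Character vector of artifact kinds present (empty = regular).
#' @param seed Integer seed the noise realization was drawn with.
#'
#' @return An object of class `section_image`.
#' @export
new_section_image <- function(pixels, spacing_mm, section_kind, geometry,
                              labels = character(), seed = NA_integer_) {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (nrow(pixels) < 128) {
    rlang::abort("`pixels` must be at least 128 x 128.")
  }
  if (!is.numeric(spacing_mm) || spacing_mm <= 0) {
    rlang::abort("`spacing_mm` must be a positive number.")
  }
  section_kind <- match_section_kind(section_kind)
  bad <- setdiff(labels, artifact_kinds())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown artifact label(s): ", paste(bad, collapse = ", ")))
  }
  structure(
    list(
      pixels = pixels, spacing_mm = spacing_mm, section_kind = section_kind,
      geometry = geometry, labels = sort(unique(labels)), seed = seed
    ),
    class = "section_image"
  )
}

section_kinds <- function() {
  c("high_contrast", "low_contrast", "spatial_resolution", "uniformity")
}

artifact_kinds <- function() {
  c("rings", "scatter", "beam_hardening", "crescent")
}

match_section_kind <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 || !kind %in% section_kinds()) {
    rlang::abort(paste0(
      "Unknown section kind ", deparse(kind), "; must be one of ",
      paste(section_kinds(), collapse = ", "), "."
    ))
  }
  kind
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf(
    "<section_image> %s, %d x %d px @ %.3g mm/px, labels: %s\n",
    x$section_kind, nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
    if (length(x$labels) == 0) "regular" else paste(x$labels, collapse = "+")
  ))
  invisible(x)
}

# Default phantom geometry: a 110 mm-diameter water-equivalent disk (background
# 1000) centred in the image. Contrast sections carry three rods (3, 9, 20 mm
# diameter) on a 30 mm pitch circle; the spatial-resolution section carries six
# 10 x 10 mm bar groups at 2, 3, 4, 5, 6, 8 lp/cm (one group = f line pairs
# across 10 mm); the uniformity section is the bare disk.
default_geometry <- function(section_kind) {
  g <- list(
    disk_radius_mm = 55,
    background = 1000,
    background_roi = list(x_mm = 0, y_mm = 0, diameter_mm = 20),
    uniformity_layout = list(
      center_diameter_mm = 15, peripheral_radius_mm = 38, peripheral_diameter_mm = 15
    )
  )
  if (section_kind %in% c("high_contrast", "low_contrast")) {
    delta <- if (section_kind == "high_contrast") 200 else 20
    ang <- c(90, 210, 330) * pi / 180
    g$rods <- tibble::tibble(
      role = c("rod_20mm", "rod_9mm", "rod_3mm"),
      diameter_mm = c(20, 9, 3),
      x_mm = 30 * cos(ang),
      y_mm = 30 * sin(ang),
      value = g$background + delta
    )
  }
  if (section_kind == "spatial_resolution") {
    g$bars <- tibble::tibble(
      freq_lpcm = c(2, 3, 4, 5, 6, 8),
      x_mm = rep(c(-18, 0, 18), 2),
      y_mm = rep(c(-14, 14), each = 3),
      width_mm = 10, height_mm = 10
    )
    g$bar_amplitude <- 100
    g$noise_patch = list(x_mm = 0, y_mm = 0, width_mm = 8, height_mm = 8)
  }
  g
}

# Noiseless template raster for a section kind.
section_template <- function(section_kind, spacing_mm, size, geometry) {
  px <- matrix(0, size, size)
  disk <- disc_mask(size, spacing_mm, c(0, 0), geometry$disk_radius_mm)
  px[disk] <- geometry$background
  grid <- pixel_grid(size, spacing_mm)
  if (!is.null(geometry$rods)) {
    for (i in seq_len(nrow(geometry$rods))) {
      r <- geometry$rods[i, ]
      m <- disc_mask(size, spacing_mm, c(r$x_mm, r$y_mm), r$diameter_mm / 2)
      px[m] <- r$value
    }
  }
  if (!is.null(geometry$bars)) {
    a <- geometry$bar_amplitude
    for (i in seq_len(nrow(geometry$bars))) {
      b <- geometry$bars[i, ]
      m <- rect_mask(size, spacing_mm, c(b$x_mm, b$y_mm), b$width_mm, b$height_mm)
      half_period <- 5 / b$freq_lpcm            # mm; full period = 10/f mm
      x0 <- b$x_mm - b$width_mm / 2
      bar <- (floor((grid$x - x0) / half_period) %% 2) == 0
      px[m & bar] <- geometry$background + a
      px[m & !bar] <- geometry$background - a
    }
  }
  px
}

#' Generate a synthetic phantom-section image
#'
#' Renders the noiseless geometric template for one of the four phantom
#' sections (background disk plus section-specific inserts) and adds
#' zero-mean Gaussian noise of the stated sigma. Identical
#' `(parameters, seed)` reproduce bit-identical pixels; the generator never
#' touches the global RNG state.
#'
#' @param section_kind `"high_contrast"`, `"low_contrast"`,
#'   `"spatial_resolution"` or `"uniformity"`.
#' @param noise_sigma Standard deviation of additive Gaussian noise, in
#'   intensity units (default 15).
#' @param spacing_mm Pixel size in mm (default 0.5).
#' @param size Image side in pixels (default 256, minimum 128).
#' @param seed Integer seed for the noise realization.
#'
#' @return A [section_image][new_section_image] with empty labels and the
#'   geometry descriptor filled in.
#' @examples
#' img <- generate_section("high_contrast", noise_sigma = 15, seed = 7)
#' img
#' @export
generate_section <- function(section_kind, noise_sigma = 15, spacing_mm = 0.5,
                             size = 256, seed = 0) {
  section_kind <- match_section_kind(section_kind)
  if (size < 128) rlang::abort("`size` must be at least 128 pixels.")
  if (!is.numeric(spacing_mm) || spacing_mm <= 0) {
    rlang::abort("`spacing_mm` must be a positive number.")
  }
  if (noise_sigma < 0) rlang::abort("`noise_sigma` must be non-negative.")
  geometry <- default_geometry(section_kind)
  px <- section_template(section_kind, spacing_mm, size, geometry)
  if (noise_sigma > 0) {
    noise <- withr::with_seed(
      as.integer(seed),
      matrix(stats::rnorm(size * size, sd = noise_sigma), size, size)
    )
    px <- px + noise
  }
  new_section_image(px, spacing_mm, section_kind, geometry,
                    labels = character(), seed = as.integer(seed))
}
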