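#' Parametric artifact specification
#'
#' Describes one image-domain artifact perturbation. The four kinds emulate the
#' classic cone-beam CT artifact families:
#'
#' * `rings` — additive alternating-sign annular offsets (detector gain
#'   errors) at configured radii;
#' * `scatter` — additive smooth radial dome (cupping of positive sign) over
#'   the phantom disk plus a multiplicative contrast reduction;
#' * `beam_hardening` — additive cupping depression (negative radial
#'   parabola) over the phantom disk, plus dark streaks on the segments
#'   joining high-density rods where such rods exist;
#' * `crescent` — additive offset on a thin crescent (lune) near the image
#'   centre, emulating residual bowtie-filter motion.
#'
#' A magnitude of 0 makes the injector the identity map on pixels.
#'
#' @param kind One of `"rings"`, `"scatter"`, `"beam_hardening"`, `"crescent"`.
#' @param magnitude Amplitude in intensity units (>= 0). Defaults per kind:
#'   rings 30, scatter 60, beam hardening 50, crescent 10.
#' @param ... Kind-specific shape parameters overriding the defaults:
#'   `radii_mm`, `width_mm` (rings); `contrast_loss` (scatter);
#'   `streak_magnitude`, `streak_width_mm`, `dense_threshold` (beam
#'   hardening); `radius_mm`, `offset_mm`, `feather_mm` (crescent).
#'
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind, magnitude = NULL, ...) {
  if (!is.character(kind) || length(kind) != 1 || !kind %in% artifact_kinds()) {
    rlang::abort(paste0(
      "Unknown artifact kind ", deparse(kind), "; must be one of ",
      paste(artifact_kinds(), collapse = ", "), "."
    ))
  }
  defaults <- switch(kind,
    rings = list(magnitude = 30, radii_mm = c(10, 18, 26, 34), width_mm = 1.5),
    scatter = list(magnitude = 60, contrast_loss = 0.1),
    beam_hardening = list(magnitude = 50, streak_magnitude = 40,
                          streak_width_mm = 1.5, dense_threshold = 100),
    crescent = list(magnitude = 10, radius_mm = 18, offset_mm = c(0.5, 0),
                    feather_mm = 2)
  )
  spec <- utils::modifyList(defaults, list(...))
  if (!is.null(magnitude)) spec$magnitude <- magnitude
  if (!is.numeric(spec$magnitude) || spec$magnitude < 0) {
    rlang::abort("`magnitude` must be non-negative.")
  }
  spec$kind <- kind
  structure(spec, class = "artifact_spec")
}

#' Inject an artifact into a phantom-section image
#'
#' Applies the closed-form perturbation described by `spec` and adds
#' `spec$kind` to the image's label set. All injectors are deterministic;
#' randomness lives only in [generate_section()].
#'
#' @param img A [section_image][new_section_image].
#' @param spec An [artifact_spec()].
#'
#' @return A new `section_image` with perturbed pixels and updated labels.
#' @examples
#' img <- generate_section("uniformity", noise_sigma = 0)
#' out <- inject_artifact(img, artifact_spec("scatter"))
#' out$labels
#' @export
inject_artifact <- function(img, spec) {
  if (!inherits(img, "section_image")) rlang::abort("`img` must be a section_image.")
  if (!inherits(spec, "artifact_spec")) rlang::abort("`spec` must be an artifact_spec.")
  px <- img$pixels
  if (spec$magnitude > 0) {
    px <- switch(spec$kind,
      rings = apply_rings(px, img, spec),
      scatter = apply_scatter(px, img, spec),
      beam_hardening = apply_beam_hardening(px, img, spec),
      crescent = apply_crescent(px, img, spec)
    )
  }
  new_section_image(px, img$spacing_mm, img$section_kind, img$geometry,
                    labels = union(img$labels, spec$kind), seed = img$seed)
}

apply_rings <- function(px, img, spec) {
  size <- nrow(px)
  g <- pixel_grid(size, img$spacing_mm)
  r <- sqrt(g$x^2 + g$y^2)
  for (i in seq_along(spec$radii_mm)) {
    ann <- abs(r - spec$radii_mm[i]) <= spec$width_mm / 2
    px[ann] <- px[ann] + (if (i %% 2 == 1) 1 else -1) * spec$magnitude
  }
  px
}

apply_scatter <- function(px, img, spec) {
  size <- nrow(px)
  R <- img$geometry$disk_radius_mm
  bg <- img$geometry$background
  g <- pixel_grid(size, img$spacing_mm)
  r2 <- (g$x^2 + g$y^2) / R^2
  disk <- r2 <= 1
  px[disk] <- bg + (px[disk] - bg) * (1 - spec$contrast_loss)
  px[disk] <- px[disk] + spec$magnitude * (1 - r2[disk])
  px
}

apply_beam_hardening <- function(px, img, spec) {
  size <- nrow(px)
  R <- img$geometry$disk_radius_mm
  g <- pixel_grid(size, img$spacing_mm)
  r2 <- (g$x^2 + g$y^2) / R^2
  disk <- r2 <= 1
  px[disk] <- px[disk] - spec$magnitude * (1 - r2[disk])
  rods <- img$geometry$rods
  if (!is.null(rods)) {
    dense <- rods[rods$value - img$geometry$background >= spec$dense_threshold, ]
    if (nrow(dense) >= 2) {
      pairs <- utils::combn(nrow(dense), 2)
      for (p in seq_len(ncol(pairs))) {
        a <- dense[pairs[1, p], ]; b <- dense[pairs[2, p], ]
        d <- dist_to_segment(g$x, g$y, c(a$x_mm, a$y_mm), c(b$x_mm, b$y_mm))
        in_rod <- (g$x - a$x_mm)^2 + (g$y - a$y_mm)^2 <= (a$diameter_mm / 2)^2 |
          (g$x - b$x_mm)^2 + (g$y - b$y_mm)^2 <= (b$diameter_mm / 2)^2
        streak <- d <= spec$streak_width_mm / 2 & !in_rod & disk
        px[streak] <- px[streak] - spec$streak_magnitude
      }
    }
  }
  px
}

crescent_mask <- function(size, spacing_mm, spec) {
  a <- disc_mask(size, spacing_mm, c(0, 0), spec$radius_mm)
  b <- disc_mask(size, spacing_mm, spec$offset_mm, spec$radius_mm)
  a & !b
}

# The crescent is a thin lune of the nominal amplitude convolved with a
# Gaussian point-spread (feather), emulating the smooth low-amplitude shading
# left by bowtie-filter motion; for a thin lune the realized peak is below
# the nominal amplitude. The smoothing kernel is truncated at 3 sigma, so
# pixels beyond the feathered support are untouched.
apply_crescent <- function(px, img, spec) {
  m <- crescent_mask(nrow(px), img$spacing_mm, spec)
  bump <- spec$magnitude * gaussian_smooth(m * 1, spec$feather_mm / img$spacing_mm)
  px + bump
}
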