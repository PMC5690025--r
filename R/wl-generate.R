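#' Generate a synthetic Winston-Lutz EPID image
#'
#' Renders the portal image of a Winston-Lutz acquisition: a bright disk (the
#' radiation field collimated by a circular cone) containing a darker disk
#' (the ball bearing, BB), the BB displaced from the field centre by
#' `bb_offset_mm`. Default intensity levels place the field in the 2500-2700
#' band and the BB in the 1700-2200 band, matching the analyzer's default
#' threshold bands. The ground-truth centres are returned alongside the
#' pixels.
#'
#' @param bb_offset_mm Length-2 numeric, BB displacement (x, y) in mm.
#' @param cone_diam_mm,bb_diam_mm Field and BB diameters in mm (BB smaller).
#' @param spacing_mm Pixel size in mm.
#' @param size Image side in pixels.
#' @param field_level,bb_level,bg_level Intensity levels for field, BB and
#'   background.
#' @param noise_sigma Additive Gaussian noise sigma (0 = noiseless render).
#' @param seed Integer seed for the noise realization.
#' @param field_center_mm Field centre relative to the image centre, in mm
#'   (sub-pixel positions allowed).
#' @param gantry,couch,collimator Acquisition angles in degrees (metadata).
#' @param id Acquisition identifier (metadata).
#'
#' @return An object of class `wl_image`: a list with `pixels`, `spacing_mm`,
#'   the angles, and a `truth` record holding the exact field and BB centres
#'   in pixel (row, col) and mm coordinates.
#' @examples
#' wl <- generate_wl_image(bb_offset_mm = c(1, 0), spacing_mm = 0.25)
#' wl$truth$offset_px
#' @export
generate_wl_image <- function(bb_offset_mm = c(0, 0), cone_diam_mm = 30,
                              bb_diam_mm = 10, spacing_mm = 0.25, size = 256,
                              field_level = 2600, bb_level = 1950,
                              bg_level = 800, noise_sigma = 0, seed = 0,
                              field_center_mm = c(0, 0),
                              gantry = 0, couch = 0, collimator = 0,
                              id = "wl") {
  if (bb_diam_mm >= cone_diam_mm) {
    rlang::abort("`bb_diam_mm` must be smaller than `cone_diam_mm`.")
  }
  if (sqrt(sum(bb_offset_mm^2)) + bb_diam_mm / 2 >= cone_diam_mm / 2) {
    rlang::abort("BB offset pushes the BB outside the radiation field.")
  }
  bb_center_mm <- field_center_mm + bb_offset_mm
  field <- disc_mask(size, spacing_mm, field_center_mm, cone_diam_mm / 2)
  bb <- disc_mask(size, spacing_mm, bb_center_mm, bb_diam_mm / 2)
  px <- matrix(bg_level, size, size)
  px[field] <- field_level
  px[bb] <- bb_level
  if (noise_sigma > 0) {
    px <- px + withr::with_seed(
      as.integer(seed),
      matrix(stats::rnorm(size * size, sd = noise_sigma), size, size)
    )
  }
  c0 <- (size + 1) / 2
  to_px <- function(p) c(row = c0 + p[2] / spacing_mm, col = c0 + p[1] / spacing_mm)
  structure(
    list(
      pixels = px, spacing_mm = spacing_mm,
      gantry = gantry %% 360, couch = couch %% 360, collimator = collimator %% 360,
      id = id,
      truth = list(
        field_center_mm = field_center_mm, bb_center_mm = bb_center_mm,
        field_center_px = to_px(field_center_mm), bb_center_px = to_px(bb_center_mm),
        offset_mm = sqrt(sum(bb_offset_mm^2)),
        offset_px = sqrt(sum((bb_offset_mm / spacing_mm)^2))
      ),
      seed = as.integer(seed)
    ),
    class = "wl_image"
  )
}

#' @export
print.wl_image <- function(x, ...) {
  cat(sprintf(
    "<wl_image> %s: %d x %d px @ %.3g mm/px, gantry %g, couch %g, true offset %.3f mm\n",
    x$id, nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$gantry, x$couch,
    x$truth$offset_mm
  ))
  invisible(x)
}
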