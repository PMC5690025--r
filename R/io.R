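# Dataset serialization: 16-bit grayscale TIFFs plus a JSON manifest holding
# per-image labels, seeds, spacing and geometry. Stored pixels are rounded to
# integers in [0, 65535]; integer-valued images therefore round-trip exactly.

#' Write a phantom dataset to disk
#'
#' @param dataset Tibble from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- paste0(dataset$id, ".tiff")
  for (i in seq_len(nrow(dataset))) {
    px <- round(pmin(pmax(dataset$image[[i]]$pixels, 0), 65535))
    tiff::writeTIFF(px / 65535, file.path(dir, files[i]), bits.per.sample = 16)
  }
  manifest <- lapply(seq_len(nrow(dataset)), function(i) {
    img <- dataset$image[[i]]
    list(
      id = dataset$id[i], file = files[i],
      section_kind = img$section_kind, labels = I(img$labels),
      seed = img$seed, spacing_mm = img$spacing_mm,
      geometry = serialize_geometry(img$geometry)
    )
  })
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom dataset written by [write_dataset()]
#'
#' @param dir Directory containing the TIFFs and `manifest.json`.
#' @return A dataset tibble with the same columns as [generate_dataset()].
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  rows <- lapply(manifest, function(m) {
    px <- tiff::readTIFF(file.path(dir, m$file)) * 65535
    labels <- unlist(m$labels) %||% character(0)
    img <- new_section_image(
      round(px), m$spacing_mm, m$section_kind,
      deserialize_geometry(m$geometry), labels = labels, seed = m$seed
    )
    tibble::tibble(
      id = m$id, section_kind = m$section_kind,
      class = class_key(labels), labels = list(labels),
      seed = m$seed, image = list(img)
    )
  })
  dplyr::bind_rows(rows)
}

serialize_geometry <- function(g) {
  lapply(g, function(el) if (inherits(el, "data.frame")) unclass(as.list(el)) else el)
}

deserialize_geometry <- function(g) {
  tabular <- c("rods", "bars")
  for (nm in intersect(tabular, names(g))) {
    g[[nm]] <- tibble::as_tibble(lapply(g[[nm]], unlist))
  }
  for (nm in setdiff(names(g), tabular)) {
    if (is.list(g[[nm]])) g[[nm]] <- lapply(g[[nm]], function(x) unlist(x))
  }
  g
}

#' Read a QA configuration file
#'
#' Thin YAML loader for pipeline configuration (paths, tolerances, profiles,
#' seeds); returns the parsed list unchanged so callers can pass entries to
#' the corresponding functions.
#'
#' @param path Path to a YAML file.
#' @return Named list.
#' @export
read_qa_config <- function(path) {
  yaml::read_yaml(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a Winston-Lutz image series
#'
#' Images go to 16-bit TIFFs with a JSON sidecar (`wl_manifest.json`)
#' carrying spacing, angles and ids, so a series can be re-analyzed later or
#' produced by other tools.
#'
#' @param images List of [wl_image][generate_wl_image] objects.
#' @param dir Directory.
#' @return `write_wl_series()` returns `dir` invisibly; `read_wl_series()`
#'   returns a list of `wl_image` objects.
#' @export
write_wl_series <- function(images, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    file <- sprintf("%s_%02d.tiff", img$id, i)
    px <- round(pmin(pmax(img$pixels, 0), 65535))
    tiff::writeTIFF(px / 65535, file.path(dir, file), bits.per.sample = 16)
    list(id = img$id, file = file, spacing_mm = img$spacing_mm,
         gantry = img$gantry, couch = img$couch, collimator = img$collimator)
  })
  jsonlite::write_json(manifest, file.path(dir, "wl_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_wl_series
#' @export
read_wl_series <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "wl_manifest.json"),
                                 simplifyVector = FALSE)
  lapply(manifest, function(m) {
    px <- round(tiff::readTIFF(file.path(dir, m$file)) * 65535)
    structure(
      list(pixels = px, spacing_mm = m$spacing_mm, gantry = m$gantry,
           couch = m$couch, collimator = m$collimator, id = m$id,
           truth = NULL, seed = NA_integer_),
      class = "wl_image"
    )
  })
}
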