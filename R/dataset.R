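#' Generate a labeled synthetic phantom dataset
#'
#' Produces `n_per_class` images for every (section kind, class) combination,
#' each with a distinct seed derived from `master_seed`, and returns them in a
#' tibble with the image in a list-column. A class is a set of artifact kinds
#' (the empty set is the regular class); multi-artifact classes apply the
#' injectors sequentially in the fixed order scatter, beam hardening, rings,
#' crescent so datasets are reproducible.
#'
#' @param n_per_class Images per class per section (>= 2).
#' @param classes List of character vectors of artifact kinds; `character(0)`
#'   or `"regular"` denotes the artifact-free class. Defaults to the five
#'   single classes (regular plus each artifact alone).
#' @param section_kinds Section kinds to generate (default: all four).
#' @param noise_sigma,spacing_mm,size Passed to [generate_section()].
#' @param master_seed Integer master seed; per-image seeds are derived from it.
#' @param specs Optional named list of [artifact_spec()] objects overriding
#'   the default spec per kind.
#'
#' @return A tibble with columns `id`, `section_kind`, `class` (collapsed
#'   label string), `labels` (list-column), `seed` and `image` (list-column of
#'   [section_image][new_section_image] objects).
#' @examples
#' ds <- generate_dataset(n_per_class = 2, section_kinds = "uniformity",
#'                        classes = list("regular", "rings"), master_seed = 1)
#' dplyr::count(ds, class)
#' @export
generate_dataset <- function(n_per_class = 40,
                             classes = list(character(0), "rings", "scatter",
                                            "beam_hardening", "crescent"),
                             section_kinds = c("high_contrast", "low_contrast",
                                               "spatial_resolution", "uniformity"),
                             noise_sigma = 15, spacing_mm = 0.5, size = 256,
                             master_seed = 0, specs = NULL) {
  if (n_per_class < 2) rlang::abort("`n_per_class` must be at least 2.")
  if (length(classes) == 0) rlang::abort("`classes` must be non-empty.")
  classes <- lapply(classes, normalize_class)
  keys <- vapply(classes, class_key, character(1))
  if (anyDuplicated(keys)) {
    rlang::abort(paste0("Duplicate class specs: ", keys[duplicated(keys)][1]))
  }
  section_kinds <- vapply(section_kinds, match_section_kind, character(1))

  combos <- tidyr::expand_grid(
    section_kind = section_kinds,
    class = keys,
    replicate = seq_len(n_per_class)
  )
  combos$labels <- rep(rep(classes, each = n_per_class), times = length(section_kinds))
  combos$seed <- derive_seed(master_seed, seq_len(nrow(combos)))
  combos$image <- purrr::pmap(
    list(combos$section_kind, combos$labels, combos$seed),
    function(kind, labels, seed) {
      img <- generate_section(kind, noise_sigma = noise_sigma,
                              spacing_mm = spacing_mm, size = size, seed = seed)
      for (a in intersect(injection_order(), labels)) {
        spec <- if (!is.null(specs[[a]])) specs[[a]] else artifact_spec(a)
        img <- inject_artifact(img, spec)
      }
      img
    }
  )
  tibble::tibble(
    id = sprintf("%s_%s_%03d", combos$section_kind, combos$class, combos$replicate),
    section_kind = combos$section_kind,
    class = combos$class,
    labels = combos$labels,
    seed = combos$seed,
    image = combos$image
  )
}

# Fixed multi-artifact application order.
injection_order <- function() c("scatter", "beam_hardening", "rings", "crescent")

normalize_class <- function(cls) {
  if (length(cls) == 1 && identical(cls, "regular")) return(character(0))
  bad <- setdiff(cls, artifact_kinds())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown artifact kind(s) in class spec: ",
                        paste(bad, collapse = ", ")))
  }
  sort(unique(cls))
}

class_key <- function(labels) {
  if (length(labels) == 0) "regular" else paste(sort(labels), collapse = "+")
}
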