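#' Build a QA baseline from reference metrics
#'
#' Averages the classical metrics of a reference (commissioning) dataset per
#' section and metric, and attaches the tolerance each future measurement
#' will be checked against.
#'
#' @param metrics Long metric tibble from [iq_metrics()] (or
#'   [compute_iq_metrics()] rows), columns `section_kind`, `metric`, `value`.
#' @param tolerance Default tolerance (> 0); relative by default (0.1 = 10%).
#' @param tolerance_type `"relative"` or `"absolute"`.
#' @param overrides Optional tibble `section_kind`, `metric`, `tolerance`,
#'   `tolerance_type` overriding the default per metric.
#' @return Baseline tibble: `section_kind`, `metric`, `value`, `tolerance`,
#'   `tolerance_type`.
#' @export
create_baseline <- function(metrics, tolerance = 0.1,
                            tolerance_type = c("relative", "absolute"),
                            overrides = NULL) {
  tolerance_type <- match.arg(tolerance_type)
  if (tolerance <= 0) rlang::abort("`tolerance` must be positive.")
  base <- metrics |>
    dplyr::group_by(.data$section_kind, .data$metric) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::mutate(tolerance = tolerance, tolerance_type = tolerance_type)
  if (!is.null(overrides)) {
    base <- dplyr::rows_update(base, overrides,
                               by = c("section_kind", "metric"))
  }
  base
}

#' Compare measured metrics against a baseline
#'
#' A metric passes when `|measured - baseline| <= tolerance` (absolute) or
#' `<= tolerance * |baseline|` (relative). Every measured metric must be
#' covered by the baseline; a missing one is a hard error naming it.
#'
#' @param measured Long metric tibble (`section_kind`, `metric`, `value`).
#' @param baseline A [create_baseline()] tibble.
#' @return Tibble with `section_kind`, `metric`, `measured`, `baseline`,
#'   `delta`, `limit`, `pass`.
#' @export
compare_to_baseline <- function(measured, baseline) {
  key <- paste(measured$section_kind, measured$metric)
  bkey <- paste(baseline$section_kind, baseline$metric)
  missing <- setdiff(key, bkey)
  if (length(missing) > 0) {
    rlang::abort(paste0("Metric(s) missing from baseline: ",
                        paste(missing, collapse = ", ")))
  }
  measured |>
    dplyr::rename(measured = "value") |>
    dplyr::left_join(baseline, by = c("section_kind", "metric")) |>
    dplyr::mutate(
      delta = .data$measured - .data$value,
      limit = ifelse(.data$tolerance_type == "relative",
                     .data$tolerance * abs(.data$value), .data$tolerance),
      pass = abs(.data$delta) <= .data$limit
    ) |>
    dplyr::select("section_kind", "metric", "measured",
                  baseline = "value", "delta", "limit", "pass")
}

#' Run the monthly image-quality analysis
#'
#' For every image of the input set: locate ROIs, compute the classical
#' metrics, compare them to the baseline, extract the full feature vector and
#' classify artifacts. Results are aggregated into a `qa_report`; the overall
#' status is `"fail"` as soon as any metric is out of tolerance or any image
#' carries a detected artifact.
#'
#' @param dataset Dataset tibble (e.g. from [generate_dataset()] or
#'   [read_dataset()]).
#' @param baseline A [create_baseline()] tibble.
#' @param model A trained [artifact_classifier][train_artifact_classifier].
#' @return An object of class `qa_report`: list with `metrics` (per-image
#'   baseline comparison), `classifications`, `overall` and `config`.
#' @export
run_monthly_iq <- function(dataset, baseline, model) {
  if (nrow(dataset) == 0) rlang::abort("Input image set is empty.")
  metrics <- iq_metrics(dataset)
  comparisons <- metrics |>
    dplyr::group_by(.data$id) |>
    dplyr::group_modify(function(df, key) {
      compare_to_baseline(df[, c("section_kind", "metric", "value")], baseline)
    }) |>
    dplyr::ungroup()
  features <- extract_features(dataset)
  classifications <- classify_artifacts(model, features)
  clean <- vapply(classifications$detected,
                  function(d) identical(d, "regular"), logical(1))
  overall <- if (all(comparisons$pass, na.rm = TRUE) &&
                 !any(is.na(comparisons$pass)) && all(clean)) "pass" else "fail"
  structure(
    list(metrics = comparisons, classifications = classifications,
         overall = overall,
         config = list(n_images = nrow(dataset),
                       sections = sort(unique(dataset$section_kind)))),
    class = "qa_report"
  )
}

#' @export
print.qa_report <- function(x, ...) {
  cat(sprintf("<qa_report> %d image(s), overall: %s\n",
              x$config$n_images, x$overall))
  cat(sprintf("  metrics out of tolerance: %d / %d\n",
              sum(!x$metrics$pass, na.rm = TRUE), nrow(x$metrics)))
  flagged <- x$classifications[
    !vapply(x$classifications$detected, function(d) identical(d, "regular"),
            logical(1)), ]
  cat(sprintf("  images with detected artifacts: %d / %d\n",
              nrow(flagged), nrow(x$classifications)))
  invisible(x)
}

#' Serialize a QA report
#'
#' Writes the report as deterministic JSON (no timestamps, so identical
#' inputs give byte-identical files) and optionally as a human-readable
#' markdown summary.
#'
#' @param report A [run_monthly_iq()] report.
#' @param path_json Path for the JSON report.
#' @param path_md Optional path for a markdown summary.
#' @return `path_json`, invisibly.
#' @export
write_qa_report <- function(report, path_json, path_md = NULL) {
  payload <- list(
    overall = report$overall,
    config = report$config,
    metrics = report$metrics,
    classifications = dplyr::mutate(
      report$classifications,
      detected = vapply(.data$detected, paste, character(1), collapse = "+")
    )
  )
  jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  if (!is.null(path_md)) {
    lines <- c(
      "# Monthly imaging QA report", "",
      sprintf("Overall status: **%s**", report$overall), "",
      sprintf("- images analyzed: %d", report$config$n_images),
      sprintf("- metrics out of tolerance: %d / %d",
              sum(!report$metrics$pass, na.rm = TRUE), nrow(report$metrics)),
      sprintf("- images with detected artifacts: %d / %d",
              sum(!vapply(report$classifications$detected,
                          function(d) identical(d, "regular"), logical(1))),
              nrow(report$classifications))
    )
    writeLines(lines, path_md)
  }
  invisible(path_json)
}

#' Daily couch shift residual check
#'
#' After a known random couch displacement (within 2 cm per axis) is applied
#' and recovered by image registration, the residual `recovered - applied`
#' per axis must stay within 2 mm for the regular IGRT profile or 1 mm for
#' the SBRT profile. Registration itself is out of scope here; the two shift
#' vectors are inputs.
#'
#' @param applied_shift_mm,recovered_shift_mm Length-3 numeric (mm).
#' @param profile `"igrt"` (2 mm) or `"sbrt"` (1 mm).
#' @return An object of class `shift_check`: tibble of per-axis residuals
#'   plus `pass` and `profile` fields.
#' @examples
#' run_daily_shift_check(c(5, 0, -3), c(5.2, 1.5, -3), profile = "igrt")$pass
#' @export
run_daily_shift_check <- function(applied_shift_mm, recovered_shift_mm,
                                  profile = c("igrt", "sbrt")) {
  profile <- match.arg(profile)
  if (length(applied_shift_mm) != 3 || length(recovered_shift_mm) != 3) {
    rlang::abort("Shift vectors must have 3 axes.")
  }
  if (any(abs(applied_shift_mm) > 20)) {
    rlang::abort("Applied shift exceeds the 2 cm per-axis limit.")
  }
  tol <- if (profile == "igrt") 2 else 1
  residual <- recovered_shift_mm - applied_shift_mm
  axes <- tibble::tibble(
    axis = c("x", "y", "z"),
    applied_mm = applied_shift_mm,
    recovered_mm = recovered_shift_mm,
    residual_mm = residual,
    tolerance_mm = tol,
    pass = abs(residual) <= tol
  )
  structure(list(axes = axes, profile = profile, tolerance_mm = tol,
                 pass = all(axes$pass)),
            class = "shift_check")
}

#' @export
print.shift_check <- function(x, ...) {
  cat(sprintf("<shift_check> profile %s (tolerance %g mm): %s\n",
              x$profile, x$tolerance_mm, if (x$pass) "PASS" else "FAIL"))
  print(x$axes)
  invisible(x)
}

#' @rdname run_daily_shift_check
#' @param x A `shift_check`.
#' @param ... Unused.
#' @method tidy shift_check
#' @export
tidy.shift_check <- function(x, ...) x$axes
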