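#' First-order statistics of an ROI
#'
#' Mean, standard deviation, histogram entropy, skewness and kurtosis of a
#' pixel sample. Entropy uses a 256-bin equal-width histogram over the sample
#' min-max and is reported in bits. Skewness and kurtosis are standardized
#' central moments (`m3 / m2^1.5` and the excess `m4 / m2^2 - 3`), defined as
#' 0 when the sample is constant.
#'
#' @param x Numeric vector of at least 2 pixels.
#' @return Named numeric of length 5: `mean`, `STDV`, `entropy`, `skewness`,
#'   `kurtosis`.
#' @examples
#' first_order_stats(c(rep(0, 50), rep(100, 50)))[c("mean", "entropy")]
#' @export
first_order_stats <- function(x) {
  if (length(x) < 2) rlang::abort("At least 2 pixels are required.")
  if (anyNA(x) || any(!is.finite(x))) rlang::abort("Pixels must be finite.")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    return(c(mean = m, STDV = 0, entropy = 0, skewness = 0, kurtosis = 0))
  }
  skew <- mean((x - m)^3) / m2^1.5
  kurt <- mean((x - m)^4) / m2^2 - 3
  c(mean = m, STDV = stats::sd(x), entropy = histogram_entropy(x, 256),
    skewness = skew, kurtosis = kurt)
}

histogram_entropy <- function(x, bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  idx <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * bins) + 1, bins)
  p <- tabulate(idx, bins)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

# Offsets (drow, dcol) for the four co-occurrence directions. Angles follow
# the usual image convention (x along columns, y up = decreasing row), so with
# symmetric matrices 315 deg is the 135 deg diagonal.
glcm_offsets <- function(distance = 1) {
  list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0), `315` = c(1, 1)) |>
    lapply(function(o) o * distance)
}

glcm_feature_names <- function() {
  c("contrast", "correlation", "dissimilarity", "energy", "entropy",
    "homogeneity", "inverse difference", "inverse difference normalized",
    "inverse difference moment normalized",
    "information measure of correlation 1",
    "information measure of correlation 2",
    "maximum probability", "autocorrelation", "cluster shade",
    "cluster prominence", "sum average", "sum entropy", "sum variance",
    "difference entropy")
}

# Equal-width quantization of masked pixels to 1..levels over their min-max.
quantize_pixels <- function(pixels, mask, levels) {
  q <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  v <- pixels[mask]
  rng <- range(v)
  q[mask] <- if (rng[1] == rng[2]) 1L else {
    pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  }
  q
}

# Symmetric normalized co-occurrence matrix for one offset; only pixel pairs
# with both ends inside the mask contribute.
glcm_matrix <- function(q, drow, dcol, levels) {
  nr <- nrow(q); nc <- ncol(q)
  if (nr <= abs(drow) || nc <= abs(dcol)) {
    rlang::abort("Image is smaller than the co-occurrence offset.")
  }
  r1 <- max(1, 1 - drow):min(nr, nr - drow)
  c1 <- max(1, 1 - dcol):min(nc, nc - dcol)
  a <- q[r1, c1]
  b <- q[r1 + drow, c1 + dcol]
  ok <- !is.na(a) & !is.na(b)
  counts <- matrix(tabulate((a[ok] - 1L) * levels + b[ok], levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  if (sum(counts) == 0) rlang::abort("No co-occurring pixel pairs in the mask.")
  counts / sum(counts)
}

# The 19 scalar features of one symmetric normalized GLCM (levels x levels,
# gray levels indexed 1..L). Logarithms are base 2 (bits).
glcm_features_from_matrix <- function(P) {
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  d <- i - j
  px <- rowSums(P)                       # == colSums by symmetry
  mu <- sum(seq_len(L) * px)
  sigma2 <- sum((seq_len(L) - mu)^2 * px)
  ent2 <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }

  # sum and difference distributions
  psum <- vapply(2:(2 * L), function(k) sum(P[i + j == k]), numeric(1))
  pdiff <- vapply(0:(L - 1), function(k) sum(P[abs(d) == k]), numeric(1))
  sum_avg <- sum((2:(2 * L)) * psum)

  hxy <- ent2(P)
  pxy <- px[row(P)] * px[col(P)]         # product of marginals, matrix order
  pos <- P > 0 & pxy > 0
  hxy1 <- -sum(P[pos] * log2(pxy[pos]))
  hxy2 <- { pp <- pxy[pxy > 0]; -sum(pp * log2(pp)) }
  hx <- ent2(px)
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - hxy)), 0))
  corr <- if (sigma2 > 0) sum((i - mu) * (j - mu) * P) / sigma2 else 1

  stats::setNames(c(
    sum(d^2 * P),
    corr,
    sum(abs(d) * P),
    sum(P^2),
    hxy,
    sum(P / (1 + d^2)),
    sum(P / (1 + abs(d))),
    sum(P / (1 + abs(d) / L)),
    sum(P / (1 + d^2 / L^2)),
    imc1,
    imc2,
    max(P),
    sum(i * j * P),
    sum((i + j - 2 * mu)^3 * P),
    sum((i + j - 2 * mu)^4 * P),
    sum_avg,
    ent2(psum),
    sum(((2:(2 * L)) - sum_avg)^2 * psum),
    ent2(pdiff)
  ), glcm_feature_names())
}

#' Gray-level co-occurrence texture features
#'
#' Quantizes the masked pixels to `levels` gray levels by equal-width binning
#' over their min-max (hence invariant to any increasing affine rescaling),
#' builds one symmetric normalized co-occurrence matrix per direction (0, 45,
#' 90 and 315 degrees at the given pixel distance), and computes 19 named
#' scalar features per direction: 76 values in total.
#'
#' @param pixels Numeric matrix.
#' @param mask Logical matrix of pixels belonging to the ROI (default: all).
#' @param levels Number of gray levels (default 8).
#' @param distance Neighbor distance in pixels (default 1).
#' @return Named numeric of length 76, names `"<feature> (<angle> deg)"`.
#' @export
glcm_features <- function(pixels, mask = NULL, levels = 8, distance = 1) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (anyNA(pixels[mask])) rlang::abort("Masked pixels must be finite.")
  q <- quantize_pixels(pixels, mask, levels)
  out <- lapply(names(glcm_offsets(distance)), function(ang) {
    o <- glcm_offsets(distance)[[ang]]
    f <- glcm_features_from_matrix(glcm_matrix(q, o[1], o[2], levels))
    stats::setNames(f, sprintf("%s (%s deg)", names(f), ang))
  })
  unlist(out)
}

#' Multi-scale filter-response features
#'
#' For each scale `s` the image is Gaussian-smoothed with `sigma = s` and
#' three responses are summarized by their mean and standard deviation over
#' the ROI: the smoothed intensity (first order), the central-difference
#' gradient magnitude (gradient) and the discrete Laplacian (second order) —
#' 6 values per scale, 18 in total for scales 1, 2 and 4. The ROI is eroded
#' by the kernel support so edge effects from outside the ROI never leak in.
#'
#' @inheritParams glcm_features
#' @param scales Numeric vector of scales (default `c(1, 2, 4)`).
#' @return Named numeric of length `6 * length(scales)`.
#' @export
scale_features <- function(pixels, mask = NULL, scales = c(1, 2, 4)) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(pixels), ncol(pixels))
  if (anyNA(pixels[mask]) || any(!is.finite(pixels[mask]))) {
    rlang::abort("Masked pixels must be finite.")
  }
  out <- lapply(scales, function(s) {
    sm <- gaussian_smooth(pixels, s)
    interior <- erode_mask(mask, ceiling(3 * s) + 2L)
    if (!any(interior)) rlang::abort("ROI too small for the largest kernel.")
    gm <- gradient_magnitude(sm)[interior]
    lp <- laplacian(sm)[interior]
    v <- c(mean(sm[interior]), stats::sd(sm[interior]),
           mean(gm), stats::sd(gm), mean(lp), stats::sd(lp))
    stats::setNames(v, sprintf(
      "%s (scale %g)",
      c("smoothed mean", "smoothed SD", "gradient mean", "gradient SD",
        "laplacian mean", "laplacian SD"), s))
  })
  unlist(out)
}

#' Names of the 99 texture features, in registry order
#'
#' 5 first-order statistics, then 76 co-occurrence features (19 per direction
#' for 0, 45, 90, 315 degrees), then 18 scale features (6 per scale for
#' scales 1, 2, 4). This order is fixed; classifiers refer to features by
#' these names.
#'
#' @return Character vector of length 99.
#' @export
texture_feature_names <- function() {
  c(
    c("mean", "STDV", "entropy", "skewness", "kurtosis"),
    unlist(lapply(names(glcm_offsets()), function(ang) {
      sprintf("%s (%s deg)", glcm_feature_names(), ang)
    })),
    unlist(lapply(c(1, 2, 4), function(s) {
      sprintf("%s (scale %g)",
              c("smoothed mean", "smoothed SD", "gradient mean", "gradient SD",
                "laplacian mean", "laplacian SD"), s)
    }))
  )
}

#' Classical metric names appended to the texture block for a section kind
#'
#' @param section_kind A section kind.
#' @return Character vector of metric names.
#' @export
classical_metric_names <- function(section_kind) {
  switch(match_section_kind(section_kind),
    high_contrast = ,
    low_contrast = c("CNR 3 mm", "CNR 9 mm", "CNR 20 mm"),
    spatial_resolution = c("MTF50", "MTF10"),
    uniformity = c("uniformity", "noise")
  )
}

# Whole-section texture ROI: interior of the phantom disk, one pixel margin.
section_texture_mask <- function(img) {
  disc_mask(nrow(img$pixels), img$spacing_mm, c(0, 0),
            img$geometry$disk_radius_mm - img$spacing_mm)
}

#' Full feature vector for one section image
#'
#' Concatenates the 99 texture features (computed over the whole section,
#' i.e. the interior of the phantom disk) with the section's classical
#' metrics, in fixed registry order.
#'
#' @param img A [section_image][new_section_image].
#' @param metrics Optional precomputed [compute_iq_metrics()] tibble for the
#'   same image; computed on the fly when `NULL`. A section-kind mismatch is
#'   an error.
#' @return A one-row tibble: `section_kind` followed by one column per
#'   feature.
#' @export
extract_feature_vector <- function(img, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- compute_iq_metrics(img)
  } else if (!all(metrics$section_kind == img$section_kind)) {
    rlang::abort("`metrics` were computed for a different section kind.")
  }
  mask <- section_texture_mask(img)
  tex <- c(
    first_order_stats(img$pixels[mask]),
    glcm_features(img$pixels, mask),
    scale_features(img$pixels, mask)
  )
  stopifnot(identical(names(tex), texture_feature_names()))
  classical <- stats::setNames(metrics$value, metrics$metric)
  classical <- classical[classical_metric_names(img$section_kind)]
  tibble::tibble(section_kind = img$section_kind,
                 !!!as.list(c(tex, classical)))
}

#' Feature table for a whole dataset
#'
#' Applies [extract_feature_vector()] to every image of a dataset tibble and
#' binds the identifying columns back on, giving the samples-by-features
#' table the classifier trains on.
#'
#' @param dataset A tibble from [generate_dataset()].
#' @return A wide tibble: `id`, `section_kind`, `class`, `labels`
#'   (list-column), then one column per feature.
#' @export
extract_features <- function(dataset) {
  feats <- purrr::map_dfr(dataset$image, extract_feature_vector)
  dplyr::bind_cols(
    dataset[, intersect(c("id", "class", "labels"), names(dataset))],
    feats
  ) |>
    dplyr::relocate(dplyr::any_of(c("id", "section_kind", "class", "labels")))
}
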