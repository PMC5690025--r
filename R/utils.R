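# Internal raster helpers. Images are plain numeric matrices indexed [row, col];
# physical coordinates are mm, origin at the image centre, x along columns,
# y along rows (increasing with row index).

pixel_grid <- function(size, spacing_mm) {
  c0 <- (size + 1) / 2
  ax <- (seq_len(size) - c0) * spacing_mm
  list(
    x = matrix(ax, nrow = size, ncol = size, byrow = TRUE),
    y = matrix(ax, nrow = size, ncol = size, byrow = FALSE)
  )
}

disc_mask <- function(size, spacing_mm, center_mm = c(0, 0), radius_mm) {
  g <- pixel_grid(size, spacing_mm)
  (g$x - center_mm[1])^2 + (g$y - center_mm[2])^2 <= radius_mm^2
}

rect_mask <- function(size, spacing_mm, center_mm, width_mm, height_mm) {
  g <- pixel_grid(size, spacing_mm)
  abs(g$x - center_mm[1]) <= width_mm / 2 & abs(g$y - center_mm[2]) <= height_mm / 2
}

# Shift a matrix by (drow, dcol) with edge replication (indices clamped).
shift_clamped <- function(m, drow, dcol) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + drow, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dcol, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian smoothing, edge-replicated. Kernel truncated at 3 sigma.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- ceiling(3 * sigma)
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(w)) out <- out + w[t] * shift_clamped(m, 0L, t - r - 1L)
  m2 <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(w)) m2 <- m2 + w[t] * shift_clamped(out, t - r - 1L, 0L)
  m2
}

# Central-difference gradient magnitude (intensity units per pixel).
gradient_magnitude <- function(m) {
  gx <- (shift_clamped(m, 0L, 1L) - shift_clamped(m, 0L, -1L)) / 2
  gy <- (shift_clamped(m, 1L, 0L) - shift_clamped(m, -1L, 0L)) / 2
  sqrt(gx^2 + gy^2)
}

# 4-neighbour discrete Laplacian.
laplacian <- function(m) {
  shift_clamped(m, 1L, 0L) + shift_clamped(m, -1L, 0L) +
    shift_clamped(m, 0L, 1L) + shift_clamped(m, 0L, -1L) - 4 * m
}

# Binary erosion by a (2k+1)x(2k+1) square element, separable running-min.
erode_mask <- function(mask, k) {
  if (k <= 0) return(mask)
  rows <- mask
  for (d in seq_len(k)) {
    rows <- rows & shift_pad_false(mask, 0L, d) & shift_pad_false(mask, 0L, -d)
  }
  out <- rows
  for (d in seq_len(k)) {
    out <- out & shift_pad_false(rows, d, 0L) & shift_pad_false(rows, -d, 0L)
  }
  out
}

# Shift with FALSE padding (for mask erosion, so borders erode away).
shift_pad_false <- function(m, drow, dcol) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  rs <- seq_len(nr) - drow; cs <- seq_len(nc) - dcol
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

# Distance from points (x, y) to the segment p1-p2 (all in mm).
dist_to_segment <- function(x, y, p1, p2) {
  vx <- p2[1] - p1[1]; vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  t <- ((x - p1[1]) * vx + (y - p1[2]) * vy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((x - (p1[1] + t * vx))^2 + (y - (p1[2] + t * vy))^2)
}

derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(index)) %% 2147483647)
}
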