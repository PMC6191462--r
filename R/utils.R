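# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a stage seed from a master seed
#'
#' Maps a master seed and a stage tag to a reproducible 31-bit seed, so that
#' independent pipeline stages (phantom generation, region growing, fold
#' assignment, ...) consume independent but fully determined random streams.
#'
#' @param master integer master seed.
#' @param tag character stage tag, e.g. `"case-7"` or `"cv-folds"`.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), length(tag) == 1L)
  h <- as.double(master %% 2147483647)
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

#' Dice overlap between two binary masks
#'
#' @param a,b logical arrays of identical shape (or `binary_mask` objects).
#' @return Dice coefficient `2|A∩B| / (|A|+|B|)`; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  a <- mask_values(a); b <- mask_values(b)
  stopifnot(identical(dim(a), dim(b)))
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

mask_values <- function(x) {
  if (inherits(x, "binary_mask")) x$values else x
}

# linear (0-based) index <-> (i,j,k) 0-based array index helpers
lin_to_ijk <- function(lin, dim) {
  i <- lin %% dim[1]
  j <- (lin %/% dim[1]) %% dim[2]
  k <- lin %/% (dim[1] * dim[2])
  cbind(i, j, k)
}

ijk_to_lin <- function(ijk, dim) {
  ijk[, 1] + ijk[, 2] * dim[1] + ijk[, 3] * dim[1] * dim[2]
}

# world coordinates (mm) of 0-based voxel indices
ijk_to_world <- function(ijk, spacing, origin) {
  sweep(sweep(ijk, 2, spacing, `*`), 2, origin, `+`)
}

world_to_ijk <- function(xyz, spacing, origin) {
  round(sweep(sweep(xyz, 2, origin, `-`), 2, spacing, `/`))
}

# Polyline utilities ---------------------------------------------------------

polyline_lengths <- function(pts) {
  d <- diff(pts)
  sqrt(rowSums(d * d))
}

polyline_arclength <- function(pts) sum(polyline_lengths(pts))

#' Resample a polyline to uniform arc-length steps
#'
#' Linear interpolation along the cumulative arc length; the first and last
#' points are preserved exactly. Used before point-wise curvature/torsion so
#' that window-based estimates are step-independent.
#'
#' @param pts numeric matrix `n x 3` of points (mm).
#' @param step_mm target spacing between consecutive output points (mm).
#' @return A numeric matrix of resampled points.
#' @export
resample_polyline <- function(pts, step_mm) {
  stopifnot(is.matrix(pts), ncol(pts) == 3, step_mm > 0)
  if (nrow(pts) < 2) return(pts)
  s <- c(0, cumsum(polyline_lengths(pts)))
  total <- s[length(s)]
  if (total <= 0) return(pts[1, , drop = FALSE])
  n_out <- max(2L, as.integer(round(total / step_mm)) + 1L)
  si <- seq(0, total, length.out = n_out)
  out <- vapply(1:3, function(d) approx(s, pts[, d], xout = si, ties = "ordered")$y,
                numeric(n_out))
  dedupe_polyline(out)
}

# drop consecutive duplicate points
dedupe_polyline <- function(pts) {
  if (nrow(pts) < 2) return(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
  pts[keep, , drop = FALSE]
}

# Smooth a polyline with a centred moving average, endpoints fixed.
smooth_polyline <- function(pts, window = 3L) {
  n <- nrow(pts)
  if (n < 3 || window < 3) return(pts)
  half <- window %/% 2L
  out <- pts
  for (idx in 2:(n - 1)) {
    lo <- max(1L, idx - half); hi <- min(n, idx + half)
    out[idx, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out
}
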