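# Planar homography between image pixels and the 2D pitch plane.
#
# Field frame convention: origin at the center of the attacked goal line,
# +x in meters from the penalty spot toward the goal (so the spot sits at
# x = -11), +y to the kicker's left. 0 degrees = facing the goal.

#' Construct a homography object
#'
#' A 3x3 projective map from image pixels to field meters (or any two
#' planes), defined up to scale. Normalized so that `h9 = 1` when
#' `|h9| > 1e-9`, otherwise to unit Frobenius norm.
#'
#' @param M Numeric 3x3 matrix, invertible.
#' @return Object of class `homography` (a normalized 3x3 matrix).
#' @export
homography <- function(M) {
  M <- unclass(as.matrix(M))
  if (!is.numeric(M) || any(dim(M) != c(3L, 3L)) || any(!is.finite(M)))
    pp_stop("homography must be a finite numeric 3x3 matrix",
            "pp_geometry_error")
  if (abs(det(M)) < 1e-12)
    pp_stop("homography matrix is singular", "pp_geometry_error")
  M <- if (abs(M[3L, 3L]) > 1e-9) M / M[3L, 3L] else M / sqrt(sum(M^2))
  structure(M, class = "homography")
}

#' @export
print.homography <- function(x, ...) {
  cat("<homography> image -> field (up to scale)\n")
  print(unclass(x))
  invisible(x)
}

#' Invert a homography
#' @param H A `homography`.
#' @return The inverse map as a `homography`.
#' @export
invert_homography <- function(H) homography(solve(unclass(H)))

# Hartley similarity normalization: centroid to origin, mean distance sqrt(2)
hartley_transform <- function(pts) {
  ctr <- colMeans(pts)
  d <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3L, 3L, byrow = TRUE)
}

dlt_system <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]
    u <- dst[i, 1]; v <- dst[i, 2]
    A[2L * i - 1L, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2L * i, ]      <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  A
}

solve_h_nullspace <- function(A) {
  sv <- svd(A, nu = 0, nv = 9L)
  if (sv$d[8L] / sv$d[1L] < 1e-10)
    pp_stop("degenerate correspondence configuration (rank-deficient DLT system)",
            "pp_geometry_error")
  matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
}

#' Estimate the image-to-field homography by the DLT
#'
#' Direct linear transformation from >= 4 point correspondences, solved as
#' the null vector (least-squares for over-determined systems) of the
#' stacked 2n x 9 constraint matrix via SVD. Hartley point normalization is
#' applied on both sides for conditioning at pixel scales. With exactly 4
#' correspondences in general position the solution is exact.
#'
#' @param correspondences Data frame with columns `img_x`, `img_y`,
#'   `field_x`, `field_y` (>= 4 rows). Field coordinates in meters; corners
#'   projected outside the visible image are accepted as given.
#' @return A `homography` mapping image points to field points.
#' @export
estimate_homography <- function(correspondences) {
  cn <- c("img_x", "img_y", "field_x", "field_y")
  if (!all(cn %in% names(correspondences)))
    pp_stop(sprintf("correspondences need columns %s", toString(cn)),
            "pp_geometry_error")
  if (nrow(correspondences) < 4L)
    pp_stop("at least 4 correspondences are required", "pp_geometry_error")
  src <- as.matrix(correspondences[, c("img_x", "img_y")])
  dst <- as.matrix(correspondences[, c("field_x", "field_y")])
  Ts <- hartley_transform(src)
  Td <- hartley_transform(dst)
  nsrc <- t(Ts %*% rbind(t(src), 1))[, 1:2, drop = FALSE]
  ndst <- t(Td %*% rbind(t(dst), 1))[, 1:2, drop = FALSE]
  Hn <- solve_h_nullspace(dlt_system(nsrc, ndst))
  homography(solve(Td) %*% Hn %*% Ts)
}

#' Project an image point to field coordinates
#'
#' Applies `[x', y', w']^T = H [x, y, 1]^T` and divides by the homogeneous
#' coordinate.
#'
#' @param H A `homography`.
#' @param image_point Numeric length-2 `(x, y)`.
#' @return Numeric `(x, y)` field point in meters.
#' @export
project_point <- function(H, image_point) {
  p <- unclass(H) %*% c(image_point[1:2], 1)
  if (abs(p[3L]) < 1e-12)
    pp_stop("image point maps to infinity (homogeneous w' ~ 0)",
            "pp_geometry_error")
  c(x = p[1L] / p[3L], y = p[2L] / p[3L])
}

#' Project several image points at once
#' @param H A `homography`.
#' @param pts n x 2 matrix of image points.
#' @return n x 2 matrix of field points.
#' @export
project_points <- function(H, pts) {
  t(apply(as.matrix(pts), 1L, function(p) project_point(H, p)))
}

#' Read a corner-correspondence file
#'
#' @param path CSV with columns `corner_id`, `img_x`, `img_y`, `field_x`,
#'   `field_y`.
#' @return Data frame of correspondences.
#' @export
read_corners <- function(path) {
  if (!file.exists(path))
    pp_stop(sprintf("corner file '%s' does not exist", path), "pp_io_error")
  df <- utils::read.csv(path)
  need <- c("img_x", "img_y", "field_x", "field_y")
  if (!all(need %in% names(df)))
    pp_stop(sprintf("corner file must have columns %s", toString(need)),
            "pp_geometry_error")
  df
}
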