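#' Ellipse-equivalent aspect ratio of a cell outline
#'
#' Fits each cell with the ellipse having the same area-weighted second
#' central moments as the polygon interior and returns the ratio of its
#' major to minor axis, i.e. `sqrt(lambda_max / lambda_min)` of the
#' covariance tensor of the polygon. This is the deterministic, closed-form
#' reading of "fit an ellipse and extract major and minor axes": it is
#' exact for true ellipses and invariant to rotation, translation and
#' uniform scaling.
#'
#' For cells living on a curved surface, a k x 3 matrix may be given; the
#' outline is first projected onto its own best-fit plane (principal
#' components of the vertices), mirroring curvature-aware 2.5D measurement.
#'
#' @param polygon k x 2 (or k x 3) matrix of outline vertices, ordered
#'   along the boundary, not self-intersecting, enclosing positive area.
#' @return Aspect ratio >= 1.
#' @examples
#' rect <- cbind(c(0, 2, 2, 0), c(0, 0, 1, 1))
#' cell_aspect_ratio(rect) # 2
#' @export
cell_aspect_ratio <- function(polygon) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) == 3L) polygon <- project_to_plane(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon must be a k x 2 (or k x 3) matrix with k >= 3")
  cov <- polygon_moments(polygon)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) stop("degenerate polygon: zero minor axis")
  sqrt(ev[1] / ev[2])
}

# second central moment (covariance) tensor of a polygon interior, per unit
# area; closed form via Green's theorem
polygon_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  if (A == 0) stop("degenerate polygon: zero area")
  if (A < 0) { # reorder to CCW
    return(polygon_moments(xy[rev(seq_len(nrow(xy))), , drop = FALSE]))
  }
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  ixx <- sum(cr * (x^2 + x * x2 + x2^2)) / 12
  iyy <- sum(cr * (y^2 + y * y2 + y2^2)) / 12
  ixy <- sum(cr * (x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y)) / 24
  # central, per unit area
  m <- matrix(c(ixx / A - cx^2, ixy / A - cx * cy,
                ixy / A - cx * cy, iyy / A - cy^2), 2, 2)
  m
}

# project a 3D outline onto its best-fit (least-squares) plane
project_to_plane <- function(P) {
  cen <- colMeans(P)
  Pc <- sweep(P, 2, cen)
  sv <- svd(Pc, nu = 0, nv = 2)
  Pc %*% sv$v
}
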