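# Small 3D geometry kernel shared by the generators, hydrogen placement and
# the interaction detectors. All coordinates are in Angstrom, angles in degrees.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("degenerate geometry: zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at `b` formed by points a-b-c, in degrees
#' @keywords internal
angle3 <- function(a, b, c) {
  u <- unitv(a - b)
  v <- unitv(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Torsion angle of points a-b-c-d, in degrees, in (-180, 180]
#' @keywords internal
torsion4 <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

# Natural extension of reference frame (NeRF): place point D bonded to C with
# bond length |CD|, angle B-C-D and torsion A-B-C-D.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Rotation matrix for rotation by `theta` degrees about unit axis `u`
rotation_matrix <- function(u, theta) {
  u <- unitv(u)
  th <- deg2rad(theta)
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3, byrow = TRUE)
}

# rotation vector (axis * angle in radians) from a rotation matrix
rotvec_from_matrix <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- max(-1, min(1, ct))
  theta <- acos(ct)
  if (theta < 1e-9) return(c(0, 0, 0))
  if (abs(theta - pi) < 1e-6) {
    # axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonals
    if (axis[1] > 1e-6) {
      axis[2] <- B[1, 2] / axis[1]; axis[3] <- B[1, 3] / axis[1]
    } else if (axis[2] > 1e-6) {
      axis[3] <- B[2, 3] / axis[2]
    }
    return(unitv(axis) * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

# All pairwise distances between two coordinate matrices (n x 3, m x 3)
cross_dist <- function(xa, xb) {
  a2 <- rowSums(xa^2)
  b2 <- rowSums(xb^2)
  d2 <- outer(a2, b2, "+") - 2 * (xa %*% t(xb))
  d2[d2 < 0] <- 0
  sqrt(d2)
}
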