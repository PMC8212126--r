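# Rotation / quaternion utilities shared by the samplers, the pose
# descriptors and the self-organizing map.  Quaternions are length-4
# numeric vectors (w, x, y, z), kept at unit norm.

#' Normalize a quaternion to unit length
#'
#' @param q numeric(4), (w, x, y, z).
#' @return numeric(4) with unit Euclidean norm.
#' @keywords internal
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' The matrix acts on row vectors: `xyz %*% t(R)` rotates coordinates.
#'
#' @param q numeric(4) unit quaternion (w, x, y, z).
#' @return 3x3 rotation matrix with determinant +1.
#' @export
quat_to_mat <- function(q) {
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method; the returned quaternion has nonnegative scalar part
#' (the q / -q double cover is resolved toward w >= 0).
#'
#' @param R 3x3 rotation matrix.
#' @return numeric(4) unit quaternion (w, x, y, z).
#' @export
mat_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- quat_normalize(q)
  if (q[1] < 0) q <- -q
  q
}

#' Draw a uniformly distributed random rotation quaternion
#'
#' Uses the subgroup algorithm (Shoemake), uniform over SO(3) under the
#' session RNG stream.
#'
#' @return numeric(4) unit quaternion.
#' @export
quat_random <- function() {
  u <- stats::runif(3)
  c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3]))
}

#' Spherical linear interpolation between unit quaternions
#'
#' The second quaternion is sign-aligned to the first (shortest arc) before
#' interpolating, so the q / -q double cover never produces long-way paths.
#'
#' @param qa,qb unit quaternions.
#' @param t interpolation fraction in `[0, 1]`.
#' @return unit quaternion on the geodesic from `qa` toward `qb`.
#' @export
quat_slerp <- function(qa, qb, t) {
  d <- sum(qa * qb)
  if (d < 0) { qb <- -qb; d <- -d }
  d <- min(d, 1)
  if (d > 1 - 1e-10) return(quat_normalize((1 - t) * qa + t * qb))
  th <- acos(d)
  quat_normalize((sin((1 - t) * th) * qa + sin(t * th) * qb) / sin(th))
}

# Rodrigues rotation of row-vector coordinates about a unit axis by angle.
rotate_about_axis <- function(xyz, origin, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# Kabsch: rotation R (det +1) minimizing ||Pc R - Qc|| for centred row-major
# coordinate matrices; returns list(R, rmsd, center_p, center_q).
kabsch_fit <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  s <- svd(M)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(R = R, rmsd = rmsd, center_p = cp, center_q = cq)
}

# Place a fourth atom from three predecessors given bond length, bond angle
# (at c) and torsion a-b-c-new (NeRF construction).  Angles in radians.
place_atom_internal <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) {            # colinear predecessors: pick any perpendicular
    n <- c(bc[2], -bc[1], 0)
    nn <- sqrt(sum(n^2))
    if (nn < 1e-12) { n <- c(0, bc[3], -bc[2]); nn <- sqrt(sum(n^2)) }
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}
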