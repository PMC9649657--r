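# Rigid-body geometry: vector helpers, internal-coordinate atom placement
# (NeRF), dihedral measurement, Kabsch superposition, rotation conversions.

vec_cross <- function(a, b) {
  c(a[2]*b[3] - a[3]*b[2], a[3]*b[1] - a[1]*b[3], a[1]*b[2] - a[2]*b[1])
}

vec_norm <- function(a) sqrt(sum(a * a))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle difference into (-180, 180]
#' @param x angle(s) in degrees
#' @return wrapped angle(s) in degrees
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# Place atom D given positions of A, B, C and internal coordinates
# bond |C-D|, angle B-C-D (deg), torsion A-B-C-D (deg). Standard NeRF.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  th <- deg2rad(angle)
  ph <- deg2rad(torsion)
  # sign of the out-of-plane component chosen so that the measured dihedral
  # A-B-C-D equals the requested torsion
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph),
          -bond * sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / vec_norm(bc)
  ab <- b - a
  n <- vec_cross(ab, bc)
  nn <- vec_norm(n)
  if (nn < 1e-10) stop("degenerate geometry in atom placement (collinear frame)")
  n <- n / nn
  m <- vec_cross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(M %*% d2 + c)
}

#' Measure the dihedral angle defined by four points
#' @param p1,p2,p3,p4 numeric length-3 coordinates (Angstrom)
#' @return angle in degrees in (-180, 180]
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, b2 / vec_norm(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

bond_angle <- function(p1, p2, p3) {
  v1 <- p1 - p2; v2 <- p3 - p2
  cs <- sum(v1 * v2) / (vec_norm(v1) * vec_norm(v2))
  rad2deg(acos(max(-1, min(1, cs))))
}

# Kabsch: least-squares rotation/translation mapping `mob` onto `ref`
# (n x 3 matrices). Returns rotation (applied as x %*% t(R)), translation,
# and the residual RMSD.
kabsch_fit <- function(ref, mob) {
  if (nrow(ref) != nrow(mob)) stop("point sets differ in size")
  if (nrow(ref) < 3) stop("degenerate selection: need at least 3 atoms")
  cr <- colMeans(ref); cm <- colMeans(mob)
  P <- sweep(ref, 2, cr)
  Q <- sweep(mob, 2, cm)
  if (qr(Q)$rank < 2) stop("degenerate selection: collinear atoms")
  H <- t(Q) %*% P
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- Q %*% t(R)
  rmsd <- sqrt(mean(rowSums((P - moved)^2)))
  trans <- cr - as.numeric(R %*% cm)
  list(rotation = R, translation = trans, rmsd = rmsd)
}

apply_transform <- function(x, rotation, translation) {
  sweep(x %*% t(rotation), 2, translation, `+`)
}

# axis-angle (rotation vector, radians) -> rotation matrix
rotvec_to_matrix <- function(v) {
  th <- vec_norm(v)
  if (th < 1e-12) return(diag(3))
  u <- v / th
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

matrix_to_rotvec <- function(R) {
  cs <- (sum(diag(R)) - 1) / 2
  th <- acos(max(-1, min(1, cs)))
  if (th < 1e-8) return(c(0, 0, 0))
  if (abs(th - pi) < 1e-6) {
    # antipodal case: extract axis from R + I
    A <- (R + diag(3)) / 2
    u <- sqrt(pmax(0, diag(A)))
    i <- which.max(u)
    u <- A[, i] / u[i]
    return(u / vec_norm(u) * th)
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(th))
  ax * th
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
           2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
           2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
         3, 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3,2]-R[2,3])/s, (R[1,3]-R[3,1])/s, (R[2,1]-R[1,2])/s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1,1] - R[2,2] - R[3,3]) * 2
      q <- c((R[3,2]-R[2,3])/s, 0.25*s, (R[1,2]+R[2,1])/s, (R[1,3]+R[3,1])/s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2,2] - R[1,1] - R[3,3]) * 2
      q <- c((R[1,3]-R[3,1])/s, (R[1,2]+R[2,1])/s, 0.25*s, (R[2,3]+R[3,2])/s)
    } else {
      s <- sqrt(1 + R[3,3] - R[1,1] - R[2,2]) * 2
      q <- c((R[2,1]-R[1,2])/s, (R[1,3]+R[3,1])/s, (R[2,3]+R[3,2])/s, 0.25*s)
    }
  }
  q / vec_norm(q)
}

# angular distance between two rotations, degrees
rotation_angle_between <- function(R1, R2) {
  R <- t(R1) %*% R2
  cs <- (sum(diag(R)) - 1) / 2
  rad2deg(acos(max(-1, min(1, cs))))
}

#' Deterministic quasi-uniform rotation set
#'
#' Generates `n` quaternions covering SO(3) approximately uniformly using the
#' super-Fibonacci spiral construction. Seedless and reproducible; used as the
#' rotation search grid for rigid-body docking.
#'
#' @param n number of rotations
#' @return an `n x 4` matrix of unit quaternions (w, x, y, z)
#' @export
rotation_samples <- function(n) {
  stopifnot(n >= 1)
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041
  i <- seq_len(n) - 0.5
  t <- i / n
  d <- 2 * pi * i
  r <- sqrt(t); R <- sqrt(1 - t)
  alpha <- d / phi
  beta <- d / psi
  cbind(r * sin(alpha), r * cos(alpha), R * sin(beta), R * cos(beta))
}
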