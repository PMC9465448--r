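# Elementary vector geometry shared by all modules. Coordinates are plain
# numeric length-3 vectors (Angstrom); point sets are n x 3 matrices.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Angle at vertex `b` of the triangle a-b-c, in degrees
#' @param a,b,c points (length-3 numeric)
#' @return angle in degrees, in [0, 180]
#' @keywords internal
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Dihedral angle of points a-b-c-d about the b-c axis, degrees in (-180, 180]
#' @keywords internal
vdihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Place atom D given reference atoms A, B, C (NeRF construction): D is bonded
# to C at `bond` Angstrom, with angle D-C-B = `angle` degrees and dihedral
# A-B-C-D = `torsion` degrees.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), -sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  # columns: bc, m, n form a right-handed frame at c
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R %*% x + t` against `y`, with equal weights. The reflection branch of the
#' SVD solution is corrected so that `det(R) = +1`.
#'
#' @param x,y n x 3 matrices of corresponding points (moving, target)
#' @return list with `rotation` (3x3), `translation` (length 3) and `rmsd`
#' @examples
#' x <- matrix(rnorm(12), 4, 3)
#' f <- kabsch(x, x)
#' f$rmsd  # 0
#' @export
kabsch <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  stopifnot(ncol(x) == 3, ncol(y) == 3, nrow(x) == nrow(y), nrow(x) >= 1)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  if (max(abs(x0)) < 1e-12 && nrow(x) > 1)
    stop("degenerate superposition: all moving points are identical")
  h <- t(x0) %*% y0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cy - as.numeric(rot %*% cx)
  fitted <- sweep(x %*% t(rot), 2, trans, "+")
  list(rotation = rot,
       translation = trans,
       rmsd = sqrt(mean(rowSums((fitted - y)^2))))
}

#' Apply a rigid transform to a point matrix
#' @param xyz n x 3 matrix
#' @param transform list with `rotation` and `translation` (as from [kabsch()])
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

# Deterministic unit sphere points (golden-spiral lattice), n x 3.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Random proper rotation from a seeded RNG stream (uniform quaternion).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
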