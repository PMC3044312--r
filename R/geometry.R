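## Small 3D geometry kernel: dihedrals, internal-coordinate atom placement
## (NeRF), ideal Cbeta construction and Kabsch superposition. All coordinates
## are in Angstroms, vectors are length-3 numerics.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stopf("degenerate geometry: zero-length vector")
  a / n
}

#' Dihedral angle defined by four points
#'
#' @param p1,p2,p3,p4 length-3 coordinate vectors (Angstrom).
#' @return angle in degrees, wrapped to (-180, 180].
#' @keywords internal
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three previously placed atoms a, b, c, place d at `bond` Angstrom
#' from c, with angle b-c-d equal to `angle` degrees and dihedral a-b-c-d
#' equal to `torsion` degrees.
#'
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * cos(tor) * sin(pi - ang),
          bond * sin(tor) * sin(pi - ang))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  ## rotation matrix with columns bc, m, n
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Ideal Cbeta position from backbone N, CA, C
#'
#' Places a Cbeta at 1.521 Angstrom from CA with near-tetrahedral geometry
#' and L-amino-acid chirality, via the standard virtual-Cbeta direction
#' (linear combination of N->CA, CA->C and their cross product). Used when a
#' non-glycine query residue is threaded onto a glycine template residue,
#' and when decoy coordinates are re-idealized.
#'
#' @keywords internal
place_cb <- function(n, ca, c) {
  b <- ca - n
  cc <- c - ca
  a <- vcross(b, cc)
  dir <- -0.58273431 * a + 0.56802827 * b - 0.54067466 * cc
  ca + 1.521 * vunit(dir)
}

#' Kabsch least-squares superposition
#'
#' Optimal rotation/translation of `mobile` onto `fixed` (both k x 3
#' matrices, rows paired). Returns the transformed mobile coordinates and
#' the RMSD after fitting.
#'
#' @keywords internal
kabsch_fit <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3L)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm)
  B <- sweep(fixed, 2, cf)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  out <- sweep(A %*% t(R), 2, cf, FUN = "+")
  list(coords = out,
       rotation = R,
       rmsd = sqrt(mean(rowSums((out - fixed)^2))))
}

#' Apply a rigid-body transform to an n x 3 coordinate matrix
#' @keywords internal
rigid_transform <- function(xyz, rotation, translation = c(0, 0, 0)) {
  sweep(xyz %*% t(rotation), 2, translation, FUN = "+")
}

#' A deterministic non-trivial rotation matrix (for tests/diagnostics)
#' @keywords internal
rotation_matrix <- function(axis = c(1, 1, 1), angle_deg = 37) {
  u <- vunit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
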