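## Low-level vector geometry shared by every torsion / plane / twist routine.
## All positions are numeric length-3 vectors in Angstrom, all angles degrees.

DEG <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle between two vectors
#'
#' @param a,b Numeric length-3 vectors.
#' @return Angle in degrees in [0, 180].
#' @keywords internal
vangle <- function(a, b) {
  ua <- vunit(a); ub <- vunit(b)
  ## atan2 form is stable near 0 and 180
  atan2(vnorm(vcross(ua, ub)), sum(ua * ub)) * DEG
}

#' Torsion (dihedral) angle of four points
#'
#' Computes the dihedral angle defined by points `p1-p2-p3-p4` using the
#' standard atan2-on-cross-products formulation, following the IUPAC sign
#' convention (cis = 0, positive clockwise looking from p2 to p3).
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @param range One of `"360"` (default, angle mapped into \[0, 360)) or
#'   `"180"` (signed angle in (-180, 180\]).
#' @return Torsion angle in degrees.
#' @examples
#' dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0))   # 0 (cis)
#' dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(2,1,0))   # 180 (trans)
#' @export
dihedral <- function(p1, p2, p3, p4, range = c("360", "180")) {
  range <- match.arg(range)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("degenerate torsion: two consecutive points coincide")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("degenerate torsion: three consecutive points are colinear")
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  ang <- atan2(y, x) * DEG
  if (range == "360") ang <- ang %% 360
  ang
}

#' Map an angle in degrees into [0, 360)
#' @keywords internal
wrap360 <- function(x) {
  y <- x %% 360
  ## guard against 360-minus-epsilon artefacts of the modulo
  ifelse(360 - y < 1e-9, 0, y)
}

#' Map an angle in degrees into (-180, 180]
#' @keywords internal
wrap180 <- function(x) {
  y <- x %% 360
  ifelse(y > 180, y - 360, y)
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three placed atoms `a-b-c`, returns the position `d` such that
#' `|c-d| = bond`, the angle b-c-d equals `angle` and the torsion a-b-c-d
#' equals `torsion`.
#'
#' @param a,b,c Numeric length-3 reference positions.
#' @param bond Bond length c-d (Angstrom).
#' @param angle Bond angle b-c-d (degrees).
#' @param torsion Torsion a-b-c-d (degrees, IUPAC sign).
#' @return Numeric length-3 position of the new atom.
#' @keywords internal
nerfPlace <- function(a, b, c, bond, angle, torsion) {
  angle <- angle / DEG
  torsion <- torsion / DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Least-squares plane through a set of points
#'
#' Fits a plane by SVD of the centered coordinates; the normal is the
#' singular direction of least variance, oriented (when `orient` is given)
#' to have positive dot product with `orient`.
#'
#' @param xyz Numeric n x 3 matrix.
#' @param orient Optional length-3 vector fixing the normal hemisphere.
#' @return List with `centroid`, unit `normal` and `rms` (out-of-plane RMS
#'   of the fitted points, Angstrom).
#' @keywords internal
fitPlane <- function(xyz, orient = NULL) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L, nrow(xyz) >= 3L)
  ctr <- colMeans(xyz)
  m <- sweep(xyz, 2L, ctr)
  sv <- svd(m, nu = 0L, nv = 3L)
  normal <- sv$v[, 3L]
  if (!is.null(orient) && sum(normal * orient) < 0) normal <- -normal
  rms <- sqrt(mean((m %*% normal)^2))
  list(centroid = ctr, normal = normal, rms = rms)
}

## Rotation matrices about coordinate axes (degrees)
rotZ <- function(theta) {
  t <- theta / DEG
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3L, 3L)
}

rotX <- function(theta) {
  t <- theta / DEG
  matrix(c(1, 0, 0, 0, cos(t), sin(t), 0, -sin(t), cos(t)), 3L, 3L)
}

## Rotation about an arbitrary unit axis (Rodrigues), degrees
rotAxis <- function(axis, theta) {
  u <- vunit(axis)
  t <- theta / DEG
  ct <- cos(t); st <- sin(t)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0), 3L, 3L)
  diag(3L) * ct + st * K + (1 - ct) * (u %o% u)
}

#' Signed stacking twist between two stacked bases
#'
#' The twist is the signed angle between the C1'-to-glycosidic-nitrogen
#' vectors of the two residues, projected onto the plane perpendicular to
#' `axis`. Positive values correspond to a right-handed helical step
#' (rotation by the right-hand rule about the 5'-to-3' axis), negative to a
#' left-handed step.
#'
#' @param lower,upper Residue atom tables (see [getResidue()]) of the 5' and
#'   3' stacked residues.
#' @param axis Numeric length-3 stacking axis, oriented 5' to 3'.
#' @return Signed twist in degrees in (-180, 180].
#' @export
stackingTwist <- function(lower, upper, axis) {
  if (vnorm(axis) < 1e-9) stop("stacking axis must be nonzero")
  ax <- vunit(axis)
  v1 <- glycosidicVector(lower)
  v2 <- glycosidicVector(upper)
  p1 <- v1 - sum(v1 * ax) * ax
  p2 <- v2 - sum(v2 * ax) * ax
  if (vnorm(p1) < 1e-6 || vnorm(p2) < 1e-6)
    stop("undefined twist: glycosidic vector parallel to the stacking axis")
  wrap180(atan2(sum(vcross(p1, p2) * ax), sum(p1 * p2)) * DEG)
}

## C1' -> glycosidic nitrogen vector of a residue atom table
glycosidicVector <- function(res) {
  c1 <- atomXYZ(res, "C1'")
  n <- atomXYZ(res, if (isPurine(res)) "N9" else "N1")
  if (is.null(c1) || is.null(n))
    stop("residue lacks C1' or its glycosidic nitrogen")
  n - c1
}
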