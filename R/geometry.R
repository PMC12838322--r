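#' Euclidean distance between two points
#'
#' @param a,b numeric 3-vectors (Angstrom)
#' @return distance in Angstrom
#' @export
atomDistance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L,
            all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

.cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector where a direction is required")
  v / n
}

#' Signed torsion angle of four points
#'
#' Standard right-hand (IUPAC) convention: trans = 180 degrees, cis = 0.
#' Result is in degrees in the half-open range (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors
#' @return angle in degrees
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b2^2)) < 1e-12) stop("undefined dihedral: p2 == p3")
  n1 <- .cross(b1, b2)
  n2 <- .cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10)
    stop("undefined dihedral: collinear bounding triple")
  b2u <- .unit(b2)
  x <- sum(n1 * n2)
  y <- sum(.cross(n1, n2) * b2u)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# NeRF placement: new atom D bonded to C with |C-D| = bondLength,
# angle(B,C,D) = bondAngle (deg), torsion(A,B,C,D) = torsion (deg).
.placeAtom <- function(a, b, c, bondLength, bondAngle, torsion) {
  th <- bondAngle * pi / 180
  ph <- torsion * pi / 180
  bc <- .unit(c - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d2 <- bondLength * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c + bc * d2[1L] + m * d2[2L] + n * d2[3L]
}
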