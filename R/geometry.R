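## Small 3-vector helpers shared by builders and classifiers. All coordinates
## are in Angstroms, all angles in degrees unless noted.

vec_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vec_len <- function(a) sqrt(sum(a^2))

vec_unit <- function(a) {
  n <- vec_len(a)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Torsion (dihedral) angle of four points
#'
#' Returns the signed dihedral a-b-c-d in degrees in (-180, 180].
#'
#' @param a,b,c,d Numeric 3-vectors (Angstroms).
#' @return Angle in degrees.
#' @export
torsion_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vec_cross(b1, b2)
  n2 <- vec_cross(b2, b3)
  m1 <- vec_cross(n1, vec_unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

bond_angle <- function(a, b, c) {
  u <- vec_unit(a - b)
  v <- vec_unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

## Natural-extension (NeRF) placement: position atom D bonded to C with bond
## length `len`, angle B-C-D `ang`, and torsion A-B-C-D `tors` (degrees).
place_atom <- function(a, b, c, len, ang, tors) {
  theta <- deg2rad(ang)
  chi <- -deg2rad(tors)
  bc <- vec_unit(c - b)
  n <- vec_unit(vec_cross(b - a, bc))
  m <- cbind(bc, vec_cross(n, bc), n)
  d2 <- c(-len * cos(theta), len * sin(theta) * cos(chi), len * sin(theta) * sin(chi))
  as.numeric(c + m %*% d2)
}

## Apply a rigid motion (3x3 rotation + translation) to an n x 3 matrix.
transform_coords <- function(xyz, rotation = diag(3), translation = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, -translation)
}

rotation_about_z <- function(angle_deg) {
  a <- deg2rad(angle_deg)
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

## Random proper rotation (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' matched coordinate sets, or computes the RMSD in a fixed frame without
#' fitting (for ligand-displacement series on multi-model files).
#'
#' @param coords_a,coords_b n x 3 matrices (or data frames with x, y, z
#'   columns) of matched positions in Angstroms; `coords_b` is moved onto
#'   `coords_a`.
#' @param fit If `FALSE`, skip the fit and report the raw RMSD (rotation =
#'   identity, translation = 0).
#' @return An object of class `superposition`: list with `rotation` (3 x 3,
#'   det +1), `translation`, `rmsd` (Angstroms), `n_atoms`.
#' @export
superpose <- function(coords_a, coords_b, fit = TRUE) {
  a <- coords_matrix(coords_a)
  b <- coords_matrix(coords_b)
  if (nrow(a) != nrow(b)) abort("coordinate sets must have equal length")
  if (!fit) {
    rmsd <- sqrt(mean(rowSums((a - b)^2)))
    return(structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmsd = rmsd, n_atoms = nrow(a)),
                     class = "superposition"))
  }
  if (nrow(a) < 3) abort("at least 3 points are required for superposition")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  if (qr(a0)$rank < 2) abort("points are collinear; superposition is degenerate")
  h <- t(b0) %*% a0
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- sweep(b0 %*% t(rot), 2, -ca)
  rmsd <- sqrt(mean(rowSums((moved - a)^2)))
  translation <- as.numeric(ca - rot %*% cb)
  structure(list(rotation = rot, translation = translation,
                 rmsd = rmsd, n_atoms = nrow(a)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid superposition of %d atoms: rmsd = %.4f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

coords_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != 3) abort("coordinates must be n x 3")
  if (!all(is.finite(x))) abort("coordinates must be finite")
  x
}
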