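#' Rigid-body frames and rotation utilities
#'
#' The global coordinate system is right-handed with +x anterior, +y to the
#' subject's left, and +z cranial. Gravity acts in -z. All rotations are
#' proper orthonormal 3x3 matrices; user-facing angles are in degrees and
#' converted to radians internally.
#'
#' @param origin numeric length-3 position (m).
#' @param R 3x3 rotation matrix.
#' @return `new_frame()` returns a list with elements `origin` and `R`,
#'   classed `"ls_frame"`.
#' @export
new_frame <- function(origin = c(0, 0, 0), R = diag(3)) {
  origin <- as.numeric(origin)
  stopifnot(length(origin) == 3L, all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > 1e-8 || det(R) < 0)
    stop("frame rotation must be orthonormal with determinant +1")
  structure(list(origin = origin, R = R), class = "ls_frame")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Elementary rotation matrices (angle in degrees)
#' @param a angle in degrees.
#' @rdname rotations
#' @export
rot_x <- function(a) {
  a <- deg2rad(a); c_ <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c_, s, 0, -s, c_), 3, 3)
}
#' @rdname rotations
#' @export
rot_y <- function(a) {
  a <- deg2rad(a); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, 0, -s, 0, 1, 0, s, 0, c_), 3, 3)
}
#' @rdname rotations
#' @export
rot_z <- function(a) {
  a <- deg2rad(a); c_ <- cos(a); s <- sin(a)
  matrix(c(c_, s, 0, -s, c_, 0, 0, 0, 1), 3, 3)
}

#' Rotation vector (axis-angle, radians) to rotation matrix
#' @param w numeric length-3 rotation vector in radians.
#' @export
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) {
    W <- skew(w)
    return(diag(3) + W + 0.5 * W %*% W)
  }
  k <- w / th
  K <- skew(k)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to rotation vector (radians)
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_rotvec <- function(R) {
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  th <- acos(ct)
  if (th < 1e-10) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (abs(pi - th) < 1e-6) {
    # near pi: extract axis from symmetric part
    A <- (R + diag(3)) / 2
    k <- sqrt(pmax(diag(A), 0))
    # fix signs using off-diagonals
    i <- which.max(k)
    if (i == 1) { k[2] <- A[1, 2] / k[1]; k[3] <- A[1, 3] / k[1] }
    if (i == 2) { k[1] <- A[1, 2] / k[2]; k[3] <- A[2, 3] / k[2] }
    if (i == 3) { k[1] <- A[1, 3] / k[3]; k[2] <- A[2, 3] / k[3] }
    return(th * k / sqrt(sum(k^2)))
  }
  th / (2 * sin(th)) *
    c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Transform points from a body frame to world coordinates
#' @param frame an `ls_frame`.
#' @param pts n x 3 matrix of body-frame points.
#' @export
frame_transform <- function(frame, pts) {
  pts <- rbind(pts)
  P <- pts %*% t(frame$R)
  P[, 1] <- P[, 1] + frame$origin[1]
  P[, 2] <- P[, 2] + frame$origin[2]
  P[, 3] <- P[, 3] + frame$origin[3]
  P
}

#' Sagittal rotation angle (degrees, about global +y) of a rotation matrix
#'
#' For motion dominated by rotation about +y this equals the y component of
#' the rotation vector; positive values tip the +x (anterior) axis caudally,
#' i.e. flexion.
#' @param R rotation matrix.
#' @export
sagittal_angle <- function(R) rad2deg(matrix_to_rotvec(R)[2])

frame_compose <- function(f1, f2) {
  # f1 then f2 applied in f1's coordinates: world pose of f2 given parent f1
  new_frame(origin = as.numeric(f1$origin + f1$R %*% f2$origin),
            R = f1$R %*% f2$R)
}
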