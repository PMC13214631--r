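# Rodrigues rotation-vector algebra.
#
# A rotation by phi (0 <= phi < 180 degrees) about a unit axis n is encoded as
# the 3-vector r = tan(phi/2) * n.  The zero vector is the identity.  Rotation
# vectors compose by the Rodrigues rule and invert by negation, so the whole
# algebra lives in plain numeric length-3 vectors; angles are degrees at every
# public interface and radians internally.

DEG <- pi / 180

.tol <- 1e-9

deg2rad <- function(x) x * DEG
rad2deg <- function(x) x / DEG

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

norm3 <- function(v) sqrt(sum(v * v))

unit3 <- function(v) {
  n <- norm3(v)
  if (n < .tol) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

check_vec3 <- function(v, what = "vector") {
  if (!is.numeric(v) || length(v) != 3L || anyNA(v)) {
    stop(sprintf("%s must be a numeric vector of length 3 with no NA", what),
         call. = FALSE)
  }
  as.numeric(v)
}

#' Angle between two vectors
#'
#' @param u,v Numeric 3-vectors (need not be unit length).
#' @return The angle in degrees, in \[0, 180\].
#' @export
angle_between <- function(u, v) {
  u <- unit3(check_vec3(u, "u"))
  v <- unit3(check_vec3(v, "v"))
  # atan2 form is accurate for both small and near-180-degree angles
  rad2deg(atan2(norm3(cross3(u, v)), sum(u * v)))
}

#' Rotation vector from axis and angle
#'
#' Builds the Rodrigues vector `tan(angle/2) * axis`.  Rotations of 180 degrees
#' or more are not representable (the tangent diverges) and are rejected.
#'
#' @param axis Unit 3-vector (checked to 1e-9 unless `normalize = TRUE`).
#' @param angle_deg Rotation angle in degrees, `0 <= angle_deg < 180`.
#' @param normalize If `TRUE`, a non-unit axis is normalized instead of
#'   rejected.
#' @return A numeric 3-vector.
#' @examples
#' rv_from_axis_angle(c(0, 0, 1), 90)  # (0, 0, 1)
#' @export
rv_from_axis_angle <- function(axis, angle_deg, normalize = FALSE) {
  axis <- check_vec3(axis, "axis")
  if (!is.numeric(angle_deg) || length(angle_deg) != 1L || is.na(angle_deg)) {
    stop("angle_deg must be a single number", call. = FALSE)
  }
  if (angle_deg < 0 || angle_deg >= 180) {
    stop("angle_deg must lie in [0, 180): a half-turn has no finite rotation vector",
         call. = FALSE)
  }
  n <- norm3(axis)
  if (abs(n - 1) > .tol) {
    if (!normalize) {
      stop(sprintf("axis is not unit length (|axis| = %.6g); pass normalize = TRUE to rescale", n),
           call. = FALSE)
    }
    axis <- axis / n
  }
  tan(deg2rad(angle_deg) / 2) * axis
}

#' Rotation angle and axis of a rotation vector
#'
#' @param r Rotation vector.
#' @return `rv_angle()`: the angle in degrees, in \[0, 180).  `rv_axis()`: the
#'   unit axis (errors for the identity, which has no axis).
#' @export
rv_angle <- function(r) {
  r <- check_vec3(r, "r")
  rad2deg(2 * atan(norm3(r)))
}

#' @rdname rv_angle
#' @export
rv_axis <- function(r) {
  r <- check_vec3(r, "r")
  if (norm3(r) < .tol) stop("the identity rotation has no axis", call. = FALSE)
  r / norm3(r)
}

#' Compose two rotation vectors
#'
#' Implements the Rodrigues composition rule
#' `(outer + inner + outer x inner) / (1 - outer . inner)`,
#' which matches the matrix product `R(outer) %*% R(inner)`: rotations apply
#' from right to left, i.e. `inner` acts first.
#'
#' @param outer,inner Rotation vectors.
#' @return The rotation vector of the composite rotation.
#' @section Errors: if the composite rotation is a half-turn the denominator
#'   vanishes and the result is unrepresentable; this is rejected explicitly.
#' @export
rv_compose <- function(outer, inner) {
  outer <- check_vec3(outer, "outer")
  inner <- check_vec3(inner, "inner")
  denom <- 1 - sum(outer * inner)
  if (abs(denom) < .tol) {
    stop("composite rotation is a half-turn (180 degrees): not representable as a rotation vector",
         call. = FALSE)
  }
  (outer + inner + cross3(outer, inner)) / denom
}

#' Inverse rotation vector
#'
#' The inverse of `tan(phi/2) n` is the rotation by the same angle about the
#' opposite axis, i.e. simply `-r`.
#'
#' @param r Rotation vector.
#' @export
rv_inverse <- function(r) -check_vec3(r, "r")

#' Euler parameters of a rotation
#'
#' The pair `rho = cos(phi/2)`, `e = sin(phi/2) n` (a unit quaternion with
#' scalar part `rho`).  Unlike the rotation vector, this form represents
#' half-turns (`rho = 0`).
#'
#' @param rho Scalar part.
#' @param e Vector part (3-vector).
#' @return An object of class `"er_params"`.
#' @export
er_params <- function(rho, e) {
  e <- check_vec3(e, "e")
  if (abs(rho^2 + sum(e * e) - 1) > 1e-6) {
    stop("(rho, e) is not a unit quaternion", call. = FALSE)
  }
  structure(list(rho = rho, e = e), class = "er_params")
}

#' @rdname er_params
#' @param r Rotation vector to convert.
#' @export
er_from_rv <- function(r) {
  r <- check_vec3(r, "r")
  rho <- 1 / sqrt(1 + sum(r * r))
  er_params(rho, rho * r)
}

#' @rdname er_params
#' @param p An `"er_params"` object with `rho > 0` (angle below 180 degrees).
#' @export
rv_from_er <- function(p) {
  stopifnot(inherits(p, "er_params"))
  if (abs(p$rho) < .tol) {
    stop("half-turn (rho = 0) has no finite rotation vector", call. = FALSE)
  }
  p$e / p$rho
}

#' Compose Euler parameters
#'
#' `rho = rho' rho'' - e' . e''` and `e = rho' e'' + rho'' e' + e'' x e'`,
#' where the double-primed factor is the outer (second-applied) rotation.
#' Agrees with [rv_compose()] through `e / rho` whenever both sides are
#' representable.
#'
#' @param outer,inner `"er_params"` objects.
#' @export
er_compose <- function(outer, inner) {
  stopifnot(inherits(outer, "er_params"), inherits(inner, "er_params"))
  rho <- inner$rho * outer$rho - sum(inner$e * outer$e)
  e <- inner$rho * outer$e + outer$rho * inner$e + cross3(outer$e, inner$e)
  er_params(rho, e)
}

#' Convert between rotation vectors and rotation matrices
#'
#' `rv_to_matrix()` returns the 3x3 proper orthogonal matrix acting on column
#' vectors; `matrix_to_rv()` inverts it.  Matrices within tolerance of a
#' half-turn (trace near -1) are rejected since no finite rotation vector
#' exists.
#'
#' @param r Rotation vector.
#' @return A 3x3 rotation matrix.
#' @export
rv_to_matrix <- function(r) {
  r <- check_vec3(r, "r")
  n2 <- sum(r * r)
  if (n2 < 1e-300) return(diag(3))
  n <- r / sqrt(n2)
  phi <- 2 * atan(sqrt(n2))
  K <- matrix(c(0, n[3], -n[2],
                -n[3], 0, n[1],
                n[2], -n[1], 0), 3, 3)
  diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
}

#' @rdname rv_to_matrix
#' @param M A 3x3 proper rotation matrix (orthogonal, det +1, checked to 1e-6).
#' @export
matrix_to_rv <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(3L, 3L))) {
    stop("M must be a 3x3 matrix", call. = FALSE)
  }
  if (max(abs(t(M) %*% M - diag(3))) > 1e-6 || det(M) < 0) {
    stop("M is not a proper rotation matrix", call. = FALSE)
  }
  tr <- M[1, 1] + M[2, 2] + M[3, 3]
  if (tr < -1 + 1e-9) {
    stop("rotation is a half-turn (trace = -1): not representable as a rotation vector",
         call. = FALSE)
  }
  # quaternion extraction: q0 = cos(phi/2) > 0 away from half-turns
  q0 <- sqrt(max(0, 1 + tr)) / 2
  e <- c(M[3, 2] - M[2, 3], M[1, 3] - M[3, 1], M[2, 1] - M[1, 2]) / (4 * q0)
  e / q0
}

#' Apply a rotation vector to a point or direction
#'
#' @param r Rotation vector.
#' @param v 3-vector to rotate.
#' @export
rv_apply <- function(r, v) {
  as.numeric(rv_to_matrix(r) %*% check_vec3(v, "v"))
}

#' Geodesic rotation between two unit vectors
#'
#' The rotation in the plane spanned by `u` and `v` (axis `u x v / |u x v|`,
#' angle the angle between them) that carries `u` onto `v`.  Returns the zero
#' vector when `u == v`; antiparallel inputs have no unique axis and are
#' rejected.
#'
#' @param u,v Unit 3-vectors (checked to 1e-9).
#' @return A rotation vector whose axis is perpendicular to both `u` and `v`.
#' @export
geodesic_rv <- function(u, v) {
  u <- check_vec3(u, "u")
  v <- check_vec3(v, "v")
  if (abs(norm3(u) - 1) > 1e-6 || abs(norm3(v) - 1) > 1e-6) {
    stop("u and v must be unit vectors", call. = FALSE)
  }
  cr <- cross3(u, v)
  s <- norm3(cr)
  d <- sum(u * v)
  if (s < .tol) {
    if (d > 0) return(c(0, 0, 0))
    stop("u and v are antiparallel: the rotation axis is undefined", call. = FALSE)
  }
  tan(atan2(s, d) / 2) * (cr / s)
}
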