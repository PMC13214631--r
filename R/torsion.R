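# Torsion-free / torsional decomposition of eye posture changes.
#
# Any posture change splits uniquely into (i) the geodesic rotation r that
# carries the resting image-plane normal j onto its rotated image b — its axis
# lies in the resting image plane, which plays the role of the Listing plane —
# and (ii) a residual torsional rotation q about j itself.  The split is exact:
# r o q reconstructs the full rotation algebraically.

#' Decompose a posture change into torsion-free and torsional parts
#'
#' Given a posture reached from the resting posture, computes the torsion-free
#' rotation vector `geodesic_rv(j, b)` (axis in the plane `y = 0`), the
#' "primed" frame obtained by rotating the posture frame back by `-r` (its
#' middle vector returns to `j` exactly), the signed torsion angle `tau` from
#' `k` to the primed `c` about `+j`, and the torsional rotation vector
#' `q = tan(tau/2) j`.  By construction `rv_compose(r, q)` equals the full
#' rotation.
#'
#' Positive `tau` is a counterclockwise rotation of the frame about `+j` seen
#' from in front of the head; `tau_unsigned` is the frame angle used for
#' reporting.
#'
#' @param posture An `"eye_posture"`.
#' @param erp_eye The `"erp_eye"` the posture started from.
#' @return An object of class `"torsion_decomposition"`: fields `r`, `q`,
#'   `phi_deg`, `tau_deg`, `tau_unsigned_deg`, `n_axis` (or NULL for the
#'   identity), `primed_frame`, `side`.
#' @export
decompose_posture <- function(posture, erp_eye) {
  stopifnot(inherits(posture, "eye_posture"), inherits(erp_eye, "erp_eye"))
  j <- erp_eye$frame$j
  k <- erp_eye$frame$k
  b <- posture$frame$b_vec
  if (sum(b * j) < -1 + 1e-9) {
    stop("frame normal is antiparallel to the resting normal: decomposition undefined",
         call. = FALSE)
  }
  r <- geodesic_rv(j, b)
  R_back <- rv_to_matrix(rv_inverse(r))
  primed <- list(a = as.numeric(R_back %*% posture$frame$a_vec),
                 j = as.numeric(R_back %*% b),
                 c = as.numeric(R_back %*% posture$frame$c_vec))
  # signed angle from k to primed c about +j
  tau <- rad2deg(atan2(sum(cross3(k, primed$c) * j), sum(k * primed$c)))
  q <- tan(deg2rad(tau) / 2) * j
  structure(list(
    side = posture$side,
    r = r,
    q = q,
    phi_deg = rv_angle(r),
    tau_deg = tau,
    tau_unsigned_deg = abs(tau),
    n_axis = if (norm3(r) > 1e-12) rv_axis(r) else NULL,
    primed_frame = primed,
    full_rotation = posture$full_rotation
  ), class = "torsion_decomposition")
}

#' @export
print.torsion_decomposition <- function(x, ...) {
  cat(sprintf("<torsion_decomposition: %s eye, phi = %.3f deg, tau = %+.3f deg>\n",
              x$side, x$phi_deg, x$tau_deg))
  invisible(x)
}

#' Tidy a torsion decomposition
#'
#' @param x A `"torsion_decomposition"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy torsion_decomposition
#' @export
tidy.torsion_decomposition <- function(x, ...) {
  n <- x$n_axis %||% c(NA_real_, NA_real_, NA_real_)
  tibble::tibble(eye = x$side, phi_deg = x$phi_deg, tau_deg = x$tau_deg,
                 n_x = n[1], n_y = n[2], n_z = n[3],
                 r_x = x$r[1], r_y = x$r[2], r_z = x$r[3], q_y = x$q[2])
}

#' Torsional disparity
#'
#' The difference between right- and left-eye torsion angles,
#' `tau_r - tau_l`, in degrees.
#'
#' @param tau_r,tau_l Torsion angles in degrees.
#' @export
torsional_disparity <- function(tau_r, tau_l) tau_r - tau_l

#' Transfer rotation vectors between two tertiary postures
#'
#' For two postures reached from the resting posture with decompositions
#' `(r1, q1)` and `(r2, q2)`, the change from the first to the second has
#' torsion-free part `r12 = r2 o (-r1)` and torsional part
#' `q12 = tan((tau2 - tau1)/2) j`.  Note the half-angle form: composing two
#' rotations about the common axis `j` adds their angles, so the transfer
#' torsion angle is `tau2 - tau1` and its rotation vector carries the
#' half-angle tangent (this alone satisfies `q12 o q1 = q2`).
#'
#' Swapping the arguments negates `r12`, `q12`, and `tau12` (the reverse move
#' is the inverse).
#'
#' @param dec1,dec2 `"torsion_decomposition"` objects referenced to the same
#'   resting posture.
#' @return An object of class `"transfer_rvs"`: fields `r12`, `q12`,
#'   `tau12_deg`, `phi12_deg`.
#' @export
transfer_rvs <- function(dec1, dec2) {
  stopifnot(inherits(dec1, "torsion_decomposition"),
            inherits(dec2, "torsion_decomposition"))
  r12 <- rv_compose(dec2$r, rv_inverse(dec1$r))
  tau12 <- dec2$tau_deg - dec1$tau_deg
  q12 <- tan(deg2rad(tau12) / 2) * c(0, 1, 0)
  structure(list(r12 = r12, q12 = q12, tau12_deg = tau12,
                 phi12_deg = rv_angle(r12), side = dec1$side),
            class = "transfer_rvs")
}

#' @export
print.transfer_rvs <- function(x, ...) {
  cat(sprintf("<transfer_rvs: r12 = (%.5f, %.5f, %.5f), phi12 = %.3f deg, tau12 = %+.3f deg>\n",
              x$r12[1], x$r12[2], x$r12[3], x$phi12_deg, x$tau12_deg))
  invisible(x)
}

#' Transfer of torsional disparity
#'
#' The change in torsional disparity between two tertiary postures,
#' `delta_t12 = delta_t2 - delta_t1`; antisymmetric under swapping the
#' postures.
#'
#' @param delta_t1,delta_t2 Torsional disparities (degrees) of the two
#'   postures.
#' @export
disparity_transfer <- function(delta_t1, delta_t2) delta_t2 - delta_t1
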