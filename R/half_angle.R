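# The binocular half-angle rule: bisectors, displacement planes, the overlay
# check, and the tilt-angle coefficient (TAC).
#
# For a tertiary posture fixating F1, the displacement plane is perpendicular
# to the bisector of the resting image-plane normal j and the visual axis
# through F1.  The half-angle rule predicts that the transfer rotation vector
# r12 for a move away from F1 lies (approximately) in that plane, i.e. makes
# about 90 degrees with the bisector.

#' Bisector of the resting normal and a tertiary visual axis
#'
#' `normalize( j + unit(F1 - O*) )`, with `O*` the resting optical center or
#' the translated (rotated) one.
#'
#' @param erp_eye An `"erp_eye"`.
#' @param F1 Tertiary fixation point, cm.
#' @param use_translated_center If `TRUE`, `O*` is the optical center of the
#'   posture fixating `F1` (requires `posture`).
#' @param posture The `"eye_posture"` at `F1` (only needed when
#'   `use_translated_center = TRUE`).
#' @return A unit 3-vector.
#' @export
bisector <- function(erp_eye, F1, use_translated_center = FALSE, posture = NULL) {
  stopifnot(inherits(erp_eye, "erp_eye"))
  F1 <- check_vec3(F1, "F1")
  O_star <- if (use_translated_center) {
    stopifnot(inherits(posture, "eye_posture"))
    posture$o_prime
  } else {
    erp_eye$optical_center
  }
  if (norm3(F1 - O_star) < 1e-9) {
    stop("F1 coincides with the optical center", call. = FALSE)
  }
  unit3(erp_eye$frame$j + unit3(F1 - O_star))
}

#' Angle between a transfer rotation vector and the bisector
#'
#' Exactly 90 degrees would mean the rotation vector lies in the displacement
#' plane (the half-angle rule holding exactly).
#'
#' @param r12 Nonzero rotation vector.
#' @param e Unit bisector.
#' @return Angle in degrees, in \[0, 180\].
#' @export
alignment_angle <- function(r12, e) {
  r12 <- check_vec3(r12, "r12")
  if (norm3(r12) < 1e-12) {
    stop("alignment angle undefined for a zero rotation vector", call. = FALSE)
  }
  angle_between(r12, e)
}

#' Overlay check of the half-angle rule
#'
#' Rotates the point `F1` about the (translated) optical center of the `F2`
#' posture by `r12` and returns the angle between the line from that center
#' through the rotated point and the visual axis of the `F2` posture.  A small
#' residual certifies that the torsion-free transfer rotation generates the
#' actual gaze change.
#'
#' @param erp_eye An `"erp_eye"`.
#' @param F1 Starting fixation, cm.
#' @param posture2 The `"eye_posture"` fixating the end target.
#' @param r12 Transfer rotation vector (use `-r12` for the reverse move).
#' @param center Rotation/anchor point for the check: `"o_prime"` (default,
#'   the translated optical center) or `"rotation_center"`.
#' @param erp The `"binocular_erp"` (needed for `center = "rotation_center"`).
#' @return Residual angle in degrees.
#' @export
overlay_check <- function(erp_eye, F1, posture2, r12,
                          center = c("o_prime", "rotation_center"), erp = NULL) {
  stopifnot(inherits(erp_eye, "erp_eye"), inherits(posture2, "eye_posture"))
  F1 <- check_vec3(F1, "F1")
  center <- match.arg(center)
  ctr <- switch(center,
                o_prime = posture2$o_prime,
                rotation_center = erp_eye$rotation_center)
  if (norm3(F1 - ctr) < 1e-9 || norm3(posture2$target - ctr) < 1e-9) {
    stop("degenerate overlay geometry", call. = FALSE)
  }
  rotated <- ctr + rv_apply(r12, F1 - ctr)
  if (norm3(rotated - ctr) < 1e-9) stop("degenerate overlay geometry", call. = FALSE)
  angle_between(rotated - ctr, posture2$target - ctr)
}

#' Half-angle report: displacement plane, alignment, eccentricity, tilt, TAC
#'
#' Builds the full half-angle diagnostic for a move between two tertiary
#' fixations.  The eccentricity `xi` is the angle between the visual axis
#' through `F1` and the image-plane normal at `O*`; the displacement-plane
#' tilt `nu` is obtained from the point `J1` where the chord between
#' equidistant points on the visual axis (`I1`) and the normal line (`H1`)
#' crosses the plane through `O*` perpendicular to `r12` (the plane in which
#' points actually move under the rotation).  That crossing is solved exactly
#' from `(J1 - O*) . r12 = 0`, so the report does not depend on the chord
#' distance `d` or on any display scale.  `tac = nu / xi`; 0.5 means the
#' half-angle rule holds exactly.  `nu` carries the sign of the tilt (toward
#' the visual axis positive).
#'
#' @param erp_eye An `"erp_eye"`.
#' @param F1 Starting tertiary fixation, cm.
#' @param posture1 The `"eye_posture"` at `F1` (for the translated optical
#'   center); may be `NULL` to anchor at the resting optical center.
#' @param r12 Transfer rotation vector for the move away from `F1`.
#' @param use_translated_center Anchor `xi`/`nu` at the translated optical
#'   center (default `TRUE`) or the resting one.
#' @param bisector_at_translated_center Anchor the bisector at the translated
#'   center too (default `FALSE`).
#' @return An object of class `"half_angle_report"` with fields `bisector`,
#'   `plane_point`, `plane_normal`, `pi_deg` (alignment angle), `xi_deg`,
#'   `nu_deg`, `tac`, `j1`, `side`.
#' @export
tac_report <- function(erp_eye, F1, posture1 = NULL, r12,
                       use_translated_center = TRUE,
                       bisector_at_translated_center = FALSE) {
  stopifnot(inherits(erp_eye, "erp_eye"))
  F1 <- check_vec3(F1, "F1")
  r12 <- check_vec3(r12, "r12")
  if (norm3(r12) < 1e-12) {
    stop("tac_report needs a nonzero transfer rotation vector", call. = FALSE)
  }
  j <- erp_eye$frame$j
  O_star <- if (use_translated_center && !is.null(posture1)) {
    stopifnot(inherits(posture1, "eye_posture"))
    posture1$o_prime
  } else {
    erp_eye$optical_center
  }
  v_hat <- unit3(F1 - O_star)
  xi <- angle_between(v_hat, j)
  if (xi < 1e-9) stop("F1 lies on the normal line: eccentricity is zero", call. = FALSE)
  r_hat <- unit3(r12)
  # chord between H1 = O* + d j and I1 = O* + d v_hat; the crossing with the
  # plane (J1 - O*).r12 = 0 is at parameter t independent of d
  denom <- sum((v_hat - j) * r_hat)
  if (abs(denom) < 1e-12) {
    stop(paste("no crossing of the chord with the displacement plane:",
               "r12 makes equal angles with the normal and the visual axis"),
         call. = FALSE)
  }
  t <- -sum(j * r_hat) / denom
  j1_dir <- j + t * (v_hat - j)
  nu <- angle_between(j1_dir, j) * sign(t)
  e <- bisector(erp_eye, F1,
                use_translated_center = bisector_at_translated_center,
                posture = posture1)
  structure(list(
    side = erp_eye$side,
    bisector = e,
    plane_point = O_star,
    plane_normal = e,
    pi_deg = alignment_angle(r12, e),
    xi_deg = xi,
    nu_deg = nu,
    tac = nu / xi,
    j1 = O_star + j1_dir,
    r12 = r12
  ), class = "half_angle_report")
}

#' @export
print.half_angle_report <- function(x, ...) {
  cat(sprintf("<half_angle_report: %s eye, pi = %.3f deg, xi = %.3f deg, nu = %+.3f deg, tac = %.3f>\n",
              x$side, x$pi_deg, x$xi_deg, x$nu_deg, x$tac))
  invisible(x)
}

#' Tidy a half-angle report
#'
#' @param x A `"half_angle_report"`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy half_angle_report
#' @export
tidy.half_angle_report <- function(x, ...) {
  tibble::tibble(eye = x$side, pi_deg = x$pi_deg, xi_deg = x$xi_deg,
                 nu_deg = x$nu_deg, tac = x$tac,
                 e_x = x$bisector[1], e_y = x$bisector[2], e_z = x$bisector[3])
}
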