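# Gaze kinematics: the rigid rotation of an eye (about its rotation center)
# that redirects its gaze from the resting fixation Fa to a new target, under
# a selectable rotation convention.

#' Gaze-rotation conventions
#'
#' Redirecting a gaze axis to a new target fixes only two of the three
#' rotational degrees of freedom; the conventions differ in how the residual
#' torsion about the line of sight is disposed of:
#'
#' * `fixation_geodesic` — single rotation about the axis perpendicular to the
#'   old and new fixation axes (rotation-center based; the closed-form
#'   construction).
#' * `visual_geodesic` — same, for the visual axis through the optical center.
#' * `gimbal_vertical_first` — rotation about the head-vertical axis (z)
#'   applied first, then about a horizontal (x) axis.
#' * `gimbal_horizontal_first` — the horizontal-axis rotation applied first.
#'
#' The gimbal conventions carry "false torsion" of the order of degrees for
#' oblique targets, which is what a simulation that moves a fixation axis by
#' successive azimuth/elevation rotations realizes.
#'
#' @param tag One of the four convention tags.
#' @param refine_for_O_translation If `TRUE`, iterate the construction so the
#'   rotated visual axis passes through the target to 1e-6 cm, compensating
#'   for the small translation of the optical center (it rides on a sphere of
#'   radius `|O - C|` about the rotation center).
#' @return An object of class `"gaze_convention"`.
#' @export
gaze_convention <- function(tag = "fixation_geodesic",
                            refine_for_O_translation = FALSE) {
  tag <- match.arg(tag, gaze_convention_tags())
  structure(list(tag = tag,
                 refine_for_O_translation = isTRUE(refine_for_O_translation)),
            class = "gaze_convention")
}

#' @rdname gaze_convention
#' @export
gaze_convention_tags <- function() {
  c("fixation_geodesic", "visual_geodesic",
    "gimbal_vertical_first", "gimbal_horizontal_first")
}

as_gaze_convention <- function(x) {
  if (inherits(x, "gaze_convention")) return(x)
  gaze_convention(x)
}

#' Rotation vector between two fixation axes
#'
#' The single rotation about `C` that carries the fixation axis through
#' `F_from` onto the one through `F_to`: angle between `F_from - C` and
#' `F_to - C`, axis their normalized cross product.
#'
#' @param C Rotation center, cm.
#' @param F_from,F_to Old and new fixation points, cm.
#' @return A rotation vector; zero if the two axes already coincide.
#' @export
fixation_axis_rv <- function(C, F_from, F_to) {
  C <- check_vec3(C, "C")
  v_a <- check_vec3(F_from, "F_from") - C
  v_1 <- check_vec3(F_to, "F_to") - C
  if (norm3(v_a) < 1e-9 || norm3(v_1) < 1e-9) {
    stop("fixation point coincides with the rotation center", call. = FALSE)
  }
  cr <- cross3(v_a, v_1)
  s <- norm3(cr)
  d <- sum(v_a * v_1)
  psi <- atan2(s, d)
  if (s / (norm3(v_a) * norm3(v_1)) < 1e-12) {
    if (d > 0) return(c(0, 0, 0))
    stop("F_from, C, F_to are collinear with opposite gaze directions: axis undefined",
         call. = FALSE)
  }
  tan(psi / 2) * (cr / s)
}

# solve R = Rx(B) %*% Rz(A) mapping unit u0 to unit u1 (vertical-axis
# rotation applied first); returns the rotation vector
gimbal_vf_rv <- function(u0, u1) {
  r_xy <- sqrt(u0[1]^2 + u0[2]^2)
  if (r_xy < 1e-12 || abs(u1[1]) > r_xy) {
    stop("target unreachable under the vertical-first gimbal convention", call. = FALSE)
  }
  # (Rz(A) u0)_x = u1_x, preserved by the subsequent x-rotation
  A <- atan2(u0[1], u0[2]) - asin(u1[1] / r_xy)
  rz <- tan(A / 2) * c(0, 0, 1)
  w <- rv_apply(rz, u0)
  B <- atan2(u1[3], u1[2]) - atan2(w[3], w[2])
  rx <- tan(B / 2) * c(1, 0, 0)
  rv_compose(rx, rz)
}

# solve R = Rz(A) %*% Rx(B) (horizontal-axis rotation applied first)
gimbal_hf_rv <- function(u0, u1) {
  r_yz <- sqrt(u0[2]^2 + u0[3]^2)
  if (r_yz < 1e-12 || abs(u1[3]) > r_yz) {
    stop("target unreachable under the horizontal-first gimbal convention", call. = FALSE)
  }
  B <- asin(u1[3] / r_yz) - atan2(u0[3], u0[2])
  rx <- tan(B / 2) * c(1, 0, 0)
  w <- rv_apply(rx, u0)
  A <- atan2(u1[2], u1[1]) - atan2(w[2], w[1])
  rz <- tan(A / 2) * c(0, 0, 1)
  rv_compose(rz, rx)
}

full_rotation_for_target <- function(eye, target, convention, fa) {
  C <- eye$rotation_center
  O <- eye$optical_center
  switch(convention$tag,
    fixation_geodesic = fixation_axis_rv(C, fa, target),
    visual_geodesic = {
      r <- geodesic_rv(unit3(fa - O), unit3(target - O))
      if (convention$refine_for_O_translation) {
        for (iter in 1:50) {
          O_prime <- C + rv_apply(r, O - C)
          r_new <- geodesic_rv(unit3(fa - O), unit3(target - O_prime))
          if (max(abs(r_new - r)) < 1e-12) { r <- r_new; break }
          r <- r_new
        }
      }
      r
    },
    gimbal_vertical_first = gimbal_vf_rv(unit3(fa - C), unit3(target - C)),
    gimbal_horizontal_first = gimbal_hf_rv(unit3(fa - C), unit3(target - C))
  )
}

#' Rotate one eye to a new fixation target
#'
#' Computes the full rigid rotation (about the eye's rotation center) that
#' redirects the gaze from the resting fixation to `target` under the chosen
#' convention, and applies it to the orientation frame, the optical center,
#' and the nodal point.
#'
#' @param eye An `"erp_eye"` from [build_erp()].
#' @param target Fixation target, cm.
#' @param convention A [gaze_convention()] or its tag.
#' @param fa Resting fixation point (defaults must be supplied by the caller
#'   via [binocular_fixate()]; this low-level interface takes it explicitly).
#' @param warn_envelope Warn if the rotation exceeds 60 degrees (the stated
#'   validity envelope of the model); rotations of 90 degrees or more are
#'   rejected.
#' @return An object of class `"eye_posture"`: fields `target`,
#'   `full_rotation`, `frame` (`a_vec`, `b_vec`, `c_vec`), `o_prime`,
#'   `n_prime`, `side`, `convention`.
#' @export
rotate_eye_to_target <- function(eye, target, convention = "fixation_geodesic",
                                 fa, warn_envelope = TRUE) {
  stopifnot(inherits(eye, "erp_eye"))
  target <- check_vec3(target, "target")
  fa <- check_vec3(fa, "fa")
  convention <- as_gaze_convention(convention)
  if (norm3(target - eye$optical_center) < 1e-9) {
    stop("target coincides with the optical center", call. = FALSE)
  }
  r <- full_rotation_for_target(eye, target, convention, fa)
  theta <- rv_angle(r)
  if (theta >= 90) {
    stop(sprintf("rotation of %.1f degrees is outside the supported range (< 90)", theta),
         call. = FALSE)
  }
  if (warn_envelope && theta > 60) {
    warning(sprintf("rotation of %.1f degrees exceeds the 60-degree validity envelope", theta))
  }
  R <- rv_to_matrix(r)
  C <- eye$rotation_center
  structure(list(
    side = eye$side,
    target = target,
    full_rotation = r,
    frame = list(a_vec = as.numeric(R %*% eye$frame$i),
                 b_vec = as.numeric(R %*% eye$frame$j),
                 c_vec = as.numeric(R %*% eye$frame$k)),
    o_prime = C + as.numeric(R %*% (eye$optical_center - C)),
    n_prime = C + as.numeric(R %*% (eye$nodal_point - C)),
    convention = convention$tag
  ), class = "eye_posture")
}

#' @export
print.eye_posture <- function(x, ...) {
  cat(sprintf("<eye_posture: %s eye -> (%.2f, %.2f, %.2f), %s, %.3f deg>\n",
              x$side, x$target[1], x$target[2], x$target[3],
              x$convention, rv_angle(x$full_rotation)))
  invisible(x)
}

#' Binocular fixation on a target
#'
#' Rotates both eyes from the resting posture to the same target so that
#' bifoveal fixation is preserved.
#'
#' @param erp A `"binocular_erp"`.
#' @param target Fixation target, cm.
#' @param convention A [gaze_convention()] or tag; defaults to the one stored
#'   in the configuration.
#' @param ... Passed to [rotate_eye_to_target()].
#' @return A list with elements `right` and `left` (class `"eye_posture"`).
#' @export
binocular_fixate <- function(erp, target, convention = NULL, ...) {
  stopifnot(inherits(erp, "binocular_erp"))
  convention <- as_gaze_convention(convention %||% erp$config$convention)
  list(right = rotate_eye_to_target(erp$right, target, convention, erp$fixation, ...),
       left = rotate_eye_to_target(erp$left, target, convention, erp$fixation, ...))
}

#' Displacement of the optical center under a posture change
#'
#' The optical center rides on a sphere of radius `|O - C|` about the rotation
#' center; a rotation by `theta` displaces it by `2 sin(theta/2)` times its
#' distance from the rotation axis, which `|O - C|` bounds from above — below
#' 0.03 cm for rotations under 60 degrees with the default geometry.
#'
#' @param eye The `"erp_eye"` the posture started from.
#' @param posture An `"eye_posture"`.
#' @return Displacement in cm.
#' @export
optical_center_displacement <- function(eye, posture) {
  stopifnot(inherits(eye, "erp_eye"), inherits(posture, "eye_posture"))
  norm3(posture$o_prime - eye$optical_center)
}

#' Posture from an explicit rotation
#'
#' Applies a given rotation vector to a resting eye (about its rotation
#' center), bypassing any gaze convention.  Useful for constructing arbitrary
#' postures, e.g. in property checks of the torsion decomposition.
#'
#' @param eye An `"erp_eye"`.
#' @param r Rotation vector to apply.
#' @param target Optional fixation target to record in the posture; defaults
#'   to the rotated image of a point 100 cm along the resting visual axis.
#' @return An `"eye_posture"`.
#' @export
posture_from_rotation <- function(eye, r, target = NULL) {
  stopifnot(inherits(eye, "erp_eye"))
  r <- check_vec3(r, "r")
  R <- rv_to_matrix(r)
  C <- eye$rotation_center
  if (is.null(target)) {
    ahead <- eye$optical_center + 100 * eye$frame$j
    target <- C + as.numeric(R %*% (ahead - C))
  }
  structure(list(
    side = eye$side,
    target = check_vec3(target, "target"),
    full_rotation = r,
    frame = list(a_vec = as.numeric(R %*% eye$frame$i),
                 b_vec = as.numeric(R %*% eye$frame$j),
                 c_vec = as.numeric(R %*% eye$frame$k)),
    o_prime = C + as.numeric(R %*% (eye$optical_center - C)),
    n_prime = C + as.numeric(R %*% (eye$nodal_point - C)),
    convention = "explicit"
  ), class = "eye_posture")
}
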