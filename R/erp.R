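# Binocular resting-posture (ERP) geometry.
#
# Head frame: +x rightward, +y anterior (toward the scene), +z up; units are
# centimeters and degrees throughout.  In the resting posture both image
# planes coincide with the head frontal plane y = 0, the lens equatorial
# planes are parallel to them, and the frames attached at the optical centers
# agree with the head axes.

#' Misalignment angles of the model eye
#'
#' The reduced eye used here has its fovea displaced from the posterior pole
#' (horizontal angle `alpha`, vertical `gamma`, measured at the rotation
#' center) and its crystalline lens tilted away from the optical axis
#' (horizontal `beta`, vertical `epsilon`).  Defaults are the typical values
#' in the human population.
#'
#' @param alpha_deg Fovea horizontal displacement (degrees).
#' @param beta_deg Lens horizontal tilt (degrees); values in roughly
#'   \[-0.4, 4.7\] are physiological.
#' @param gamma_deg Fovea vertical displacement (degrees).
#' @param epsilon_deg Lens vertical tilt (degrees).
#' @return A named list of class `"misalignment_angles"`.
#' @export
misalignment_angles <- function(alpha_deg = 5.2, beta_deg = 3.3,
                                gamma_deg = -2, epsilon_deg = -1) {
  ang <- list(alpha_deg = alpha_deg, beta_deg = beta_deg,
              gamma_deg = gamma_deg, epsilon_deg = epsilon_deg)
  for (nm in names(ang)) {
    v <- ang[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || abs(v) > 15) {
      stop(sprintf("%s must be a single angle in [-15, 15] degrees", nm),
           call. = FALSE)
    }
  }
  structure(ang, class = "misalignment_angles")
}

#' Binocular geometry configuration
#'
#' Bundles everything needed to construct the eyes' resting posture: the
#' interocular half-distance, the nodal-point distance, the misalignment
#' angles (mirror-symmetric between the eyes), the resting-posture binocular
#' fixation point `Fa`, the gaze-rotation convention, and numeric tolerances.
#'
#' `Fa` is an input, not derived: it is the fixation at the abathic distance
#' (about 1 m for the default angles) at which both image planes are frontal,
#' and its closed form in terms of the misalignment angles is outside the
#' scope of this package.
#'
#' @param a_cm Interocular half-distance in cm (rotation centers at
#'   `(+-a, 0, 0)`).
#' @param nodal_cm Distance from the rotation center to the nodal point along
#'   the eye's optical axis, in cm.
#' @param angles A [misalignment_angles()] object (or arguments passed on).
#' @param fa_cm Resting-posture fixation point, cm, with `fa_cm[2] > 0`.
#' @param convention Gaze-rotation convention tag, see [gaze_convention()].
#' @param tilt_sign `+1` (default) tilts the right eye's optical axis
#'   temporally (+x) for `beta_deg > 0`; `-1` flips the horizontal tilt for
#'   sensitivity analysis.
#' @param tolerance Absolute tolerance for unit/orthogonality checks.
#' @return An object of class `"binocular_config"`.
#' @examples
#' cfg <- binocular_config()
#' erp <- build_erp(cfg)
#' @export
binocular_config <- function(a_cm = 3.25, nodal_cm = 0.6,
                             angles = misalignment_angles(),
                             fa_cm = c(0, 99.56, 1.72),
                             convention = "fixation_geodesic",
                             tilt_sign = 1,
                             tolerance = 1e-9) {
  stopifnot(inherits(angles, "misalignment_angles"))
  if (!is.numeric(a_cm) || a_cm <= 0) stop("a_cm must be > 0", call. = FALSE)
  if (!is.numeric(nodal_cm) || nodal_cm <= 0) stop("nodal_cm must be > 0", call. = FALSE)
  fa_cm <- check_vec3(fa_cm, "fa_cm")
  if (fa_cm[2] <= 0) stop("fa_cm must lie in front of the head (y > 0)", call. = FALSE)
  if (!tilt_sign %in% c(-1, 1)) stop("tilt_sign must be +1 or -1", call. = FALSE)
  convention <- match.arg(convention, gaze_convention_tags())
  structure(list(a_cm = a_cm, nodal_cm = nodal_cm, angles = angles,
                 fa_cm = fa_cm, convention = convention,
                 tilt_sign = tilt_sign, tolerance = tolerance),
            class = "binocular_config")
}

#' @export
print.binocular_config <- function(x, ...) {
  cat("<binocular_config>\n")
  cat(sprintf("  a = %.3f cm, nodal distance = %.2f cm\n", x$a_cm, x$nodal_cm))
  cat(sprintf("  angles: alpha = %.2f, beta = %.2f, gamma = %.2f, epsilon = %.2f deg\n",
              x$angles$alpha_deg, x$angles$beta_deg,
              x$angles$gamma_deg, x$angles$epsilon_deg))
  cat(sprintf("  Fa = (%.2f, %.2f, %.2f) cm\n", x$fa_cm[1], x$fa_cm[2], x$fa_cm[3]))
  cat(sprintf("  convention = %s\n", x$convention))
  invisible(x)
}

# optical-axis direction of one eye in the resting posture: the unit vector
# from the rotation center toward the nodal point, tilted from straight-ahead
# j by the lens tilts (beta about z toward the temporal side, epsilon about x)
erp_optical_axis_dir <- function(beta_deg, epsilon_deg, side, tilt_sign = 1) {
  b <- deg2rad(beta_deg) * tilt_sign
  e <- deg2rad(epsilon_deg)
  # Rx(epsilon) %*% Rz(-beta) %*% (0,1,0), right eye; mirrored in x for left
  u <- c(sin(b), cos(b) * cos(e), cos(b) * sin(e))
  if (side == "left") u[1] <- -u[1]
  u
}

build_erp_eye <- function(side, config) {
  a <- config$a_cm
  C <- c(if (side == "right") a else -a, 0, 0)
  u_hat <- erp_optical_axis_dir(config$angles$beta_deg, config$angles$epsilon_deg,
                                side, config$tilt_sign)
  N <- C + config$nodal_cm * u_hat
  n_foot <- c(N[1], 0, N[3])
  Fa <- config$fa_cm
  dy <- Fa[2] - N[2]
  if (abs(dy) < config$tolerance) {
    stop("line through the nodal point and Fa is parallel to the image plane: degenerate configuration",
         call. = FALSE)
  }
  # visual axis: through the nodal point and Fa; the optical center is its
  # intersection with the image plane y = 0
  t <- N[2] / (N[2] - Fa[2])
  O <- N + t * (Fa - N)
  structure(list(side = side,
                 rotation_center = C,
                 optical_axis_dir = u_hat,
                 nodal_point = N,
                 lens_axis_foot = n_foot,
                 optical_center = O,
                 frame = list(i = c(1, 0, 0), j = c(0, 1, 0), k = c(0, 0, 1))),
            class = "erp_eye")
}

#' Construct the binocular eyes' resting posture
#'
#' Places the rotation centers at `(+-a, 0, 0)`, tilts each eye's optical axis
#' by the lens misalignment angles, puts the nodal point `nodal_cm` along that
#' axis, projects it perpendicularly onto the image plane `y = 0` (foot of the
#' lens optical axis), and intersects the visual axis (nodal point to `Fa`)
#' with the image plane to obtain the optical center where the orientation
#' frame is attached.  The left eye is the mirror image of the right through
#' the midsagittal plane `x = 0`.
#'
#' @param config A [binocular_config()].
#' @return An object of class `"binocular_erp"` with elements `right`, `left`
#'   (class `"erp_eye"`), `fixation`, and `config`.
#' @export
build_erp <- function(config = binocular_config()) {
  stopifnot(inherits(config, "binocular_config"))
  structure(list(right = build_erp_eye("right", config),
                 left = build_erp_eye("left", config),
                 fixation = config$fa_cm,
                 config = config),
            class = "binocular_erp")
}

#' @export
print.binocular_erp <- function(x, ...) {
  cat("<binocular_erp>\n")
  for (s in c("right", "left")) {
    e <- x[[s]]
    cat(sprintf("  %-5s C = (% .3f, % .3f, % .3f)  O = (% .4f, % .4f, % .4f)\n",
                s, e$rotation_center[1], e$rotation_center[2], e$rotation_center[3],
                e$optical_center[1], e$optical_center[2], e$optical_center[3]))
  }
  cat(sprintf("  Fa = (%.2f, %.2f, %.2f) cm;  |O - n| = %.4f cm (right)\n",
              x$fixation[1], x$fixation[2], x$fixation[3],
              norm3(x$right$optical_center - x$right$lens_axis_foot)))
  invisible(x)
}

#' Tidy summary of a resting posture
#'
#' One row per eye with the constructed points and the optical-center offsets.
#'
#' @param x A `"binocular_erp"` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy binocular_erp
#' @export
tidy.binocular_erp <- function(x, ...) {
  purrr::map_dfr(c("right", "left"), function(s) {
    e <- x[[s]]
    tibble::tibble(
      eye = s,
      c_x = e$rotation_center[1], c_y = e$rotation_center[2], c_z = e$rotation_center[3],
      n_x = e$nodal_point[1], n_y = e$nodal_point[2], n_z = e$nodal_point[3],
      o_x = e$optical_center[1], o_y = e$optical_center[2], o_z = e$optical_center[3],
      o_to_lens_foot_cm = norm3(e$optical_center - e$lens_axis_foot),
      o_to_c_cm = norm3(e$optical_center - e$rotation_center)
    )
  })
}

axis_line <- function(point, fixation, what) {
  d <- fixation - point
  if (norm3(d) < 1e-9) {
    stop(sprintf("fixation coincides with the %s origin: direction undefined", what),
         call. = FALSE)
  }
  list(point = point, dir = unit3(d))
}

#' Visual and fixation axes of an eye
#'
#' The visual axis runs through the optical center (and nodal point) and the
#' fixation point; the fixation axis runs through the rotation center and the
#' fixation point.  Both are returned as `(point, unit direction)` pairs.
#'
#' @param eye An `"erp_eye"`.
#' @param fixation Fixation point, cm.
#' @return A list with elements `point` and `dir`.
#' @export
visual_axis <- function(eye, fixation) {
  stopifnot(inherits(eye, "erp_eye"))
  axis_line(eye$optical_center, check_vec3(fixation, "fixation"), "visual axis")
}

#' @rdname visual_axis
#' @export
fixation_axis <- function(eye, fixation) {
  stopifnot(inherits(eye, "erp_eye"))
  axis_line(eye$rotation_center, check_vec3(fixation, "fixation"), "fixation axis")
}

#' Deviation of the resting gaze from perpendicularity
#'
#' The angle between the image-plane normal `j` and the fixation axis through
#' `Fa`.  In a classical single-eye description this would be zero (the
#' primary direction is perpendicular to the displacement plane); with
#' misaligned optics it is about 2.1 degrees for the default angles.
#'
#' @param erp A `"binocular_erp"`.
#' @param eye `"right"` or `"left"`.
#' @return Angle in degrees.
#' @export
erp_perpendicularity_deviation <- function(erp, eye = "right") {
  stopifnot(inherits(erp, "binocular_erp"))
  e <- erp[[match.arg(eye, c("right", "left"))]]
  angle_between(e$frame$j, erp$fixation - e$rotation_center)
}
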