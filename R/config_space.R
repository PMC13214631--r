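# Configuration-space algebra of fixation sequences.
#
# A posture change is the pair sigma = (r, q): torsion-free and torsional
# rotation vectors.  Pairs compose componentwise, from right to left, and a
# labelled chain of fixations telescopes to the direct change between its
# endpoints.

#' Posture-change element of the configuration space
#'
#' An element referenced to the resting posture has its torsion-free axis in
#' the plane `y = 0`; a transfer element between tertiary postures generally
#' does not (the set of in-plane rotation vectors is not closed under
#' composition), so only the torsional part's axis is constrained here.
#'
#' @param r Torsion-free rotation vector.
#' @param q Torsional rotation vector (parallel to `(0, 1, 0)`).
#' @param from,to Fixation labels (strings); used to guard composition.
#' @return An object of class `"posture_change"`.
#' @export
posture_change <- function(r, q, from = NA_character_, to = NA_character_) {
  r <- check_vec3(r, "r")
  q <- check_vec3(q, "q")
  if (abs(q[1]) > 1e-9 || abs(q[3]) > 1e-9) {
    stop("torsional part must be parallel to (0, 1, 0)", call. = FALSE)
  }
  structure(list(r = r, q = q, from = as.character(from), to = as.character(to)),
            class = "posture_change")
}

#' @export
print.posture_change <- function(x, ...) {
  cat(sprintf("<posture_change %s -> %s: r = (%.5f, %.5f, %.5f), q_y = %.5f>\n",
              x$from, x$to, x$r[1], x$r[2], x$r[3], x$q[2]))
  invisible(x)
}

#' Posture change from a torsion decomposition
#'
#' @param dec A `"torsion_decomposition"`.
#' @param from,to Fixation labels.
#' @export
as_posture_change <- function(dec, from = "Fa", to = "F") {
  stopifnot(inherits(dec, "torsion_decomposition"))
  posture_change(dec$r, dec$q, from = from, to = to)
}

#' Compose posture changes componentwise
#'
#' `(r'', q'') o (r', q') = (r'' o r', q'' o q')` — the torsion-free and
#' torsional parts compose independently.  The inner element is applied first,
#' so its destination must be the outer element's origin (checked unless
#' `check_labels = FALSE`).  Note that this componentwise product is the
#' defined configuration-space operation; it is not the decomposition of the
#' composed physical rotation (see [sigma_coupling_gap()]).
#'
#' @param outer,inner `"posture_change"` objects.
#' @param check_labels Enforce chainable labels.
#' @export
sigma_compose <- function(outer, inner, check_labels = TRUE) {
  stopifnot(inherits(outer, "posture_change"), inherits(inner, "posture_change"))
  if (check_labels && !is.na(outer$from) && !is.na(inner$to) &&
      outer$from != inner$to) {
    stop(sprintf("labels not chainable: outer starts at '%s' but inner ends at '%s'",
                 outer$from, inner$to), call. = FALSE)
  }
  posture_change(rv_compose(outer$r, inner$r),
                 rv_compose(outer$q, inner$q),
                 from = inner$from, to = outer$to)
}

#' Reverse a posture change
#'
#' The inverse element: `(-r, -q)` with the labels swapped.
#'
#' @param sigma A `"posture_change"`.
#' @export
sigma_reversal <- function(sigma) {
  stopifnot(inherits(sigma, "posture_change"))
  posture_change(rv_inverse(sigma$r), rv_inverse(sigma$q),
                 from = sigma$to, to = sigma$from)
}

#' Coupling between componentwise composition and the physical rotation
#'
#' The componentwise product of two posture changes is not, in general, the
#' torsion decomposition of the composed full rotation: composing two
#' rotations whose axes lie in the plane `y = 0` generically produces an axis
#' with a nonzero `y` component.  This diagnostic quantifies the discrepancy:
#' it reconstructs each full rotation as `rv_compose(r, q)`, composes them physically,
#' re-decomposes about `j`, and returns the rotation vectors taking the
#' componentwise parts onto the re-decomposed parts.
#'
#' @param outer,inner `"posture_change"` objects.
#' @return A list with `r_gap`, `q_gap` (rotation vectors; zero when the
#'   componentwise and physical compositions agree) and the re-decomposed
#'   `r_phys`, `q_phys`.
#' @export
sigma_coupling_gap <- function(outer, inner) {
  cw <- sigma_compose(outer, inner, check_labels = FALSE)
  full <- rv_compose(rv_compose(outer$r, outer$q),
                     rv_compose(inner$r, inner$q))
  j <- c(0, 1, 0)
  b <- rv_apply(full, j)
  r_phys <- geodesic_rv(j, b)
  q_phys <- rv_compose(rv_inverse(r_phys), full)
  list(r_gap = rv_compose(r_phys, rv_inverse(cw$r)),
       q_gap = rv_compose(q_phys, rv_inverse(cw$q)),
       r_phys = r_phys, q_phys = q_phys)
}

#' Reduce a fixation path to its net posture change
#'
#' Builds, for each fixation in the path, the posture change from the resting
#' fixation (identity for the resting fixation itself), forms the per-leg
#' transfer elements, composes them right to left, and returns the net change
#' per eye together with the direct change between the endpoints.  The two
#' agree identically (telescoping): every leg is referenced to the resting
#' posture, so intermediate fixations cancel.
#'
#' @param fixations A data frame (or tibble) with columns `id`, `x_cm`,
#'   `y_cm`, `z_cm` and at least two rows, in path order.  Use the id `"Fa"`
#'   (or coordinates equal to the resting fixation) for the resting fixation.
#' @param erp A `"binocular_erp"`.
#' @param convention Gaze convention tag or object.
#' @return A list with per-eye elements `right`, `left`, each containing
#'   `net` (composed along the path), `direct` (first to last fixation), and
#'   `legs` (list of per-leg `"posture_change"` objects).
#' @export
path_reduce <- function(fixations, erp, convention = NULL) {
  stopifnot(inherits(erp, "binocular_erp"))
  fixations <- as.data.frame(fixations)
  req <- c("id", "x_cm", "y_cm", "z_cm")
  if (!all(req %in% names(fixations)) || nrow(fixations) < 2) {
    stop("fixations must have columns id, x_cm, y_cm, z_cm and at least 2 rows",
         call. = FALSE)
  }
  convention <- as_gaze_convention(convention %||% erp$config$convention)
  ids <- as.character(fixations$id)
  pts <- lapply(seq_len(nrow(fixations)),
                function(i) c(fixations$x_cm[i], fixations$y_cm[i], fixations$z_cm[i]))

  per_eye <- function(side) {
    eye <- erp[[side]]
    base <- lapply(seq_along(pts), function(i) {
      if (norm3(pts[[i]] - erp$fixation) < 1e-9) {
        posture_change(c(0, 0, 0), c(0, 0, 0), from = "Fa", to = ids[i])
      } else {
        p <- rotate_eye_to_target(eye, pts[[i]], convention, erp$fixation)
        as_posture_change(decompose_posture(p, eye), from = "Fa", to = ids[i])
      }
    })
    legs <- lapply(seq_len(length(base) - 1L), function(i) {
      tr <- sigma_compose(base[[i + 1L]], sigma_reversal(base[[i]]),
                          check_labels = FALSE)
      posture_change(tr$r, tr$q, from = ids[i], to = ids[i + 1L])
    })
    net <- Reduce(function(acc, leg) sigma_compose(leg, acc), legs[-1], legs[[1]])
    direct <- sigma_compose(base[[length(base)]], sigma_reversal(base[[1L]]),
                            check_labels = FALSE)
    direct <- posture_change(direct$r, direct$q,
                             from = ids[1L], to = ids[length(ids)])
    list(net = net, direct = direct, legs = legs)
  }

  list(right = per_eye("right"), left = per_eye("left"))
}
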