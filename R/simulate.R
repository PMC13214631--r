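# Tabular simulation surface: target lists in, per-eye/per-fixation tables out.

#' Named fixation fixtures
#'
#' The three fixation points used throughout the worked examples: the resting
#' fixation `Fa` and the two tertiary targets `F1`, `F2`.
#'
#' @return A tibble with columns `id`, `x_cm`, `y_cm`, `z_cm`.
#' @export
target_fixtures <- function() {
  tibble::tibble(
    id = c("Fa", "F1", "F2"),
    x_cm = c(0, 15, 10),
    y_cm = c(99.56, 29.56, 49.56),
    z_cm = c(1.72, 7.72, 12.72)
  )
}

#' Generate a grid of fixation targets
#'
#' Draws `n` targets uniformly in gaze azimuth, elevation, and distance
#' (measured from the head origin), deterministically for a fixed seed.  The
#' named fixtures `F1` and `F2` are appended when `include_fixtures = TRUE`.
#'
#' @param n Number of random targets.
#' @param az_range,el_range Azimuth/elevation ranges in degrees (kept within
#'   the model's < 60 degree validity envelope).
#' @param dist_range Distance range in cm.
#' @param seed Integer seed; the global RNG state is left untouched.
#' @param include_fixtures Append the named `F1`/`F2` fixtures.
#' @return A tibble with columns `id`, `x_cm`, `y_cm`, `z_cm`.
#' @export
generate_target_grid <- function(n = 20, az_range = c(-40, 40),
                                 el_range = c(-20, 20),
                                 dist_range = c(25, 100),
                                 seed = 1L, include_fixtures = TRUE) {
  stopifnot(length(az_range) == 2, length(el_range) == 2, length(dist_range) == 2)
  if (diff(az_range) < 0 || diff(el_range) < 0 || diff(dist_range) <= 0) {
    stop("ranges must be non-decreasing (distance strictly)", call. = FALSE)
  }
  if (max(abs(c(az_range, el_range))) >= 60) {
    stop("target grid must stay within the 60-degree validity envelope", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  az <- deg2rad(stats::runif(n, az_range[1], az_range[2]))
  el <- deg2rad(stats::runif(n, el_range[1], el_range[2]))
  d <- stats::runif(n, dist_range[1], dist_range[2])
  out <- tibble::tibble(
    id = sprintf("T%02d", seq_len(n)),
    x_cm = d * cos(el) * sin(az),
    y_cm = d * cos(el) * cos(az),
    z_cm = d * sin(el)
  )
  if (include_fixtures) {
    out <- dplyr::bind_rows(out, dplyr::filter(target_fixtures(), .data$id != "Fa"))
  }
  out
}

#' Simulate binocular fixations over a target table
#'
#' Rotates both eyes from the resting posture to each target, decomposes each
#' posture change into torsion-free and torsional parts, and returns one row
#' per eye per target.
#'
#' @param targets A data frame with columns `id`, `x_cm`, `y_cm`, `z_cm`.
#' @param config A [binocular_config()].
#' @param convention Gaze convention tag or [gaze_convention()]; defaults to
#'   the configuration's.
#' @return A tibble of class `"listing_sim"` with columns `fixation_id`,
#'   `eye`, `phi_deg`, `tau_deg`, `n_axis_x/y/z`, `r_x/y/z`, `q_y`,
#'   `o_prime_x/y/z`, plus the target coordinates.
#' @examples
#' sim <- simulate_fixations(target_fixtures())
#' dplyr::filter(sim, eye == "right")
#' @export
simulate_fixations <- function(targets, config = binocular_config(),
                               convention = NULL) {
  stopifnot(inherits(config, "binocular_config"))
  targets <- tibble::as_tibble(targets)
  req <- c("id", "x_cm", "y_cm", "z_cm")
  if (!all(req %in% names(targets))) {
    stop("targets must have columns id, x_cm, y_cm, z_cm", call. = FALSE)
  }
  erp <- build_erp(config)
  convention <- as_gaze_convention(convention %||% config$convention)
  rows <- purrr::pmap_dfr(
    targets[req],
    function(id, x_cm, y_cm, z_cm) {
      tgt <- c(x_cm, y_cm, z_cm)
      purrr::map_dfr(c("right", "left"), function(side) {
        eye <- erp[[side]]
        if (norm3(tgt - erp$fixation) < 1e-9) {
          dec_row <- tibble::tibble(eye = side, phi_deg = 0, tau_deg = 0,
                                    n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
                                    r_x = 0, r_y = 0, r_z = 0, q_y = 0)
          op <- eye$optical_center
        } else {
          p <- rotate_eye_to_target(eye, tgt, convention, erp$fixation,
                                    warn_envelope = FALSE)
          dec_row <- tidy(decompose_posture(p, eye))
          op <- p$o_prime
        }
        dplyr::mutate(dec_row,
                      fixation_id = id, x_cm = x_cm, y_cm = y_cm, z_cm = z_cm,
                      o_prime_x = op[1], o_prime_y = op[2], o_prime_z = op[3],
                      .before = 1)
      })
    }
  )
  rows <- dplyr::rename(rows, n_axis_x = "n_x", n_axis_y = "n_y", n_axis_z = "n_z")
  class(rows) <- c("listing_sim", class(rows))
  attr(rows, "convention") <- convention$tag
  rows
}

#' Per-fixation torsional disparity table
#'
#' Pivots a simulation table to one row per fixation with right/left torsion
#' and their disparity `tau_r - tau_l`.
#'
#' @param sim A `"listing_sim"` tibble from [simulate_fixations()].
#' @return A tibble with columns `fixation_id`, `tau_r_deg`, `tau_l_deg`,
#'   `delta_t_deg`.
#' @export
disparity_table <- function(sim) {
  stopifnot(is.data.frame(sim), all(c("fixation_id", "eye", "tau_deg") %in% names(sim)))
  wide <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(sim), .data$fixation_id),
    tau_r_deg = .data$tau_deg[.data$eye == "right"][1],
    tau_l_deg = .data$tau_deg[.data$eye == "left"][1],
    .groups = "drop"
  )
  dplyr::mutate(wide,
                delta_t_deg = torsional_disparity(.data$tau_r_deg, .data$tau_l_deg))
}

#' Summary statistics of a simulation table
#'
#' @param x A `"listing_sim"` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of fixations, convention, torsion range.
#' @method glance listing_sim
#' @export
glance.listing_sim <- function(x, ...) {
  tibble::tibble(
    n_fixations = dplyr::n_distinct(x$fixation_id),
    convention = attr(x, "convention") %||% NA_character_,
    max_abs_tau_deg = max(abs(x$tau_deg)),
    max_phi_deg = max(x$phi_deg)
  )
}
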