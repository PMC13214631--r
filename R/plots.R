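# ggplot2 displays for simulation tables and half-angle reports.

#' Plot torsion against gaze eccentricity
#'
#' One point per eye per fixation: torsion-free rotation angle `phi` on the
#' x-axis, signed torsion `tau` on the y-axis.
#'
#' @param object A `"listing_sim"` tibble from [simulate_fixations()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot listing_sim
#' @export
autoplot.listing_sim <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$phi_deg, y = .data$tau_deg,
                               colour = .data$eye)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = "torsion-free rotation angle φ (deg)",
      y = "ocular torsion τ (deg)",
      colour = "eye",
      title = "Ocular torsion across fixation targets",
      subtitle = paste("convention:", attr(object, "convention") %||% "")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the rotation-axis cloud in the resting image plane
#'
#' Torsion-free rotation vectors have their axes in the plane `y = 0` (the
#' binocular substitute for the Listing plane); this shows their x/z
#' components, scaled by the half-angle tangent.
#'
#' @param sim A `"listing_sim"` tibble.
#' @return A ggplot object.
#' @export
plot_listing_plane <- function(sim) {
  stopifnot(is.data.frame(sim), all(c("r_x", "r_z", "eye") %in% names(sim)))
  ggplot2::ggplot(sim, ggplot2::aes(x = .data$r_x, y = .data$r_z,
                                    colour = .data$eye)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "r_x", y = "r_z",
                  title = "Torsion-free rotation vectors in the resting image plane") +
    ggplot2::theme_minimal()
}
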