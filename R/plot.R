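#' Plot a simulation trajectory
#'
#' Two base-graphics panels: population size (occupied sites, with the
#' dikaryotic fraction) and mean mating fitness per nuclear role over
#' generations.
#'
#' @param x a `"dikaryon_sim"` object from [run_simulation()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dikaryon_sim <- function(x, ...) {
  m <- x$metrics
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(m$generation, m$pop_size, type = "l",
                 xlab = "generation", ylab = "occupied sites",
                 main = "population", ...)
  graphics::lines(m$generation, m$pop_size * m$frac_dikaryotic,
                  lty = 2, col = "grey40")
  graphics::legend("bottomleft", bty = "n", lty = c(1, 2),
                   col = c("black", "grey40"),
                   legend = c("total", "dikaryotic"))
  graphics::plot(m$generation, m$mean_wm_role1, type = "l", ylim = c(0, 1),
                 col = "firebrick", xlab = "generation",
                 ylab = "mean w_m", main = "mating fitness by role")
  graphics::lines(m$generation, m$mean_wm_role2, col = "steelblue")
  graphics::lines(m$generation, m$mean_wm_mono, col = "grey50", lty = 2)
  graphics::legend("topright", bty = "n", lty = c(1, 1, 2),
                   col = c("firebrick", "steelblue", "grey50"),
                   legend = c("female (nucleus 1)", "male (nucleus 2)",
                              "monokaryon"))
  invisible(x)
}

#' Ternary scatter of nuclear fitness triples
#'
#' Projects simplex points `(w_v, w_r, w_m)` into the equilateral
#' triangle with corners vegetative (bottom left), reproductive (bottom
#' right) and mating (top), and marks the parasitic corner region
#' `w_m > 2/3`.
#'
#' @param nuclei data frame with `w_v`, `w_r`, `w_m` columns (e.g. from
#'   [nuclei_table()]) or an `n x 3` matrix.
#' @param cex,col point appearance.
#' @param threshold corner-region boundary to draw; `NULL` for none.
#' @param main plot title.
#' @return The projected coordinates, invisibly.
#' @export
plot_ternary <- function(nuclei, cex = 0.2, col = grDevices::grey(0, 0.3),
                         threshold = 2 / 3, main = "") {
  cloud <- ternary_cloud(nuclei)
  pts <- cloud$points
  tx <- pts[, "w_r"] + pts[, "w_m"] / 2
  ty <- pts[, "w_m"] * sqrt(3) / 2
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, sqrt(3) / 2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::polygon(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2))
  graphics::text(c(-0.03, 1.03, 0.5), c(-0.03, -0.03, sqrt(3) / 2 + 0.05),
                 labels = c("w_v", "w_r", "w_m"), xpd = NA)
  if (!is.null(threshold)) {
    h <- threshold * sqrt(3) / 2
    x1 <- threshold / 2 + (1 - threshold)
    graphics::segments(threshold / 2 + (1 - threshold) * 0, h, x1, h,
                       lty = 3, col = "firebrick")
  }
  graphics::points(tx, ty, pch = 16, cex = cex, col = col)
  invisible(cbind(x = tx, y = ty))
}
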