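#' Plot methods
#'
#' `autoplot.fiber_sim` draws the outflow curve (exit rate and cumulative
#' exit); `plot_bound_profile` shows surface-bound ligand along the fiber at
#' selected times; `plot_field` renders a concentration field snapshot;
#' `autoplot.fiber_sweep`-style plots can be built directly from the tidy
#' sweep tables.
#'
#' @param object a `fiber_sim` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fiber_sim <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$outflow[, c("time_s", "exit_rate_ng_per_min", "cumulative_ng")],
    -"time_s", names_to = "series", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          exit_rate_ng_per_min = "exit rate (ng/min)",
                          cumulative_ng = "cumulative exited (ng)"))) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Ligand outflow from the cartridge")
}

#' @rdname autoplot.fiber_sim
#' @param sim a `fiber_sim` object.
#' @param times times (s) to draw; defaults to the last recorded time.
#' @export
plot_bound_profile <- function(sim, times = NULL) {
  d <- sim$surface
  times <- times %||% max(d$time_s)
  keep <- vapply(d$time_s, function(t) any(abs(t - times) < 1e-9), logical(1))
  d <- d[keep, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_m * 100,
                                  y = .data$bound_per_cell,
                                  colour = factor(.data$time_s))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "axial position (cm)", y = "bound ligand (sites/cell)",
                  colour = "time (s)",
                  title = "Surface-bound ligand along the fiber")
}

#' @rdname autoplot.fiber_sim
#' @param time snapshot time (s), or `NULL` for the final field.
#' @export
plot_field <- function(sim, time = NULL) {
  field <- sim$field
  label <- max(sim$ledger$time_s)
  if (!is.null(time)) {
    times <- vapply(sim$snapshots, function(s) s$time, numeric(1))
    k <- which.min(abs(times - time))
    field <- sim$snapshots[[k]]$F
    label <- times[k]
  }
  mw <- sim$config$injection$molecular_weight
  d <- tidyr::expand_grid(
    r_m = (seq_len(nrow(field)) - 0.5) * sim$mesh$dr,
    z_m = (seq_len(ncol(field)) - 0.5) * sim$mesh$dz)
  d$ng_per_mL <- as.vector(t(field)) * mw * 1e9 * 1e-6
  ggplot2::ggplot(d, ggplot2::aes(x = .data$z_m * 100, y = .data$r_m * 1e6,
                                  fill = .data$ng_per_mL)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::labs(x = "axial position (cm)", y = "radius (um)",
                  fill = "ng/mL",
                  title = sprintf("Fluid-phase ligand at t = %g s", label))
}
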