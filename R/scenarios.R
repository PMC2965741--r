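#' Scenario presets
#'
#' Ready-to-run configurations for the package's standard in-silico
#' experiments: single-pass FGF-2 capture with and without HSPG
#' (heparinase), steady versus pulsatile pumping, diffusion-coefficient and
#' flow-rate sensitivity, affinity / density / coupling-constant sweeps, and
#' the zoned fiber whose entrance 25% carries HSPG only (an ECM-like region
#' without internalization).
#'
#' Presets that describe a sweep carry a `sweep` attribute, a list with
#' `param` and `values`, consumable by [sweep_simulations()];
#' [run_preset()] resolves it automatically.
#'
#' @param name one of `preset_names()`.
#' @param front_H0 HSPG density (sites/cell) of the entrance zone for the
#'   zoned-entrance scenarios.
#' @param flow_rate override of the volumetric rate, mL/min, for presets
#'   whose source figure sweeps flow.
#' @return a [fiber_config()], possibly with a `sweep` attribute.
#' @examples
#' preset("fig5_control")
#' attr(preset("fig9_flow_sweep"), "sweep")
#' @export
preset <- function(name, front_H0 = NULL, flow_rate = NULL) {
  cfg <- switch(
    name,
    fig5_control = fiber_config(
      injection = list(amount = 0.92),
      flow = list(volumetric_rate = 0.63, nonspecific_loss_fraction = 0.32)),
    fig5_heparinase = fiber_config(
      injection = list(amount = 0.92),
      flow = list(volumetric_rate = 0.63, nonspecific_loss_fraction = 0.30),
      sites = list(zones = data.frame(z_from = 0, z_to = 1, R0 = 1e4,
                                      H0 = 0, internalize = TRUE))),
    fig6_steady_vs_pulsatile = fiber_config(
      flow = list(volumetric_rate = 0.6)),
    fig7_base = fiber_config(
      flow = list(volumetric_rate = 0.63),
      numerics = list(total_time = 600)),
    fig7_highD = fiber_config(
      flow = list(volumetric_rate = 0.63),
      kinetics = list(D = 1.67e-9),
      numerics = list(total_time = 600)),
    fig9_flow_sweep = structure(
      fiber_config(flow = list(volumetric_rate = 0.63)),
      sweep = list(param = "flow.volumetric_rate",
                   values = c(0.63, 1.8, 3.0))),
    fig10_affinity = structure(
      fiber_config(flow = list(volumetric_rate = 0.63)),
      sweep = list(param = "kinetics.ka_FH",
                   values = 1.2e8 * c(0.1, 0.3, 1, 3, 10))),
    fig11_density = structure(
      fiber_config(flow = list(volumetric_rate = 0.63)),
      sweep = list(param = "sites.zones[1].H0",
                   values = c(2e3, 2e4, 2e5, 2.5e5, 1e6))),
    fig12_coupling = structure(
      fiber_config(flow = list(volumetric_rate = 0.63)),
      sweep = list(param = "kinetics.k_c",
                   values = c(0, 1e-4, 1e-3, 0.1))),
    fig13_zoned = structure(
      fiber_config(
        flow = list(volumetric_rate = 0.65),
        sites = list(zones = data.frame(
          z_from = c(0, 0.25), z_to = c(0.25, 1), R0 = c(0, 1e4),
          H0 = c(2.5e5, 2.5e5), internalize = c(TRUE, TRUE)))),
      sweep = list(param = "flow.volumetric_rate",
                   values = c(0.65, 1.3, 2.6))),
    table6_zone_sweep = structure(
      fiber_config(
        flow = list(volumetric_rate = 0.65),
        sites = list(zones = data.frame(
          z_from = c(0, 0.25), z_to = c(0.25, 1), R0 = c(0, 1e4),
          H0 = c(front_H0 %||% 5e5, 2.5e5),
          internalize = c(FALSE, TRUE)))),
      sweep = list(param = "sites.zones[1].H0",
                   values = c(5e6, 5e5, 5e4))),
    stop("unknown preset: ", name, call. = FALSE))
  if (!is.null(front_H0) && name != "table6_zone_sweep") {
    if (is.null(attr(cfg, "sweep")) || nrow(cfg$sites$zones) < 2)
      stop("front_H0 applies only to zoned presets", call. = FALSE)
    cfg <- set_config_value(cfg, "sites.zones[1].H0", front_H0)
  }
  if (!is.null(flow_rate))
    cfg <- set_config_value(cfg, "flow.volumetric_rate", flow_rate)
  cfg
}

#' @rdname preset
#' @export
preset_names <- function() {
  c("fig5_control", "fig5_heparinase", "fig6_steady_vs_pulsatile",
    "fig7_base", "fig7_highD", "fig9_flow_sweep", "fig10_affinity",
    "fig11_density", "fig12_coupling", "fig13_zoned", "table6_zone_sweep")
}

#' @rdname preset
#' @param ... passed to [run_simulation()] (single runs) or
#'   [sweep_simulations()] (sweep presets).
#' @export
run_preset <- function(name, front_H0 = NULL, flow_rate = NULL, ...) {
  cfg <- preset(name, front_H0 = front_H0, flow_rate = flow_rate)
  sw <- attr(cfg, "sweep")
  if (is.null(sw) || !is.null(front_H0) || !is.null(flow_rate))
    run_simulation(cfg, ...)
  else
    sweep_simulations(cfg, sw$param, sw$values, ...)
}

#' Synthetic experimental outflow curve
#'
#' Generates a deterministic-for-seed noisy unimodal exit curve on a
#' fraction grid, mimicking an ELISA fraction table: a delayed log-normal
#' bolus integrated over fixed-duration fractions with multiplicative
#' measurement noise.  Used to exercise the agreement criteria without lab
#' data.
#'
#' @param delay time before the first ligand exits, s.
#' @param peak_time time of the exit-rate peak (after the delay), s.
#' @param width spread of the exit peak, s.
#' @param total_ng total ligand in the curve, ng.
#' @param noise multiplicative noise standard deviation (0 = noiseless).
#' @param seed RNG seed (required; curves are reproducible by construction).
#' @param n_fractions,fraction_dt fraction grid definition.
#' @return tibble with `time` (fraction end, s) and `ng`.
#' @examples
#' synth_outflow(delay = 40, peak_time = 60, width = 25, total_ng = 0.6,
#'               noise = 0.05, seed = 1)
#' @export
synth_outflow <- function(delay, peak_time, width, total_ng, noise = 0,
                          seed, n_fractions = 40, fraction_dt = 10) {
  stopifnot(total_ng > 0, peak_time > 0, width > 0)
  edges <- seq(0, n_fractions * fraction_dt, by = fraction_dt)
  sdlog <- sqrt(log1p((width / peak_time)^2))
  mu <- log(peak_time)
  cum <- function(t) stats::plnorm(pmax(t - delay, 0), meanlog = mu,
                                   sdlog = sdlog)
  mass <- diff(cum(edges))
  ng <- total_ng * mass / sum(mass)  # noiseless curve integrates exactly
  if (noise > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
    ng <- ng * exp(stats::rnorm(length(ng), sd = noise))
  }
  tibble::tibble(time = edges[-1], ng = ng)
}
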