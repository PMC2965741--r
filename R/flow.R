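#' Axial velocity field
#'
#' Fully developed laminar axial velocity in one fiber.  Steady mode is the
#' Poiseuille profile `2 * u_mean * (1 - r^2/R^2)`.  Pulsatile mode
#' modulates that profile by the nonnegative waveform `1 + sin(omega t)`
#' (`omega = 2 pi * pulse_rate / 60`), whose time average over one pump
#' period is 1, so the period-averaged flux equals the set volumetric rate.
#' The radial profile is quasi-steady: at ~36 strokes/min in a 350 um tube
#' the Womersley number is far below 1, so no radial phase lag is resolved.
#'
#' @param r radial position(s), m, in `[0, R]`.
#' @param t time(s), s.
#' @param config a [fiber_config()].
#' @return axial speed, m/s (vectorized over `r` and `t`).
#' @examples
#' cfg <- fiber_config()
#' axial_velocity(0, 0, cfg)                      # centerline
#' axial_velocity(cfg$geometry$fiber_radius, 0, cfg)  # no-slip wall
#' @export
axial_velocity <- function(r, t, config) {
  R <- config$geometry$fiber_radius
  if (any(r < 0 | r > R)) stop("r must lie in [0, R]", call. = FALSE)
  base <- 2 * mean_velocity(config) * (1 - (r / R)^2)
  if (config$flow$waveform == "pulsatile") {
    omega <- 2 * pi * config$flow$pulse_rate / 60
    base * (1 + sin(omega * t))
  } else {
    base + 0 * t
  }
}

#' Inlet reservoir model
#'
#' The injected ligand mixes instantaneously into the inlet reservoir; a
#' configurable fraction is removed up front as nonspecific loss.  Under
#' pulsatile pumping the reservoir delivers one pulse volume
#' `V_pulse = q_s / pulse_rate` into the fibers per stroke at its current
#' concentration and is then diluted by ligand-free pump fluid:
#' `C_i = C_{i-1} * (V_res - V_pulse) / V_res`.
#'
#' `reservoir_init` builds the initial state; `reservoir_step` applies one
#' delivery + dilution cycle; `inlet_concentration` gives the concentration
#' entering the fibers at time `t` (closed form,
#' `C0 * ((V - Vp)/V)^floor(t / T_pulse)` for the well-mixed mode, a sharp
#' displacement front for the plug mode); `reservoir_timeline` tabulates the
#' first `n_pulses` cycles.
#'
#' @param config a [fiber_config()].
#' @return `reservoir_init`: a list with `concentration` (M), `volume` (L),
#'   `pulses_elapsed`, `cumulative_delivered_ng`.
#' @examples
#' res <- reservoir_init(fiber_config())
#' res2 <- reservoir_step(res, pulse_volume(fiber_config()))
#' res2$concentration / res$concentration  # dilution factor per pulse
#' @export
reservoir_init <- function(config) {
  inj <- config$injection
  amount <- inj$amount * (1 - config$flow$nonspecific_loss_fraction)
  list(concentration = ligand_mass_to_concentration(
         amount, config$geometry$reservoir_volume, inj$molecular_weight),
       volume = config$geometry$reservoir_volume,
       pulses_elapsed = 0L,
       cumulative_delivered_ng = 0,
       molecular_weight = inj$molecular_weight)
}

#' @rdname reservoir_init
#' @param state a reservoir state from [reservoir_init()].
#' @param pulse_volume_L fluid volume delivered this pulse, L.
#' @export
reservoir_step <- function(state, pulse_volume_L) {
  if (pulse_volume_L < 0 || pulse_volume_L >= state$volume)
    stop("pulse volume must lie in [0, reservoir volume)", call. = FALSE)
  delivered_ng <- state$concentration * pulse_volume_L *
    state$molecular_weight * 1e9
  state$cumulative_delivered_ng <- state$cumulative_delivered_ng + delivered_ng
  state$concentration <- state$concentration *
    (state$volume - pulse_volume_L) / state$volume
  state$pulses_elapsed <- state$pulses_elapsed + 1L
  state
}

#' @rdname reservoir_init
#' @param t time since flow start, s.
#' @export
inlet_concentration <- function(t, config) {
  res <- reservoir_init(config)
  q <- config$flow$volumetric_rate * 1e-3 / 60   # L/s
  if (config$reservoir_mode == "plug") {
    return(ifelse(t * q < res$volume, res$concentration, 0))
  }
  # diluted once per pump stroke, independent of the velocity waveform
  vp <- pulse_volume(config)
  n <- floor(t * config$flow$pulse_rate / 60)
  res$concentration * ((res$volume - vp) / res$volume)^n
}

#' @rdname reservoir_init
#' @param n_pulses number of pump cycles to tabulate.
#' @return `reservoir_timeline`: a tibble with one row per pulse
#'   (`pulse`, `time_s`, `concentration_M`, `delivered_ng`,
#'   `remaining_ng`).
#' @export
reservoir_timeline <- function(config, n_pulses) {
  state <- reservoir_init(config)
  vp <- pulse_volume(config)
  rows <- vector("list", n_pulses)
  for (i in seq_len(n_pulses)) {
    new <- reservoir_step(state, vp)
    rows[[i]] <- tibble::tibble(
      pulse = i,
      time_s = i * 60 / config$flow$pulse_rate,
      concentration_M = new$concentration,
      delivered_ng = new$cumulative_delivered_ng - state$cumulative_delivered_ng,
      remaining_ng = new$concentration * new$volume *
        state$molecular_weight * 1e9)
    state <- new
  }
  dplyr::bind_rows(rows)
}

#' Export a velocity-field snapshot
#'
#' @param config a [fiber_config()].
#' @param times time samples, s.
#' @param n_r number of radial samples.
#' @return a tibble with columns `r_m`, `t_s`, `u_m_per_s`.
#' @export
velocity_snapshot <- function(config, times = 0, n_r = 50) {
  r <- seq(0, config$geometry$fiber_radius, length.out = n_r)
  tidyr::expand_grid(r_m = r, t_s = times) |>
    dplyr::mutate(u_m_per_s = axial_velocity(.data$r_m, .data$t_s, config))
}
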