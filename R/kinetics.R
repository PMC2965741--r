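#' Cell-surface binding network
#'
#' Mass-action kinetics of FGF-2 on one wall cell.  The fluid-phase ligand F
#' binds the receptor R (complex C) and the proteoglycan H (complex G);
#' occupied species couple into the ternary complex T via both routes
#' (C + H and G + R, rate `k_c`, reverse `k_uc`); C, G and T each
#' homodimerize with the same coupling constants; T can also lose its ligand
#' to the fluid at the slow ternary off-rate `kd_FHR`, returning free R and
#' H.  Monomeric complexes internalize at `k_int` and dimeric complexes at
#' `k_intD`; internalized sites are not recycled.
#'
#' The state vector has 11 components, in sites (molecules) per cell:
#' `R, H, C, G, C2, G2, T, T2, I, IR, IH` where `I` is cumulative
#' internalized ligand and `IR`/`IH` tally internalized receptor and
#' proteoglycan sites (so the conservation sums
#' `R + C + 2 C2 + T + 2 T2 + IR = R0` and
#' `H + G + 2 G2 + T + 2 T2 + IH = H0` are exact invariants).
#'
#' @param state numeric vector of length 11 (see Details) or the result of
#'   [surface_state()].
#' @param F_wall fluid-phase ligand concentration at the wall, M.
#' @param config a [fiber_config()] supplying the kinetic constants.
#' @param internalize logical; set `FALSE` for ECM-like zones whose bound
#'   ligand is never internalized.
#' @return `reaction_rates`: a list with `deriv` (d/dt of the 11 states,
#'   per minute) and `uptake` (net ligand molecules bound per cell per
#'   minute; negative values release ligand to the fluid).
#' @examples
#' cfg <- fiber_config()
#' s <- surface_state(R0 = 1e4, H0 = 2.5e5)
#' reaction_rates(s, F_wall = 1e-10, cfg)$uptake
#' @export
reaction_rates <- function(state, F_wall, config, internalize = TRUE) {
  state <- as_surface_vec(state)
  if (any(state < 0)) stop("surface state must be nonnegative", call. = FALSE)
  if (F_wall < 0) stop("F_wall must be nonnegative", call. = FALSE)
  out <- cpp_surface_rates(unname(state), F_wall * 1000,
                           solver_kinetics(config), internalize)
  # back to per-minute for bench-unit reporting
  list(deriv = stats::setNames(out$deriv * 60, surface_species()),
       uptake = out$uptake * 60)
}

#' @rdname reaction_rates
#' @param R0,H0 initial free receptor / proteoglycan densities, sites/cell.
#' @export
surface_state <- function(R0 = 1e4, H0 = 2.5e5) {
  stats::setNames(c(R0, H0, rep(0, 9)), surface_species())
}

surface_species <- function() {
  c("R", "H", "C", "G", "C2", "G2", "T", "T2", "I", "IR", "IH")
}

as_surface_vec <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (length(state) != 11)
    stop("surface state must have 11 components", call. = FALSE)
  as.numeric(state)
}

#' Net wall consumption flux of ligand
#'
#' The Robin-type boundary flux seen by the transport equation:
#' net ligand molecules bound per cell per time, scaled by the wall cell
#' areal density and Avogadro's number.
#'
#' @inheritParams reaction_rates
#' @param areal_density wall cells per m^2 (default from `config`).
#' @return flux in mol m^-2 s^-1; positive values remove ligand from the
#'   fluid.
#' @export
wall_flux <- function(state, F_wall, config, internalize = TRUE,
                      areal_density = areal_cell_density(config)) {
  up <- reaction_rates(state, F_wall, config, internalize)$uptake  # per min
  up / 60 * areal_density / 6.02214076e23
}

#' Advance the surface network over a time interval
#'
#' Integrates the stiff surface ODE system with an adaptive embedded
#' Runge-Kutta 4(5) scheme at the configured tolerances (`ode_rtol`,
#' `ode_atol`).  The wall fluid concentration is either held fixed
#' (`depletion_volume = NULL`, the operator-splitting contract used inside
#' the transport solver's unit tests) or co-evolved as a well-mixed local
#' compartment of the given volume, which conserves ligand exactly between
#' the fluid and the surface.
#'
#' @inheritParams reaction_rates
#' @param dt interval, s.
#' @param depletion_volume optional fluid volume (L) per cell from which
#'   bound ligand is drawn; `NULL` freezes `F_wall`.
#' @return a list with `state` (11-vector), `F_wall` (M, unchanged when
#'   frozen) and `n_substeps`.
#' @export
advance_surface <- function(state, F_wall, dt, config, internalize = TRUE,
                            depletion_volume = NULL) {
  state <- as_surface_vec(state)
  if (any(state < 0)) stop("surface state must be nonnegative", call. = FALSE)
  if (dt < 0) stop("dt must be nonnegative", call. = FALSE)
  if (dt == 0)
    return(list(state = stats::setNames(state, surface_species()),
                F_wall = F_wall, n_substeps = 0L))
  conv <- if (is.null(depletion_volume)) 0 else
    1 / (depletion_volume * 1e-3 * 6.02214076e23)  # molecules/cell -> mol/m^3
  out <- cpp_advance_surface(state, F_wall * 1000, dt,
                             solver_kinetics(config), internalize, conv,
                             config$numerics$ode_rtol,
                             config$numerics$ode_atol)
  list(state = stats::setNames(out$state, surface_species()),
       F_wall = out$F / 1000, n_substeps = out$n_substeps)
}

#' Ligand accounting helpers for a surface state
#'
#' `bound_ligand` counts ligand molecules held in surface complexes
#' (`C + G + T + 2*(C2 + G2 + T2)`); `receptor_total` and `hspg_total`
#' return the conservation sums including internalized tallies.
#'
#' @param state an 11-component surface state.
#' @return molecules (or sites) per cell.
#' @export
bound_ligand <- function(state) {
  s <- as_surface_vec(state)
  s[3] + s[4] + s[7] + 2 * (s[5] + s[6] + s[8])
}

#' @rdname bound_ligand
#' @export
receptor_total <- function(state) {
  s <- as_surface_vec(state)
  s[1] + s[3] + 2 * s[5] + s[7] + 2 * s[8] + s[10]
}

#' @rdname bound_ligand
#' @export
hspg_total <- function(state) {
  s <- as_surface_vec(state)
  s[2] + s[4] + 2 * s[6] + s[7] + 2 * s[8] + s[11]
}
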