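#' Simulation configuration
#'
#' Assemble and validate every physical, kinetic and numerical parameter of
#' the hollow-fiber capture model.  Bench units are used at this interface
#' (lengths in metres except where noted, flow in mL/min, rate constants in
#' the per-minute / per-molar units they are usually reported in, site
#' densities in sites per cell); conversion to solver units (SI with surface
#' species in sites/cell) happens once, when a simulation is launched.
#'
#' Kinetic defaults are the base parameter set for FGF-2 on bovine aortic
#' endothelial cells at 25 degrees C; geometry defaults describe a 20-fiber
#' cartridge of 12 cm fibers with 700 um inner diameter carrying 8e5 cells
#' per fiber, fed from a 0.4 mL inlet reservoir.
#'
#' @param geometry,flow,kinetics,sites,injection,numerics named lists
#'   overriding individual defaults; see Details.
#' @param reservoir_mode `"well_mixed"` (per-pulse dilution of the inlet
#'   reservoir by ligand-free pump fluid) or `"plug"` (reservoir contents
#'   displaced undiluted, then ligand-free fluid).
#'
#' @details
#' Sections and fields (defaults in parentheses):
#' * `geometry`: `fiber_radius` m (350e-6), `fiber_length` m (0.12),
#'   `n_fibers` (20), `cells_per_fiber` (8e5), `reservoir_volume` L (4e-4).
#' * `flow`: `volumetric_rate` mL/min (0.63), `waveform`
#'   ("pulsatile"/"steady"), `pulse_rate` strokes/min (36),
#'   `nonspecific_loss_fraction` (0.30).
#' * `kinetics`: `ka_FR` 3.2e8 /M/min, `kd_FR` 0.28 /min, `ka_FH` 1.2e8
#'   /M/min, `kd_FH` 0.56 /min, `k_c` 0.0024 /(sites/cell)/min, `k_uc` 0.6
#'   /min, `kd_FHR` 0.018 /min, `k_int` 0.005 /min, `k_intD` 0.078 /min,
#'   `k_dim`/`k_undim` (`NA`: homodimerization inherits `k_c`/`k_uc`, the
#'   parsimonious default since no separate dimerization constants are
#'   reported; settable for sensitivity analyses),
#'   `v_cell` 4.7e-12 L/cell, `D` 1.67e-10 m^2/s, `mu` 0.00094 Pa s,
#'   `rho_fluid` 1000 kg/m^3.
#' * `sites`: `zones`, a data frame with columns `z_from`, `z_to` (axial
#'   fractions tiling \[0,1\]), `R0`, `H0` (sites/cell) and `internalize`
#'   (logical).  Default is a single zone with `R0 = 1e4`, `H0 = 2.5e5`.
#' * `injection`: `amount` ng (1), `molecular_weight` g/mol (18000),
#'   `start_time` s (0).
#' * `numerics`: `n_r` (50), `n_z` (240), `dt` (NULL: chosen from the
#'   advective/diffusive stability bound with safety 0.5), `pde_tol`
#'   (1e-12), `ode_rtol` (1e-8), `ode_atol` (1e-12), `total_time` s (300).
#'
#' @return An object of class `fiber_config` (a validated nested list).
#' @examples
#' cfg <- fiber_config(flow = list(volumetric_rate = 0.65))
#' mean_velocity(cfg) * 1000  # mm/s
#' @export
fiber_config <- function(geometry = list(), flow = list(), kinetics = list(),
                         sites = list(), injection = list(), numerics = list(),
                         reservoir_mode = c("well_mixed", "plug")) {
  reservoir_mode <- match.arg(reservoir_mode)
  cfg <- default_config()
  cfg$reservoir_mode <- reservoir_mode
  for (sec in c("geometry", "flow", "kinetics", "sites", "injection",
                "numerics")) {
    over <- get(sec)
    if (length(over)) {
      bad <- setdiff(names(over), names(cfg[[sec]]))
      if (length(bad))
        stop("unknown ", sec, " field(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      cfg[[sec]][names(over)] <- over
    }
  }
  if (!is.null(sites$zones)) cfg$sites$zones <- as_zone_table(sites$zones)
  validate_config(cfg)
}

default_config <- function() {
  structure(list(
    geometry = list(fiber_radius = 350e-6, fiber_length = 0.12,
                    n_fibers = 20, cells_per_fiber = 8e5,
                    reservoir_volume = 4e-4),
    flow = list(volumetric_rate = 0.63, waveform = "pulsatile",
                pulse_rate = 36, nonspecific_loss_fraction = 0.30),
    kinetics = list(ka_FR = 3.2e8, kd_FR = 0.28, ka_FH = 1.2e8, kd_FH = 0.56,
                    k_c = 0.0024, k_uc = 0.6, kd_FHR = 0.018, k_int = 0.005,
                    k_intD = 0.078, k_dim = NA_real_, k_undim = NA_real_,
                    v_cell = 4.7e-12, D = 1.67e-10,
                    mu = 0.00094, rho_fluid = 1000),
    sites = list(zones = tibble::tibble(z_from = 0, z_to = 1, R0 = 1e4,
                                        H0 = 2.5e5, internalize = TRUE)),
    injection = list(amount = 1, molecular_weight = 18000, start_time = 0),
    numerics = list(n_r = 50, n_z = 240, dt = NULL, pde_tol = 1e-12,
                    ode_rtol = 1e-8, ode_atol = 1e-12, total_time = 300),
    reservoir_mode = "well_mixed"
  ), class = "fiber_config")
}

as_zone_table <- function(zones) {
  z <- tibble::as_tibble(as.data.frame(zones))
  need <- c("z_from", "z_to", "R0", "H0")
  miss <- setdiff(need, names(z))
  if (length(miss))
    stop("zone table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"internalize" %in% names(z)) z$internalize <- TRUE
  z[order(z$z_from), c(need, "internalize")]
}

#' @rdname fiber_config
#' @param x object to validate / test
#' @export
validate_config <- function(x) {
  stopifnot(inherits(x, "fiber_config"))
  g <- x$geometry
  pos <- function(val, name) {
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0)
      stop("field '", name, "' must be a positive number", call. = FALSE)
  }
  for (f in names(g)) pos(g[[f]], paste0("geometry.", f))
  fl <- x$flow
  pos(fl$volumetric_rate, "flow.volumetric_rate")
  if (!fl$waveform %in% c("pulsatile", "steady"))
    stop("flow.waveform must be 'pulsatile' or 'steady'", call. = FALSE)
  if (fl$waveform == "pulsatile") pos(fl$pulse_rate, "flow.pulse_rate")
  if (fl$nonspecific_loss_fraction < 0 || fl$nonspecific_loss_fraction >= 1)
    stop("flow.nonspecific_loss_fraction must be in [0, 1)", call. = FALSE)
  k <- x$kinetics
  for (f in names(k)) {
    # k_dim / k_undim may be NA, meaning "inherit k_c / k_uc"
    if (f %in% c("k_dim", "k_undim") && length(k[[f]]) == 1 && is.na(k[[f]]))
      next
    if (!is.numeric(k[[f]]) || length(k[[f]]) != 1 || !is.finite(k[[f]]) ||
        k[[f]] < 0)
      stop("field 'kinetics.", f, "' must be a nonnegative number",
           call. = FALSE)
  }
  z <- x$sites$zones <- as_zone_table(x$sites$zones)
  if (any(z$R0 < 0) || any(z$H0 < 0))
    stop("site densities must be nonnegative", call. = FALSE)
  if (abs(z$z_from[1]) > 1e-12 || abs(z$z_to[nrow(z)] - 1) > 1e-12 ||
      (nrow(z) > 1 && any(abs(z$z_from[-1] - z$z_to[-nrow(z)]) > 1e-12)) ||
      any(z$z_to <= z$z_from))
    stop("zone spans must tile [0, 1] exactly without overlap",
         call. = FALSE)
  inj <- x$injection
  pos(inj$amount, "injection.amount")
  pos(inj$molecular_weight, "injection.molecular_weight")
  nm <- x$numerics
  pos(nm$n_r, "numerics.n_r"); pos(nm$n_z, "numerics.n_z")
  pos(nm$total_time, "numerics.total_time")
  if (!is.null(nm$dt)) {
    pos(nm$dt, "numerics.dt")
    if (nm$dt > stable_dt(x, safety = 1))
      stop("numerics.dt violates the advective/diffusive stability bound; ",
           "need dt <= ", signif(stable_dt(x, safety = 1), 4), " s",
           call. = FALSE)
  }
  dens <- areal_cell_density(x)
  if (!is.finite(dens) || dens <= 0)
    stop("wall cell areal density must be finite and positive", call. = FALSE)
  x
}

#' Derived configuration quantities
#'
#' @param config a [fiber_config()] object.
#' @return `mean_velocity`: cross-sectionally averaged axial speed (m/s),
#'   `q_s / (N_f * pi * R^2)`.  `areal_cell_density`: wall cells per m^2.
#'   `pulse_volume`: fluid volume (L) delivered per pump stroke.
#' @examples
#' mean_velocity(fiber_config())          # ~1.36e-3 m/s at 0.63 mL/min
#' areal_cell_density(fiber_config()) / 1e4  # ~0.3e6 per cm^2
#' @export
mean_velocity <- function(config) {
  g <- config$geometry
  q <- config$flow$volumetric_rate * 1e-6 / 60  # mL/min -> m^3/s
  q / (g$n_fibers * pi * g$fiber_radius^2)
}

#' @rdname mean_velocity
#' @export
areal_cell_density <- function(config) {
  g <- config$geometry
  g$cells_per_fiber / (2 * pi * g$fiber_radius * g$fiber_length)
}

#' @rdname mean_velocity
#' @export
pulse_volume <- function(config) {
  config$flow$volumetric_rate / config$flow$pulse_rate * 1e-3  # L per stroke
}

#' Convert an injected ligand mass to a molar concentration
#'
#' @param amount_ng mass of ligand, ng.
#' @param volume_L volume it is dissolved in, L.
#' @param mw molecular weight, g/mol (18 kDa for FGF-2).
#' @return concentration in mol/L (M).
#' @examples
#' ligand_mass_to_concentration(1, 4e-4)  # ~1.39e-10 M
#' @export
ligand_mass_to_concentration <- function(amount_ng, volume_L, mw = 18000) {
  if (!is.numeric(volume_L) || volume_L <= 0)
    stop("volume must be positive", call. = FALSE)
  if (any(amount_ng < 0)) stop("amount must be nonnegative", call. = FALSE)
  amount_ng * 1e-9 / (mw * volume_L)
}

# Largest explicit transport step: combined advective (peak velocity,
# pulsatile waveform peaks at twice the Poiseuille centerline) and diffusive
# bound, scaled by `safety`.
stable_dt <- function(config, safety = 0.5) {
  g <- config$geometry; nm <- config$numerics
  dr <- g$fiber_radius / nm$n_r
  dz <- g$fiber_length / nm$n_z
  peak <- 2 * mean_velocity(config) *
    (if (config$flow$waveform == "pulsatile") 2 else 1)
  D <- config$kinetics$D
  safety / (peak / dz + 2 * D / dr^2 + 2 * D / dz^2)
}

#' Read / write a configuration as a YAML document
#'
#' The on-disk format mirrors the constructor sections (`geometry`, `flow`,
#' `kinetics`, `sites`, `injection`, `numerics`, plus `reservoir_mode`);
#' omitted kinetic fields are filled with the base FGF-2 parameter set.
#'
#' @param path file path.
#' @param overrides named character vector of `section.field = value`
#'   overrides applied after parsing, e.g.
#'   `c("flow.volumetric_rate" = "1.8")`.
#' @return `read_config`: a validated [fiber_config()];
#'   `write_config`: `path`, invisibly.
#' @export
read_config <- function(path, overrides = NULL) {
  doc <- yaml::read_yaml(path)
  zones <- NULL
  if (!is.null(doc$sites$zones)) {
    zones <- dplyr::bind_rows(lapply(doc$sites$zones, tibble::as_tibble))
    doc$sites$zones <- NULL
  }
  args <- list(
    geometry = doc$geometry %||% list(), flow = doc$flow %||% list(),
    kinetics = doc$kinetics %||% list(),
    sites = if (is.null(zones)) list() else list(zones = zones),
    injection = doc$injection %||% list(),
    numerics = doc$numerics %||% list(),
    reservoir_mode = doc$reservoir_mode %||% "well_mixed")
  cfg <- do.call(fiber_config, args)
  if (!is.null(overrides)) {
    for (key in names(overrides))
      cfg <- set_config_value(cfg, key, as.numeric(overrides[[key]]))
  }
  cfg
}

#' @rdname read_config
#' @param config a [fiber_config()] object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fiber_config"))
  doc <- unclass(config)
  doc$sites$zones <- lapply(seq_len(nrow(config$sites$zones)), function(i)
    as.list(config$sites$zones[i, ]))
  doc$numerics <- doc$numerics[!vapply(doc$numerics, is.null, logical(1))]
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' Modify one configuration value by path
#'
#' @param config a [fiber_config()].
#' @param path dotted path, e.g. `"kinetics.k_c"`, `"flow.volumetric_rate"`,
#'   or a zone field such as `"sites.zones[1].H0"`.
#' @param value replacement value.
#' @return the modified, re-validated configuration.
#' @export
set_config_value <- function(config, path, value) {
  m <- regmatches(path, regexec("^sites\\.zones\\[(\\d+)\\]\\.(\\w+)$", path))[[1]]
  if (length(m) == 3) {
    i <- as.integer(m[2])
    config$sites$zones[[m[3]]][i] <- value
    return(validate_config(config))
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(config[[parts[1]]]) ||
      !parts[2] %in% names(config[[parts[1]]]))
    stop("unknown configuration path: ", path, call. = FALSE)
  config[[parts[1]]][[parts[2]]] <- value
  validate_config(config)
}

#' @export
print.fiber_config <- function(x, ...) {
  g <- x$geometry; fl <- x$flow; z <- x$sites$zones
  cat("<fiber_config>\n")
  cat(sprintf("  cartridge : %d fibers, R = %g um, L = %g cm, %g cells/fiber\n",
              g$n_fibers, g$fiber_radius * 1e6, g$fiber_length * 100,
              g$cells_per_fiber))
  cat(sprintf("  flow      : %g mL/min %s (%g strokes/min), loss %.0f%%, %s reservoir\n",
              fl$volumetric_rate, fl$waveform, fl$pulse_rate,
              100 * fl$nonspecific_loss_fraction, x$reservoir_mode))
  cat(sprintf("  injection : %g ng (MW %g), mean velocity %.3g mm/s\n",
              x$injection$amount, x$injection$molecular_weight,
              1000 * mean_velocity(x)))
  cat(sprintf("  zones     : %d (R0 %s; H0 %s)\n", nrow(z),
              paste(signif(z$R0, 3), collapse = "/"),
              paste(signif(z$H0, 3), collapse = "/")))
  cat(sprintf("  numerics  : %d x %d mesh, t_end %g s\n",
              x$numerics$n_r, x$numerics$n_z, x$numerics$total_time))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Solver-unit view of the kinetics: seconds and mol/m^3.  Homodimerization
# constants inherit the coupling constants unless set explicitly.
solver_kinetics <- function(config) {
  k <- config$kinetics
  k_dim <- if (is.na(k$k_dim)) k$k_c else k$k_dim
  k_undim <- if (is.na(k$k_undim)) k$k_uc else k$k_undim
  c(ka_FR = k$ka_FR / 6e4, kd_FR = k$kd_FR / 60,
    ka_FH = k$ka_FH / 6e4, kd_FH = k$kd_FH / 60,
    k_c = k$k_c / 60, k_uc = k$k_uc / 60, kd_FHR = k$kd_FHR / 60,
    k_int = k$k_int / 60, k_intD = k$k_intD / 60,
    k_dim = k_dim / 60, k_undim = k_undim / 60)
}

mol_to_ng <- function(mol, config) mol * config$injection$molecular_weight * 1e9
ng_to_mol <- function(ng, config) ng * 1e-9 / config$injection$molecular_weight
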