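#' Amount criterion for simulation/experiment agreement
#'
#' Relative difference between the experimental and simulated outflow
#' amounts, normalized by the amount of ligand entering the fibers:
#' `|M_exp - M_sim| / M_entering`.  Agreement passes when the value is
#' below 0.01 (a 1% relative difference).
#'
#' @param M_exp,M_sim outflow amounts, ng.
#' @param M_entering amount entering the fibers (after nonspecific loss), ng.
#' @param threshold pass threshold.
#' @return tibble with `amount_criterion` and `pass`.
#' @examples
#' amount_criterion(0.70, 0.695, 0.70)
#' @export
amount_criterion <- function(M_exp, M_sim, M_entering, threshold = 0.01) {
  if (!is.numeric(M_entering) || any(M_entering <= 0))
    stop("M_entering must be positive", call. = FALSE)
  v <- abs(M_exp - M_sim) / M_entering
  tibble::tibble(amount_criterion = v, pass = v < threshold)
}

#' Curve-matching criterion between outflow curves
#'
#' Aligns the initial exit times of two discrete outflow curves, rebins
#' both (mass-conservingly) onto `n_intervals` common time intervals, and
#' computes the distance `sqrt(sum_i (E_i - S_i)^2) / N` between the
#' per-interval exited amounts `E_i` (experiment) and `S_i` (simulation).
#' The criterion is the distance normalized by the amount entering the
#' fibers; the default pass threshold is 0.05.
#'
#' @param exp_series,sim_series data frames with columns `time` (fraction
#'   end time, s) and `ng` (ligand in the fraction); [fractionate()] output
#'   is accepted directly.
#' @param M_entering amount entering the fibers, ng (used to normalize; if
#'   `NULL`, the criterion is reported relative to the experimental total).
#' @param n_intervals number of common rebinning intervals `N`.
#' @param threshold pass threshold for the normalized criterion.
#' @param align_frac a curve "starts" at the first fraction whose content
#'   exceeds this fraction of its total.
#' @return tibble (one row) with `curve_distance_ng`, `curve_criterion`,
#'   `aligned_offset_s`, `n_intervals`, `pass`.
#' @examples
#' a <- data.frame(time = 1:10 * 10, ng = c(0, 0, 1, 4, 6, 3, 1, 0.5, 0, 0))
#' curve_match(a, a, M_entering = 15.5)
#' @export
curve_match <- function(exp_series, sim_series, M_entering = NULL,
                        n_intervals = 50, threshold = 0.05,
                        align_frac = 1e-3) {
  e <- as_fraction_series(exp_series)
  s <- as_fraction_series(sim_series)
  t0e <- first_exit_time(e, align_frac)
  t0s <- first_exit_time(s, align_frac)
  offset <- t0s - t0e
  span <- min(max(e$time) - t0e, max(s$time) - t0s)
  if (!is.finite(span) || span <= 0)
    stop("outflow curves do not overlap after alignment", call. = FALSE)
  edges <- seq(0, span, length.out = n_intervals + 1)
  E <- rebin_mass(e$time - t0e, e$ng, edges)
  S <- rebin_mass(s$time - t0s, s$ng, edges)
  dist <- sqrt(sum((E - S)^2)) / n_intervals
  norm <- if (is.null(M_entering)) sum(e$ng) else M_entering
  crit <- dist / norm
  tibble::tibble(curve_distance_ng = dist, curve_criterion = crit,
                 aligned_offset_s = offset, n_intervals = n_intervals,
                 pass = crit < threshold)
}

as_fraction_series <- function(x) {
  x <- as.data.frame(x)
  if (!"time" %in% names(x)) {
    if ("t_end_s" %in% names(x)) x$time <- x$t_end_s
    else if ("time_s" %in% names(x)) x$time <- x$time_s
    else stop("series needs a 'time' column", call. = FALSE)
  }
  if (!"ng" %in% names(x)) stop("series needs an 'ng' column", call. = FALSE)
  x <- x[order(x$time), c("time", "ng")]
  if (all(x$ng <= 0)) stop("series has no nonzero exit", call. = FALSE)
  x
}

first_exit_time <- function(x, align_frac) {
  thr <- align_frac * sum(x$ng)
  i <- which(x$ng > thr)[1]
  # interpolate back to the start of that fraction
  if (i == 1) 0 else x$time[i - 1]
}

# Mass-conserving rebinning: fractions are treated as uniform over their
# span; the cumulative mass is piecewise-linear and differenced at the new
# edges.  Conserves total mass on the common support exactly.  The first
# fraction is assumed to start one fraction-spacing before its end time.
rebin_mass <- function(t_end, ng, edges) {
  d1 <- if (length(t_end) > 1) t_end[2] - t_end[1] else t_end[1]
  t_edges <- c(t_end[1] - d1, t_end)
  cum <- c(0, cumsum(ng))
  diff(stats::approx(t_edges, cum,
                     xout = pmin(pmax(edges, t_edges[1]), max(t_edges)),
                     rule = 2)$y)
}

#' Read an experimental outflow fraction table
#'
#' Accepts the two CSV dialects used for ELISA fraction tables: columns
#' `time_s` + `ng`, or `volume_mL` + `ng` (converted to time with the
#' run-specific flow rate, the total volume collected divided by total flow
#' time).  A header is required.
#'
#' @param path CSV path.
#' @param flow_rate flow rate, mL/min (required for the volume dialect).
#' @return tibble with `time` (s) and `ng`.
#' @export
read_outflow_csv <- function(path, flow_rate = NULL) {
  x <- utils::read.csv(path)
  if ("time_s" %in% names(x)) {
    t <- x$time_s
  } else if ("volume_mL" %in% names(x)) {
    if (is.null(flow_rate))
      stop("flow_rate is required to convert collected volume to time",
           call. = FALSE)
    t <- x$volume_mL / flow_rate * 60
  } else stop("CSV needs a 'time_s' or 'volume_mL' column", call. = FALSE)
  if (!"ng" %in% names(x)) stop("CSV needs an 'ng' column", call. = FALSE)
  tibble::tibble(time = t, ng = x$ng)
}

#' Agreement report between a simulation and an experiment
#'
#' Combines the amount criterion and the curve-matching criterion.
#'
#' @param sim a `fiber_sim` object or a fraction table.
#' @param exp_series experimental fraction table (`time`/`ng`).
#' @param M_exp experimental outflow total, ng (default: sum of
#'   `exp_series$ng`).
#' @param M_entering amount entering the fibers, ng (default: from the
#'   simulation configuration, injected minus nonspecific loss).
#' @param ... passed to [curve_match()].
#' @return one-row tibble combining both criteria.
#' @export
agreement_report <- function(sim, exp_series, M_exp = NULL,
                             M_entering = NULL, ...) {
  if (inherits(sim, "fiber_sim")) {
    frac <- fractionate(sim)
    if (is.null(M_entering))
      M_entering <- sim$config$injection$amount *
        (1 - sim$config$flow$nonspecific_loss_fraction)
    M_sim <- max(frac$cumulative_ng)
  } else {
    frac <- as_fraction_series(sim)
    M_sim <- sum(frac$ng)
    if (is.null(M_entering))
      stop("M_entering required when 'sim' is a fraction table",
           call. = FALSE)
  }
  if (is.null(M_exp)) M_exp <- sum(as_fraction_series(exp_series)$ng)
  ac <- amount_criterion(M_exp, M_sim, M_entering)
  cm <- curve_match(exp_series, frac, M_entering = M_entering, ...)
  dplyr::bind_cols(
    dplyr::rename(ac, amount_pass = "pass"),
    dplyr::rename(cm, curve_pass = "pass"),
    tibble::tibble(M_exp = M_exp, M_sim = M_sim, M_entering = M_entering))
}

#' Retention summary of a finished run
#'
#' Partition of the injected ligand at the end of a run: total retained
#' (injected minus exited), specific retention (nonspecific reservoir loss
#' subtracted), and the per-zone partition of surface-bound and
#' internalized ligand defined by the configured axial zones.
#'
#' @param sim a [run_simulation()] result.
#' @param nonspecific_fraction fraction of the injected amount treated as
#'   nonspecific loss (default: the configured value).
#' @return list with `totals` (one-row tibble: `injected_ng`,
#'   `entering_ng`, `exited_ng`, `retained_ng`, `retained_pct`,
#'   `specific_retained_ng`, `specific_retained_pct`, `fluid_ng`,
#'   `reservoir_ng`) and `zones` (per-zone tibble with `z_from`, `z_to`,
#'   `bound_ng`, `internalized_ng`).
#' @export
retention_summary <- function(sim, nonspecific_fraction = NULL) {
  cfg <- sim$config
  nonspecific_fraction <- nonspecific_fraction %||%
    cfg$flow$nonspecific_loss_fraction
  lg <- sim$ledger[nrow(sim$ledger), ]
  injected <- lg$injected
  nonspecific <- injected * nonspecific_fraction
  retained <- injected - lg$exited
  totals <- tibble::tibble(
    injected_ng = injected,
    entering_ng = injected - nonspecific,
    exited_ng = lg$exited,
    retained_ng = retained,
    retained_pct = 100 * retained / injected,
    specific_retained_ng = retained - nonspecific,
    specific_retained_pct = 100 * (retained - nonspecific) / injected,
    in_fiber_ng = lg$bound + lg$internalized + lg$fluid,
    fluid_ng = lg$fluid,
    reservoir_ng = lg$reservoir)
  fin <- sim$surface[sim$surface$time_s == max(sim$surface$time_s), ]
  zones <- cfg$sites$zones
  L <- cfg$geometry$fiber_length
  zone_of <- findInterval(fin$z_m / L, c(zones$z_from[1], zones$z_to),
                          all.inside = TRUE)
  zt <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(
      zone = zone_of, bound_ng = fin$bound_ng,
      internalized_ng = fin$internalized_ng), .data$zone),
    bound_ng = sum(.data$bound_ng),
    internalized_ng = sum(.data$internalized_ng), .groups = "drop")
  zones_out <- dplyr::bind_cols(zones[zt$zone, c("z_from", "z_to")], zt[-1])
  list(totals = totals, zones = zones_out)
}

#' Parameter sweep
#'
#' Runs one simulation per value of a configuration parameter and tabulates
#' capture summaries, including the ratio of retained (bound plus
#' internalized) ligand to the base-case run (the unmodified configuration),
#' the scaling used for affinity-sweep figures.
#'
#' @param config base [fiber_config()].
#' @param param dotted parameter path, e.g. `"kinetics.k_c"`,
#'   `"flow.volumetric_rate"`, `"sites.zones[1].H0"`.
#' @param values numeric vector of parameter values.
#' @param include_base also run (and report) the unmodified configuration as
#'   the scaling reference; if `FALSE` the first value is the reference.
#' @param ... passed to [run_simulation()].
#' @return tibble with one row per value: `value`, `retained_ng` (bound +
#'   internalized), `bound_ng`, `internalized_ng`, `fluid_ng`, `exited_ng`,
#'   `in_fiber_ng` and `ratio_vs_base`.
#' @export
sweep_simulations <- function(config, param, values, include_base = TRUE,
                              ...) {
  run_one <- function(cfg) {
    g <- glance(run_simulation(cfg, ...))
    tibble::tibble(retained_ng = g$bound_ng + g$internalized_ng,
                   bound_ng = g$bound_ng, internalized_ng = g$internalized_ng,
                   fluid_ng = g$fluid_ng, exited_ng = g$exited_ng,
                   in_fiber_ng = g$retained_ng)
  }
  base <- if (include_base) run_one(config) else NULL
  rows <- purrr::map(values, function(v)
    run_one(set_config_value(config, param, v)))
  out <- dplyr::bind_cols(tibble::tibble(value = values),
                          dplyr::bind_rows(rows))
  ref <- if (include_base) base$retained_ng else out$retained_ng[1]
  out$ratio_vs_base <- out$retained_ng / ref
  out
}
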