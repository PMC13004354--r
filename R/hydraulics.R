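#' Hydrodynamic resistance of one tubing segment
#'
#' Poiseuille resistance of a circular tube for fully developed laminar flow,
#' `R = 128 mu L / (pi D^4)`. The fourth-power dependence on diameter means the
#' narrow cannula tip dominates the resistance of a clinical injection line.
#'
#' @param segment A [tubing_segment()].
#' @param fluid A [fluid_spec()].
#' @return Resistance in Pa.s/m^3.
#' @examples
#' seg <- tubing_segment("41g tip", 0.071, 5, unit = "mm")
#' segment_resistance(seg, fluid_spec()) / 1e12  # ~8.02
#' @export
segment_resistance <- function(segment, fluid) {
  stopifnot(inherits(segment, "tubing_segment"), inherits(fluid, "fluid_spec"))
  128 * fluid$viscosity * segment$length / (pi * segment$inner_diameter^4)
}

#' Effective resistance of a series injection system
#'
#' Sum of the segment resistances: tubes in series add like resistors in
#' series.
#'
#' @param system An [injection_system()].
#' @param fluid A [fluid_spec()].
#' @return Effective resistance in Pa.s/m^3.
#' @export
effective_resistance <- function(system, fluid) {
  stopifnot(inherits(system, "injection_system"))
  sum(vapply(system$segments, segment_resistance, numeric(1), fluid = fluid))
}

#' Share of resistance located at the distal tip
#'
#' Resistance of the last (distal) segment divided by the effective system
#' resistance. For the 5 mm 41g cannula setup this share is about 95%, which is
#' why cannula tip geometry controls the flow.
#'
#' @inheritParams effective_resistance
#' @return Fraction in `[0, 1]`.
#' @export
tip_resistance_fraction <- function(system, fluid) {
  stopifnot(inherits(system, "injection_system"))
  tip <- system$segments[[length(system$segments)]]
  segment_resistance(tip, fluid) / effective_resistance(system, fluid)
}

#' Steady-state flow rate through an injection system
#'
#' Hagen-Poiseuille flow under the driving pressure
#' `P - P_min - P_am`: machine pressure minus the minimum syringe-friction
#' pressure minus the ambient (intraocular) pressure. A non-positive driving
#' pressure yields zero flow (the model does not describe aspiration); the
#' result carries a status field distinguishing `"flowing"` from `"clamped"`.
#'
#' @param system An [injection_system()].
#' @param fluid A [fluid_spec()].
#' @param pressures A [pressure_state()].
#' @param min_pressure_tol Optional half-width (Pa) of an uncertainty interval
#'   on `P_min`; when given, the result includes the flow bounds obtained with
#'   `P_min -/+ min_pressure_tol`.
#' @return An object of class `flow_result`: a list with `flow` (m^3/s),
#'   `driving_pressure` (Pa), `status`, and optionally `flow_lower`/`flow_upper`.
#' @examples
#' sys <- system_preset("model3219")
#' fr <- flow_rate(sys, fluid_spec(), pressure_state(6, unit = "psi"))
#' fr$flow * 1e9  # ~0.82 ul/s
#' @export
flow_rate <- function(system, fluid, pressures, min_pressure_tol = NULL) {
  stopifnot(inherits(system, "injection_system"),
            inherits(pressures, "pressure_state"))
  reff <- effective_resistance(system, fluid)
  drive <- pressures$machine_pressure - system$min_pressure -
    pressures$ambient_pressure
  out <- list(
    flow = if (drive > 0) drive / reff else 0,
    driving_pressure = drive,
    status = if (drive > 0) "flowing" else "clamped"
  )
  if (!is.null(min_pressure_tol)) {
    dlo <- drive - min_pressure_tol  # P_min raised by tol
    dhi <- drive + min_pressure_tol  # P_min lowered by tol
    out$flow_lower <- max(dlo, 0) / reff
    out$flow_upper <- max(dhi, 0) / reff
  }
  structure(out, class = "flow_result")
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("<flow_result> Q = %.4g ul/s (%s, driving pressure %.1f Pa)\n",
              x$flow * 1e9, x$status, x$driving_pressure))
  if (!is.null(x$flow_lower)) {
    cat(sprintf("  P_min uncertainty band: [%.4g, %.4g] ul/s\n",
                x$flow_lower * 1e9, x$flow_upper * 1e9))
  }
  invisible(x)
}

#' Mean fluid velocity in a tube
#'
#' Cross-section averaged velocity `v = 4 Q / (pi D^2)` at a location of inner
#' diameter `D`. Evaluated at the cannula tip it gives the exit velocity of the
#' injected fluid.
#'
#' @param flow Volumetric flow in m^3/s (numeric, or a `flow_result`).
#' @param diameter Inner diameter in m (> 0).
#' @return Velocity in m/s.
#' @export
mean_velocity <- function(flow, diameter) {
  if (inherits(flow, "flow_result")) flow <- flow$flow
  if (!is.numeric(diameter) || any(!is.finite(diameter)) || any(diameter <= 0)) {
    stop("invalid geometry: diameter must be positive", call. = FALSE)
  }
  4 * flow / (pi * diameter^2)
}

#' Delivered volume over an injection
#'
#' Volume administered at constant flow over the injection time, `Q * t_inj`.
#'
#' @param flow Volumetric flow in m^3/s (numeric, or a `flow_result`).
#' @param injection_time Injection duration in s (>= 0).
#' @return Volume in microlitres.
#' @export
delivered_volume <- function(flow, injection_time) {
  if (inherits(flow, "flow_result")) flow <- flow$flow
  stopifnot(is.numeric(injection_time), all(injection_time >= 0))
  flow * injection_time * 1e9
}

#' Flow-rate table over a pressure grid
#'
#' Tabulates the predicted flow rate (ul/s) of each system at each machine
#' pressure, rounded half-up to two decimals as in the published reference
#' table. The unrounded values are attached as attribute `"unrounded"`.
#'
#' @param systems A list of [injection_system()]s (or a single one).
#' @param fluid A [fluid_spec()].
#' @param pressure_grid_psi Machine pressures in psi (default 6 to 20 by 2).
#' @param min_pressure Optional override of each system's `P_min`, in Pa.
#' @param ambient Ambient pressure in Pa (default 0).
#' @return A data frame with columns `system`, `pressure_psi`, `flow_ul_s`
#'   (long format, one row per system x pressure).
#' @export
flow_table <- function(systems, fluid, pressure_grid_psi = seq(6, 20, by = 2),
                       min_pressure = NULL, ambient = 0) {
  if (inherits(systems, "injection_system")) systems <- list(systems)
  stopifnot(length(pressure_grid_psi) > 0)
  rows <- lapply(systems, function(sys) {
    if (!is.null(min_pressure)) sys$min_pressure <- min_pressure
    q <- vapply(pressure_grid_psi, function(p) {
      flow_rate(sys, fluid,
                pressure_state(convert_pressure(p, "psi"), ambient))$flow
    }, numeric(1))
    data.frame(system = if (nzchar(sys$name)) sys$name else "(unnamed)",
               pressure_psi = pressure_grid_psi,
               flow_ul_s = q * 1e9)
  })
  tab <- do.call(rbind, rows)
  out <- tab
  out$flow_ul_s <- round_half_up(tab$flow_ul_s, 2)
  attr(out, "unrounded") <- tab$flow_ul_s
  out
}

#' Flow multiplier for a geometry or viscosity change
#'
#' Scaling of the Poiseuille flow when one parameter of a tip-dominated
#' (single-segment) system is multiplied by `ratio`: flow scales as `ratio^4`
#' for diameter, `1/ratio` for tip length, and `1/ratio` for viscosity. Halving
#' the tip diameter therefore cuts flow 16-fold, while halving the tip length
#' doubles it.
#'
#' @param kind One of `"diameter"`, `"length"`, `"viscosity"`.
#' @param ratio Multiplicative change of the parameter (> 0).
#' @return The multiplier applied to the flow rate.
#' @export
scaling_factor <- function(kind = c("diameter", "length", "viscosity"), ratio) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(ratio), all(ratio > 0))
  switch(kind,
         diameter = ratio^4,
         length = 1 / ratio,
         viscosity = 1 / ratio)
}

#' Back-calculate a tip inner diameter from an observed flow
#'
#' Inverts the series Poiseuille model to recover the inner diameter of a
#' distal tip of known length from one measured flow rate: with
#' `R_obs = driving pressure / Q`, the tip resistance is `R_obs - R_partial`
#' and `D = (128 mu L_tip / (pi (R_obs - R_partial)))^(1/4)`. Used to estimate
#' unpublished tip diameters (e.g. the 51g metal tip) from published flow
#' tables.
#'
#' @param observed_flow_ul_s Measured flow in ul/s (> 0).
#' @param pressures A [pressure_state()] for the measurement.
#' @param partial_system An [injection_system()] containing every segment
#'   except the tip (its `min_pressure` is used for the driving pressure).
#' @param tip_length Tip length in m (> 0).
#' @param fluid A [fluid_spec()].
#' @return Tip inner diameter in m.
#' @export
back_calculate_diameter <- function(observed_flow_ul_s, pressures,
                                    partial_system, tip_length, fluid) {
  stopifnot(inherits(pressures, "pressure_state"),
            inherits(partial_system, "injection_system"))
  if (!is.numeric(observed_flow_ul_s) || observed_flow_ul_s <= 0) {
    stop("observed flow must be positive", call. = FALSE)
  }
  if (tip_length <= 0) {
    stop("invalid geometry: tip_length must be positive", call. = FALSE)
  }
  drive <- pressures$machine_pressure - partial_system$min_pressure -
    pressures$ambient_pressure
  if (drive <= 0) {
    stop("driving pressure must be positive", call. = FALSE)
  }
  r_obs <- drive / (observed_flow_ul_s * 1e-9)
  r_partial <- effective_resistance(partial_system, fluid)
  if (r_obs <= r_partial) {
    stop("infeasible observation: implied total resistance does not exceed ",
         "the resistance of the partial system", call. = FALSE)
  }
  (128 * fluid$viscosity * tip_length / (pi * (r_obs - r_partial)))^0.25
}
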