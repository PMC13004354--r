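#' Jet model parameters
#'
#' The immersed-jet model has one fitted constant `K` (dimensionless) that
#' absorbs non-ideal effects — confinement between the chamber walls, gravity,
#' the non-punctual source — and the injection time `t_inj` over which the dye
#' front's travel is averaged.
#'
#' @param K Jet constant (> 0).
#' @param injection_time Injection time in s (> 0), default 5.
#' @return An object of class `jet_params`.
#' @export
jet_params <- function(K, injection_time = 5) {
  if (!is.numeric(K) || length(K) != 1 || !is.finite(K) || K <= 0) {
    stop("K must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(injection_time) || length(injection_time) != 1 ||
      injection_time <= 0) {
    stop("injection_time must be a single positive number (s)", call. = FALSE)
  }
  structure(list(K = K, injection_time = injection_time), class = "jet_params")
}

#' Local jet speed at a distance from the cannula tip
#'
#' For a round momentum-conserving jet immersed in the same liquid, the local
#' speed decays inversely with distance travelled:
#' `v_jet(z) = K * vbar * D / z`, valid far from the source (`z >> D`; a
#' warning is issued when `z <= 10 D`).
#'
#' @param mean_velocity Mean exit velocity at the tip, m/s.
#' @param diameter Tip inner diameter, m.
#' @param distance Distance from the tip, m (> 0).
#' @param params A [jet_params()].
#' @return Jet speed in m/s.
#' @export
jet_speed_at_distance <- function(mean_velocity, diameter, distance, params) {
  stopifnot(inherits(params, "jet_params"))
  if (any(distance <= 0)) stop("distance must be positive", call. = FALSE)
  if (any(distance <= 10 * diameter)) {
    warning("far-field 1/z decay assumed but distance <= 10 * diameter",
            call. = FALSE)
  }
  params$K * mean_velocity * diameter / distance
}

#' Front speed of the jet over the injection
#'
#' The observable jet speed is the distance travelled by the dye front divided
#' by the injection time, `v_jet = z_jet / t_inj`. Combining this definition
#' with the `1/z` decay law gives the self-consistent front speed
#' `v_jet = sqrt(K * vbar * D / t_inj)`. Because the mean exit velocity is
#' linear in driving pressure, the front speed grows with the square root of
#' the injection pressure.
#'
#' @inheritParams jet_speed_at_distance
#' @return Front speed in m/s (vectorised over `mean_velocity`).
#' @export
jet_front_speed <- function(mean_velocity, diameter, params) {
  stopifnot(inherits(params, "jet_params"))
  sqrt(params$K * mean_velocity * diameter / params$injection_time)
}

#' Distance travelled by the jet front
#'
#' `z_jet = v_jet * t_inj`, the penetration distance of the dye front over the
#' injection. Its ratio to the tip diameter indicates whether the far-field
#' decay law applies (`z_jet / D >> 1`).
#'
#' @param params A [jet_params()].
#' @param mean_velocity Mean exit velocity at the tip, m/s.
#' @param diameter Tip inner diameter, m.
#' @return Penetration distance in m.
#' @export
penetration_distance <- function(params, mean_velocity, diameter) {
  jet_front_speed(mean_velocity, diameter, params) * params$injection_time
}

#' Fit the jet constant to measured jet speeds
#'
#' Least-squares fit of the front-speed law to replicate-level bench
#' measurements. For each observation the mean tip exit velocity is computed
#' from the hydraulic model at that machine pressure, and `K` minimises the sum
#' of squared residuals between observed speeds and
#' `sqrt(K * vbar * D / t_inj)`. The model is linear in `sqrt(K)`, so the
#' optimum is the exact regression-through-the-origin solution
#' `sqrt(K) = sum(v_i s_i) / sum(s_i^2)` with `s_i = sqrt(vbar_i D / t_inj)`,
#' constrained to `K > 0`.
#'
#' Observations at machine pressures with non-positive driving pressure carry
#' no model signal and are dropped with a warning.
#'
#' @param observations Data frame with columns `pressure_psi` and
#'   `jet_speed_cm_s` (replicate-level).
#' @param system An [injection_system()].
#' @param fluid A [fluid_spec()].
#' @param ambient Ambient pressure in Pa (default 0).
#' @param injection_time Injection time in s (default 5).
#' @return An object of class `jet_fit`: list with `K`, `params`
#'   ([jet_params()]), `n`, `rss` (m/s scale), `fitted` and `residuals`
#'   (cm/s scale, aligned with the retained observations), and `data`.
#' @export
fit_jet_constant <- function(observations, system, fluid,
                             ambient = 0, injection_time = 5) {
  stopifnot(is.data.frame(observations),
            all(c("pressure_psi", "jet_speed_cm_s") %in% names(observations)))
  tip_d <- system$segments[[length(system$segments)]]$inner_diameter
  vbar <- vapply(observations$pressure_psi, function(p) {
    fr <- flow_rate(system, fluid,
                    pressure_state(convert_pressure(p, "psi"), ambient))
    mean_velocity(fr$flow, tip_d)
  }, numeric(1))
  keep <- vbar > 0
  if (!any(keep)) {
    stop("unfittable: no observation has positive driving pressure",
         call. = FALSE)
  }
  if (!all(keep)) {
    warning(sum(!keep), " observation(s) below the flow threshold dropped",
            call. = FALSE)
  }
  obs <- observations[keep, , drop = FALSE]
  vbar <- vbar[keep]
  if (nrow(obs) < 2 || length(unique(obs$pressure_psi)) < 2) {
    stop("unfittable: need >= 2 observations at >= 2 distinct pressures",
         call. = FALSE)
  }
  v_obs <- obs$jet_speed_cm_s / 100                    # m/s
  s <- sqrt(vbar * tip_d / injection_time)             # v = sqrt(K) * s
  sqrt_k <- sum(v_obs * s) / sum(s^2)
  if (sqrt_k <= 0) {
    stop("unfittable: fitted K is not positive", call. = FALSE)
  }
  k <- sqrt_k^2
  fitted_ms <- sqrt_k * s
  res_ms <- v_obs - fitted_ms
  structure(list(
    K = k,
    params = jet_params(k, injection_time),
    n = nrow(obs),
    rss = sum(res_ms^2),
    fitted = fitted_ms * 100,
    residuals = res_ms * 100,
    data = obs
  ), class = "jet_fit")
}

#' @export
print.jet_fit <- function(x, ...) {
  cat(sprintf("<jet_fit> K = %.4g (t_inj = %g s, n = %d, RSS = %.3g (m/s)^2)\n",
              x$K, x$params$injection_time, x$n, x$rss))
  invisible(x)
}
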