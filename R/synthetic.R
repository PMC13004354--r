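#' Effect of an experimental condition on the bench rig
#'
#' Describes how one experimental condition departs from baseline:
#' the ambient chamber pressure, a shortened viscous-fluid-injection (VFI)
#' tubing (recorded but hydraulically inert — the VFI tubing's resistance is
#' negligible next to the cannula tip), and the compliance effects of the
#' "lock-and-load" priming technique, modelled as a jet-speed multiplier and a
#' per-pressure additive offset on the residual-flow duration.
#'
#' @param ambient_mmHg Ambient chamber pressure in mmHg (default 15).
#' @param vfi_length_factor Fraction of the standard VFI tubing length kept
#'   (default 1; informational).
#' @param speed_factor Multiplier (<= 1) on the noise-free jet speed (default 1).
#' @param residual_offset Additive offset (s) on the residual duration; either
#'   a scalar or a numeric vector named by pressure in psi (default 0).
#' @return An object of class `condition_effect`.
#' @export
condition_effect <- function(ambient_mmHg = 15, vfi_length_factor = 1,
                             speed_factor = 1, residual_offset = 0) {
  stopifnot(ambient_mmHg >= 0, vfi_length_factor > 0,
            speed_factor > 0, speed_factor <= 1)
  structure(list(ambient_mmHg = ambient_mmHg,
                 vfi_length_factor = vfi_length_factor,
                 speed_factor = speed_factor,
                 residual_offset = residual_offset),
            class = "condition_effect")
}

#' Default experimental conditions
#'
#' The four bench conditions:
#' * `BC` — baseline: 15 mmHg chamber pressure, standard VFI tubing,
#'   "load-and-lock" priming;
#' * `MP1` — chamber pressure raised to 45 mmHg;
#' * `MP2` — VFI tubing shortened to a quarter (no noise-free model effect,
#'   since the VFI tubing's resistance is negligible);
#' * `MP3` — "lock-and-load" priming, which traps compressible air in the
#'   syringe: jet speed scaled down and residual durations offset upwards at
#'   the tested pressures (offsets taken from the published condition table).
#'
#' @return Named list of [condition_effect()]s.
#' @export
default_condition_effects <- function() {
  list(
    BC  = condition_effect(),
    MP1 = condition_effect(ambient_mmHg = 45),
    MP2 = condition_effect(vfi_length_factor = 0.25),
    MP3 = condition_effect(speed_factor = 0.8,
                           residual_offset = c("8" = 23.8, "14" = 19.3,
                                               "20" = 27.0))
  )
}

#' Configuration of the synthetic bench-rig generator
#'
#' Defines the measurement design and ground-truth parameters of the simulated
#' experimental rig. The defaults reproduce the bench design: machine pressures
#' 6-20 psi in 2 psi steps with triplicate baseline measurements, modified
#' conditions at 8/14/20 psi with 4 replicates each, multiplicative Gaussian
#' noise on jet speeds and additive sub-second Gaussian noise on residual
#' durations.
#'
#' Default ground truth: `K_true = 0.6912` makes the baseline front speed
#' 0.12 cm/s at 6 psi for the standard 5 mm 41g cannula setup at 15 mmHg
#' ambient; `residual_a = -1.4688`, `residual_b = 16.2794` interpolate the
#' published baseline residual durations at 6 and 20 psi (27.7 s and 47.3 s).
#'
#' @param pressure_grid Baseline machine pressures in psi (strictly increasing).
#' @param replicates_bc Baseline replicates per pressure (default 3).
#' @param replicates_mp Modified-condition replicates per pressure (default 4).
#' @param mp_pressures Pressures tested under modified conditions (default
#'   8, 14, 20 psi).
#' @param K_true Ground-truth jet constant.
#' @param injection_time Injection time in s (default 5).
#' @param residual_a,residual_b Ground-truth coefficients of
#'   `duration = a + b log(P)` (s and s per log-psi).
#' @param jet_noise_cv Coefficient of variation of the multiplicative jet-speed
#'   noise (default 0.05).
#' @param residual_noise_sd SD of the additive duration noise in s (default
#'   0.8, mid-range of the published replicate spreads).
#' @param condition_effects Named list of [condition_effect()]s; the first is
#'   treated as baseline and uses the full pressure grid.
#' @param seed Master seed; jet and residual streams use seeds derived from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(pressure_grid = seq(6, 20, by = 2),
                             replicates_bc = 3,
                             replicates_mp = 4,
                             mp_pressures = c(8, 14, 20),
                             K_true = 0.6912,
                             injection_time = 5,
                             residual_a = -1.4688,
                             residual_b = 16.2794,
                             jet_noise_cv = 0.05,
                             residual_noise_sd = 0.8,
                             condition_effects = default_condition_effects(),
                             seed = 1L) {
  stopifnot(length(pressure_grid) >= 1, all(diff(pressure_grid) > 0),
            replicates_bc >= 1, replicates_mp >= 1,
            all(mp_pressures %in% pressure_grid) || length(mp_pressures) >= 1,
            K_true > 0, injection_time > 0,
            jet_noise_cv >= 0, residual_noise_sd >= 0,
            is.list(condition_effects), length(condition_effects) >= 1,
            !is.null(names(condition_effects)))
  structure(list(pressure_grid = pressure_grid,
                 replicates_bc = as.integer(replicates_bc),
                 replicates_mp = as.integer(replicates_mp),
                 mp_pressures = mp_pressures,
                 K_true = K_true,
                 injection_time = injection_time,
                 residual_a = residual_a,
                 residual_b = residual_b,
                 jet_noise_cv = jet_noise_cv,
                 residual_noise_sd = residual_noise_sd,
                 condition_effects = condition_effects,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Derived per-stream seeds, kept below 2^31.
.stream_seed <- function(seed, stream = c("jet", "residual")) {
  stream <- match.arg(stream)
  offset <- switch(stream, jet = 0L, residual = 500009L)
  (abs(as.integer(seed)) + offset) %% .Machine$integer.max
}

# Pressures and replicate count for one condition.
.condition_design <- function(config, cond_name) {
  is_baseline <- cond_name == names(config$condition_effects)[1]
  list(pressures = if (is_baseline) config$pressure_grid else config$mp_pressures,
       reps = if (is_baseline) config$replicates_bc else config$replicates_mp)
}

#' Generate synthetic jet-speed measurements
#'
#' Simulates replicate-level jet-speed observations for every condition:
#' the noise-free speed is the hydraulic-jet model front speed at that
#' condition's ambient pressure, times the condition's speed factor;
#' measurement noise is multiplicative Gaussian with coefficient of variation
#' `jet_noise_cv`. Deterministic for a fixed config (seeded jet stream).
#'
#' @param config A [synthetic_config()].
#' @param system An [injection_system()] (default: the 5 mm 41g cannula preset).
#' @param fluid A [fluid_spec()] (default water).
#' @return Data frame with columns `pressure_psi`, `condition`, `replicate`,
#'   `jet_speed_cm_s`; the noise-free per-cell truth is attached as attribute
#'   `"truth"` (columns `pressure_psi`, `condition`, `jet_speed_cm_s`).
#' @export
generate_jet_speeds <- function(config,
                                system = system_preset("model3219"),
                                fluid = fluid_spec()) {
  stopifnot(inherits(config, "synthetic_config"))
  tip_d <- system$segments[[length(system$segments)]]$inner_diameter
  params <- jet_params(config$K_true, config$injection_time)
  truth <- list()
  rows <- list()
  set.seed(.stream_seed(config$seed, "jet"))
  for (cond in names(config$condition_effects)) {
    eff <- config$condition_effects[[cond]]
    des <- .condition_design(config, cond)
    for (p in des$pressures) {
      fr <- flow_rate(system, fluid,
                      pressure_state(convert_pressure(p, "psi"),
                                     convert_pressure(eff$ambient_mmHg, "mmHg")))
      v0 <- jet_front_speed(mean_velocity(fr$flow, tip_d), tip_d, params) *
        eff$speed_factor * 100  # cm/s
      truth[[length(truth) + 1]] <-
        data.frame(pressure_psi = p, condition = cond, jet_speed_cm_s = v0)
      eps <- stats::rnorm(des$reps, 0, config$jet_noise_cv)
      rows[[length(rows) + 1]] <-
        data.frame(pressure_psi = p, condition = cond,
                   replicate = seq_len(des$reps),
                   jet_speed_cm_s = pmax(v0 * (1 + eps), 0))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

# Residual offset of a condition at one pressure (named vector or scalar).
.residual_offset_at <- function(eff, pressure_psi) {
  off <- eff$residual_offset
  if (length(off) == 1 && is.null(names(off))) return(unname(off))
  key <- as.character(pressure_psi)
  if (key %in% names(off)) unname(off[[key]]) else 0
}

#' Generate synthetic residual-flow durations
#'
#' Simulates replicate-level residual-flow durations:
#' `duration = a + b log(P) + condition offset + Normal(0, sd)`, truncated to
#' stay positive. Deterministic for a fixed config (seeded residual stream).
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `pressure_psi`, `condition`, `replicate`,
#'   `duration_s`; noise-free truth attached as attribute `"truth"`.
#' @export
generate_residual_durations <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- list()
  rows <- list()
  set.seed(.stream_seed(config$seed, "residual"))
  for (cond in names(config$condition_effects)) {
    eff <- config$condition_effects[[cond]]
    des <- .condition_design(config, cond)
    for (p in des$pressures) {
      d0 <- config$residual_a + config$residual_b * log(p) +
        .residual_offset_at(eff, p)
      truth[[length(truth) + 1]] <-
        data.frame(pressure_psi = p, condition = cond, duration_s = d0)
      noise <- stats::rnorm(des$reps, 0, config$residual_noise_sd)
      rows[[length(rows) + 1]] <-
        data.frame(pressure_psi = p, condition = cond,
                   replicate = seq_len(des$reps),
                   duration_s = pmax(d0 + noise, .Machine$double.eps))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- do.call(rbind, truth)
  out
}

#' Simulate a full bench dataset to disk
#'
#' Writes `jet.csv` and `residual.csv` (replicate-level, in the package CSV
#' schemas) plus `truth.json` holding the generator parameters and noise-free
#' curves, so downstream fits can be scored against ground truth.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if needed).
#' @param system,fluid Passed to [generate_jet_speeds()].
#' @return Invisibly, the list of written file paths.
#' @export
simulate_em <- function(config, out_dir,
                        system = system_preset("model3219"),
                        fluid = fluid_spec()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jets <- generate_jet_speeds(config, system, fluid)
  res <- generate_residual_durations(config)
  jet_path <- file.path(out_dir, "jet.csv")
  res_path <- file.path(out_dir, "residual.csv")
  truth_path <- file.path(out_dir, "truth.json")
  utils::write.csv(jets, jet_path, row.names = FALSE)
  utils::write.csv(res, res_path, row.names = FALSE)
  truth <- list(
    K_true = config$K_true,
    injection_time_s = config$injection_time,
    residual_a_s = config$residual_a,
    residual_b_s_per_logpsi = config$residual_b,
    jet_noise_cv = config$jet_noise_cv,
    residual_noise_sd_s = config$residual_noise_sd,
    seed = config$seed,
    jet_truth = attr(jets, "truth"),
    residual_truth = attr(res, "truth")
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(jet = jet_path, residual = res_path, truth = truth_path))
}
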