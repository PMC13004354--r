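#' Run the full analysis report
#'
#' Wires the hydraulic model, the jet fit and the residual-flow fits into one
#' reproducible output bundle. Writes, under `out_dir`:
#' * `resistance_table.csv` — per-segment and effective resistances plus the
#'   distal tip share for each system;
#' * `flow_table.csv` — flow rates (ul/s) over the pressure grid;
#' * `jet_fit.csv` — fitted jet constant and per-observation diagnostics
#'   (when jet data are supplied);
#' * `residual_fit.csv` — logarithmic duration fits per condition (when
#'   residual data are supplied);
#' * `pause_table.csv` — recommended post-injection pause (s, rounded up to
#'   the next whole second, conservative) per pressure and condition;
#' * `summary.txt` — human-readable recap;
#' * `manifest.json` — command parameters, input-file digests, package
#'   version, seed and timestamp.
#'
#' All numeric CSV columns carry unit suffixes (`_ul_s`, `_cm_s`, `_s`, ...).
#' Given identical inputs and seed, the CSV outputs are byte-identical across
#' runs.
#'
#' @param out_dir Output directory (created if needed).
#' @param systems Named list of [injection_system()]s (default: the three
#'   packaged presets).
#' @param fluid A [fluid_spec()] (default water).
#' @param pressure_grid_psi Machine-pressure grid in psi.
#' @param jet_data Optional path to a jet-speed CSV (`pressure_psi`,
#'   `condition`, `replicate`, `jet_speed_cm_s`) or a data frame.
#' @param residual_data Optional path to a residual-duration CSV
#'   (`pressure_psi`, `condition`, `replicate`, `duration_s`) or a data frame.
#' @param jet_system Name (in `systems`) of the setup the jet data were
#'   measured on (default `"model3219"`).
#' @param ambient_mmHg Ambient chamber pressure for the jet fit (default 15).
#' @param injection_time Injection time in s (default 5).
#' @param safety_margin Seconds added to pause recommendations (default 3).
#' @param seed Seed recorded in the manifest (default 1).
#' @return Invisibly, a list with the in-memory report components and the
#'   manifest.
#' @export
run_report <- function(out_dir,
                       systems = load_fixture("table1_systems"),
                       fluid = fluid_spec(),
                       pressure_grid_psi = seq(6, 20, by = 2),
                       jet_data = NULL,
                       residual_data = NULL,
                       jet_system = "model3219",
                       ambient_mmHg = 15,
                       injection_time = 5,
                       safety_margin = 3,
                       seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  input_paths <- character()

  read_input <- function(x, what, required_cols) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) {
      if (!file.exists(x)) {
        stop(sprintf(
          "%s file not found: %s (expected CSV with columns %s)",
          what, x, paste(required_cols, collapse = ", ")), call. = FALSE)
      }
      input_paths[[length(input_paths) + 1]] <<- x
      x <- utils::read.csv(x, stringsAsFactors = FALSE)
    }
    missing <- setdiff(required_cols, names(x))
    if (length(missing) > 0) {
      stop(sprintf("%s data lack column(s): %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    x
  }
  jets <- read_input(jet_data, "jet-speed",
                     c("pressure_psi", "condition", "jet_speed_cm_s"))
  resid <- read_input(residual_data, "residual-duration",
                      c("pressure_psi", "condition", "duration_s"))

  # resistance table
  res_rows <- lapply(names(systems), function(nm) {
    sys <- systems[[nm]]
    seg <- data.frame(
      system = nm,
      segment = vapply(sys$segments, `[[`, character(1), "label"),
      inner_diameter_mm = vapply(sys$segments, function(s)
        s$inner_diameter * 1e3, numeric(1)),
      length_mm = vapply(sys$segments, function(s) s$length * 1e3, numeric(1)),
      resistance_1e12_Pa_s_m3 = vapply(sys$segments, function(s)
        segment_resistance(s, fluid) / 1e12, numeric(1))
    )
    seg$effective_1e12_Pa_s_m3 <- effective_resistance(sys, fluid) / 1e12
    seg$tip_fraction <- tip_resistance_fraction(sys, fluid)
    seg
  })
  resistance_table <- do.call(rbind, res_rows)

  flows <- flow_table(systems, fluid, pressure_grid_psi)

  jet_fit <- NULL
  if (!is.null(jets)) {
    # fit K on the baseline condition only; modified conditions change the
    # ambient/compliance terms and would bias a pooled fit
    bc <- if ("BC" %in% jets$condition) {
      jets[jets$condition == "BC", , drop = FALSE]
    } else {
      jets
    }
    jet_fit <- fit_jet_constant(
      bc, systems[[jet_system]], fluid,
      ambient = convert_pressure(ambient_mmHg, "mmHg"),
      injection_time = injection_time)
  }

  residual_fits <- NULL
  pause_table <- NULL
  if (!is.null(resid)) {
    conds <- unique(resid$condition)
    fits <- list()
    for (cond in conds) {
      obs <- resid[resid$condition == cond, , drop = FALSE]
      if (length(unique(obs$pressure_psi)) >= 3) {
        fits[[cond]] <- fit_log_model(obs)
      }
    }
    residual_fits <- fits
    if (length(fits) > 0) {
      prows <- list()
      for (cond in names(fits)) {
        fit <- fits[[cond]]
        pgrid <- sort(unique(
          resid$pressure_psi[resid$condition == cond]))
        pause <- vapply(pgrid, function(p) {
          ceiling(predict_pause(fit, p, condition = cond, observations = resid,
                                safety_margin = safety_margin))
        }, numeric(1))
        prows[[cond]] <- data.frame(condition = cond, pressure_psi = pgrid,
                                    pause_s = pause)
      }
      pause_table <- do.call(rbind, prows)
      rownames(pause_table) <- NULL
    }
  }

  # write outputs
  wcsv <- function(x, file) {
    utils::write.csv(x, file.path(out_dir, file), row.names = FALSE)
  }
  wcsv(resistance_table, "resistance_table.csv")
  wcsv(flows, "flow_table.csv")
  if (!is.null(jet_fit)) {
    wcsv(data.frame(K = jet_fit$K, injection_time_s = injection_time,
                    n = jet_fit$n, rss_m2_s2 = jet_fit$rss),
         "jet_fit.csv")
    wcsv(cbind(jet_fit$data,
               fitted_cm_s = jet_fit$fitted,
               residual_cm_s = jet_fit$residuals),
         "jet_fit_diagnostics.csv")
  }
  if (!is.null(residual_fits) && length(residual_fits) > 0) {
    wcsv(data.frame(
      condition = names(residual_fits),
      intercept_s = vapply(residual_fits, `[[`, numeric(1), "a"),
      slope_s_per_logpsi = vapply(residual_fits, `[[`, numeric(1), "b"),
      rss_s2 = vapply(residual_fits, `[[`, numeric(1), "rss"),
      n = vapply(residual_fits, `[[`, numeric(1), "n")
    ), "residual_fit.csv")
  }
  if (!is.null(pause_table)) wcsv(pause_table, "pause_table.csv")

  summary_lines <- c(
    "Subretinal injection flow report",
    "================================",
    sprintf("Systems: %s", paste(names(systems), collapse = ", ")),
    sprintf("Fluid viscosity: %g Pa.s", fluid$viscosity),
    sprintf("Pressure grid: %s psi",
            paste(pressure_grid_psi, collapse = ", ")),
    vapply(names(systems), function(nm) {
      sprintf("  %s: R_eff = %.2f x10^12 Pa.s/m^3, tip share %.0f%%",
              nm, effective_resistance(systems[[nm]], fluid) / 1e12,
              100 * tip_resistance_fraction(systems[[nm]], fluid))
    }, character(1)),
    if (!is.null(jet_fit)) {
      sprintf("Jet fit (baseline): K = %.4g (n = %d)", jet_fit$K, jet_fit$n)
    } else "Jet fit: no data supplied (model-only report)",
    if (!is.null(residual_fits) && length(residual_fits) > 0) {
      vapply(names(residual_fits), function(cond) {
        f <- residual_fits[[cond]]
        sprintf("Residual fit %s: duration = %.2f + %.2f log(P) s (n = %d)",
                cond, f$a, f$b, f$n)
      }, character(1))
    } else "Residual fit: no data supplied (model-only report)"
  )
  writeLines(unlist(summary_lines), file.path(out_dir, "summary.txt"))

  manifest <- list(
    command = "run_report",
    package_version = as.character(utils::packageVersion("subflowr")),
    seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    parameters = list(
      systems = names(systems),
      viscosity_Pa_s = fluid$viscosity,
      pressure_grid_psi = pressure_grid_psi,
      ambient_mmHg = ambient_mmHg,
      injection_time_s = injection_time,
      safety_margin_s = safety_margin
    ),
    input_digests = if (length(input_paths) > 0) {
      as.list(tools::md5sum(unlist(input_paths)))
    } else list()
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(resistance_table = resistance_table,
                 flow_table = flows,
                 jet_fit = jet_fit,
                 residual_fits = residual_fits,
                 pause_table = pause_table,
                 manifest = manifest))
}
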