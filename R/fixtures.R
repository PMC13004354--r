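#' Load a packaged reference dataset
#'
#' Accessor for the data shipped with the package:
#' * `"table1_systems"` — the three commercial injection-system presets as a
#'   named list of [injection_system()]s (the 51g tip diameter is synthetic,
#'   see [system_preset()]);
#' * `"table2_flows"` — the published flow-rate table (ul/s) for the three
#'   cannula setups over 6-20 psi, values verbatim as printed;
#' * `"table3_residuals"` — the published residual-flow duration summary
#'   (mean, sd, n per pressure and condition); expand to replicate level with
#'   [expand_replicates()];
#' * `"intext_values"` — scalar reference values quoted in the source report
#'   (effective resistance, tip share, unit equivalences, pause range, ...);
#' * `"s1_velocities_schema"`, `"s2_jetspeeds_schema"` — schema descriptions of
#'   the two supplementary bench tables whose cell values are not available;
#'   each returns the schema plus a clearly flagged synthetic stand-in table
#'   computed from the model at load time.
#'
#' @param name Fixture name.
#' @return See above; data frames for tables, lists otherwise.
#' @export
load_fixture <- function(name = c("table1_systems", "table2_flows",
                                  "table3_residuals", "intext_values",
                                  "s1_velocities_schema",
                                  "s2_jetspeeds_schema")) {
  name <- match.arg(name)
  path <- function(...) system.file("extdata", ..., package = "subflowr",
                                    mustWork = TRUE)
  switch(name,
    table1_systems = list(
      model3219 = system_preset("model3219"),
      model3255 = system_preset("model3255"),
      model3263 = system_preset("model3263")
    ),
    table2_flows = utils::read.csv(path("table2_flows.csv"),
                                   stringsAsFactors = FALSE),
    table3_residuals = utils::read.csv(path("table3_residuals.csv"),
                                       stringsAsFactors = FALSE),
    intext_values = jsonlite::read_json(path("intext_values.json"),
                                        simplifyVector = TRUE),
    s1_velocities_schema = {
      schema <- jsonlite::read_json(path("s1_velocities_schema.json"),
                                    simplifyVector = TRUE)
      list(schema = schema, standin = .s1_standin(), synthetic = TRUE)
    },
    s2_jetspeeds_schema = {
      schema <- jsonlite::read_json(path("s2_jetspeeds_schema.json"),
                                    simplifyVector = TRUE)
      list(schema = schema, standin = .s2_standin(), synthetic = TRUE)
    }
  )
}

# Synthetic stand-in for the mean-velocity supplement: pure model output.
.s1_standin <- function() {
  fluid <- fluid_spec()
  rows <- lapply(c("model3219", "model3255", "model3263"), function(nm) {
    sys <- system_preset(nm)
    tip_d <- sys$segments[[length(sys$segments)]]$inner_diameter
    v <- vapply(seq(6, 20, by = 2), function(p) {
      fr <- flow_rate(sys, fluid, pressure_state(convert_pressure(p, "psi")))
      mean_velocity(fr$flow, tip_d) * 100
    }, numeric(1))
    data.frame(system = nm, pressure_psi = seq(6, 20, by = 2),
               mean_velocity_cm_s = v)
  })
  do.call(rbind, rows)
}

# Synthetic stand-in for the jet-speed supplement: generator summary.
.s2_standin <- function() {
  jets <- generate_jet_speeds(synthetic_config())
  s <- summarize_residuals(
    data.frame(pressure_psi = jets$pressure_psi, condition = jets$condition,
               duration_s = jets$jet_speed_cm_s))
  data.frame(pressure_psi = s$pressure_psi, condition = s$condition,
             jet_speed_cm_s = s$mean_s, sd_cm_s = s$sd_s)
}

#' Expand a duration summary into replicates with matching moments
#'
#' Constructs replicate-level observations from per-cell (mean, sd, n)
#' summaries such that each cell's arithmetic mean and sample standard
#' deviation reproduce the summary exactly. These are symmetric stand-in
#' patterns, not the original bench replicates:
#' * odd `n`: the centre value `m` plus `(n-1)/2` symmetric pairs `m -/+ s`
#'   (so `n = 3` gives `{m - s, m, m + s}`);
#' * even `n`: `n/2` alternating pairs `m -/+ d` with `d = s * sqrt((n-1)/n)`.
#'
#' @param summary Data frame with columns `pressure_psi`, `condition`,
#'   `mean_s`, `sd_s`, `n` (e.g. `load_fixture("table3_residuals")`).
#' @return Replicate-level data frame with columns `pressure_psi`,
#'   `condition`, `replicate`, `duration_s`.
#' @export
expand_replicates <- function(summary) {
  stopifnot(is.data.frame(summary),
            all(c("pressure_psi", "condition", "mean_s", "sd_s", "n") %in%
                  names(summary)))
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    m <- summary$mean_s[i]
    s <- summary$sd_s[i]
    n <- summary$n[i]
    vals <- if (n == 1) {
      m
    } else if (n %% 2 == 1) {
      # odd: centre point at m, (n-1) points at m +/- d; sample SS = (n-1) d^2
      d <- s
      c(m, rep(c(m - d, m + d), (n - 1) / 2))
    } else {
      # even: alternating m +/- d, sample SS = n d^2 = (n-1) s^2
      d <- s * sqrt((n - 1) / n)
      rep(c(m - d, m + d), n / 2)
    }
    data.frame(pressure_psi = summary$pressure_psi[i],
               condition = summary$condition[i],
               replicate = seq_len(n),
               duration_s = vals)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
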