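#' Fluid properties
#'
#' Specifies the injected fluid. Only the dynamic viscosity enters the laminar
#' flow model; water (and the saline-based vector solutions used clinically)
#' has viscosity close to 0.001 Pa.s at room temperature.
#'
#' @param viscosity Dynamic viscosity in Pa.s; must be positive.
#' @return An object of class `fluid_spec`.
#' @examples
#' water <- fluid_spec()                # 1 mPa.s
#' dmso10 <- fluid_spec(2e-3)          # ~10% DMSO cell-therapy carrier
#' @export
fluid_spec <- function(viscosity = 1e-3) {
  if (!is.numeric(viscosity) || length(viscosity) != 1 || !is.finite(viscosity) ||
      viscosity <= 0) {
    stop("viscosity must be a single positive number (Pa.s)", call. = FALSE)
  }
  structure(list(viscosity = viscosity), class = "fluid_spec")
}

#' Tubing segment of an injection system
#'
#' One tube element of circular cross-section, characterised by its inner
#' diameter and length. Segments are assembled proximal to distal into an
#' [injection_system()].
#'
#' @param label Free-text description of the segment.
#' @param inner_diameter Inner diameter (> 0).
#' @param length Segment length (> 0).
#' @param unit Unit of the two dimensions, `"m"` (default) or `"mm"`.
#' @return An object of class `tubing_segment`; dimensions stored in metres.
#' @examples
#' tip <- tubing_segment("41g polyamide tip", 0.071, 5, unit = "mm")
#' @export
tubing_segment <- function(label, inner_diameter, length, unit = c("m", "mm")) {
  unit <- match.arg(unit)
  scale <- if (unit == "mm") 1e-3 else 1
  d <- inner_diameter * scale
  l <- length * scale
  if (!is.numeric(d) || length(d) != 1 || !is.finite(d) || d <= 0) {
    stop("invalid geometry: inner_diameter must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(l) || length(l) != 1 || !is.finite(l) || l <= 0) {
    stop("invalid geometry: length must be a single positive number",
         call. = FALSE)
  }
  structure(list(label = as.character(label)[1], inner_diameter = d, length = l),
            class = "tubing_segment")
}

#' Injection system: tubing segments in series
#'
#' An ordered (proximal to distal) series of [tubing_segment()]s plus the
#' minimum syringe pressure `P_min`, the air pressure needed to overcome static
#' friction between plunger and barrel before any flow occurs. The last
#' segment is the distal cannula tip.
#'
#' @param segments List of `tubing_segment` objects, proximal first.
#' @param min_pressure Minimum syringe pressure in Pa (>= 0). Defaults to
#'   5 psi, the value measured for the 1 ml microdose injector syringe.
#' @param name Optional system name.
#' @return An object of class `injection_system`.
#' @seealso [system_preset()] for the packaged commercial cannula setups.
#' @export
injection_system <- function(segments,
                             min_pressure = convert_pressure(5, "psi"),
                             name = "") {
  if (inherits(segments, "tubing_segment")) segments <- list(segments)
  if (!is.list(segments) || length(segments) < 1 ||
      !all(vapply(segments, inherits, logical(1), "tubing_segment"))) {
    stop("segments must be a non-empty list of tubing_segment objects",
         call. = FALSE)
  }
  if (!is.numeric(min_pressure) || length(min_pressure) != 1 ||
      !is.finite(min_pressure) || min_pressure < 0) {
    stop("min_pressure must be a single non-negative number (Pa)",
         call. = FALSE)
  }
  structure(list(name = as.character(name)[1],
                 segments = segments,
                 min_pressure = min_pressure),
            class = "injection_system")
}

#' Pressure settings for an injection
#'
#' Machine (injection) pressure and ambient pressure in the cavity the cannula
#' discharges into (the intraocular pressure surrogate). Both are gauge
#' pressures, i.e. relative to atmosphere.
#'
#' @param machine_pressure Injection pressure set on the vitrectomy machine (>= 0).
#' @param ambient_pressure Ambient chamber/intraocular pressure (>= 0, default 0).
#' @param unit Unit of both inputs: `"Pa"` (default), `"psi"`, `"mmHg"` or `"hPa"`.
#' @return An object of class `pressure_state` with pressures in Pa.
#' @examples
#' pressure_state(6, 15 / 51.7149, unit = "psi") # 6 psi machine, ~15 mmHg ambient
#' pressure_state(convert_pressure(6, "psi"), convert_pressure(15, "mmHg"))
#' @export
pressure_state <- function(machine_pressure, ambient_pressure = 0, unit = "Pa") {
  p <- convert_pressure(machine_pressure, unit)
  pam <- convert_pressure(ambient_pressure, unit)
  if (!is.numeric(p) || length(p) != 1 || !is.finite(p) || p < 0) {
    stop("machine_pressure must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(pam) || length(pam) != 1 || !is.finite(pam) || pam < 0) {
    stop("ambient_pressure must be a single non-negative number", call. = FALSE)
  }
  structure(list(machine_pressure = p, ambient_pressure = pam),
            class = "pressure_state")
}

#' @export
print.tubing_segment <- function(x, ...) {
  cat(sprintf("<tubing_segment> %s: D = %.4g mm, L = %.4g mm\n",
              x$label, x$inner_diameter * 1e3, x$length * 1e3))
  invisible(x)
}

#' @export
print.injection_system <- function(x, ...) {
  cat(sprintf("<injection_system> %s (%d segment%s, P_min = %.2f psi)\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              length(x$segments), if (length(x$segments) == 1) "" else "s",
              convert_pressure(x$min_pressure, "Pa", "psi")))
  for (s in x$segments) {
    cat(sprintf("  %-45s D = %.4g mm  L = %.4g mm\n",
                s$label, s$inner_diameter * 1e3, s$length * 1e3))
  }
  invisible(x)
}

#' Read an injection-system configuration file
#'
#' Reads the JSON configuration schema
#' `{"name", "min_pressure_psi", "segments": [{"label", "inner_diameter_mm",
#' "length_mm"}, ...]}` with segments listed proximal to distal.
#'
#' @param path Path to a JSON config file.
#' @return An [injection_system()].
#' @export
read_system_config <- function(path) {
  if (!file.exists(path)) {
    stop("system config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$segments) || length(cfg$segments) == 0) {
    stop("system config ", path, " has no segments; expected schema ",
         '{"name", "min_pressure_psi", "segments": ',
         '[{"label", "inner_diameter_mm", "length_mm"}]}', call. = FALSE)
  }
  segs <- lapply(cfg$segments, function(s) {
    tubing_segment(s$label, s$inner_diameter_mm, s$length_mm, unit = "mm")
  })
  minp <- if (is.null(cfg$min_pressure_psi)) 5 else cfg$min_pressure_psi
  injection_system(segs,
                   min_pressure = convert_pressure(minp, "psi"),
                   name = if (is.null(cfg$name)) "" else cfg$name)
}

#' Write an injection-system configuration file
#'
#' @param system An [injection_system()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_system_config <- function(system, path) {
  stopifnot(inherits(system, "injection_system"))
  cfg <- list(
    name = system$name,
    min_pressure_psi = convert_pressure(system$min_pressure, "Pa", "psi"),
    segments = lapply(system$segments, function(s) {
      list(label = s$label,
           inner_diameter_mm = s$inner_diameter * 1e3,
           length_mm = s$length * 1e3)
    })
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Packaged commercial injection-system presets
#'
#' Loads one of the shipped configurations for commercially available
#' subretinal cannulas assembled with the proximal needle section and a 5 cm
#' extension tube:
#' * `"model3219"` — 5 mm long, 41g (0.071 mm) polyamide tip;
#' * `"model3255"` — 2 mm long, 41g polyamide tip;
#' * `"model3263"` — 0.6 mm long, 51g metal tip. Its inner diameter is not
#'   published; the packaged value (~0.028 mm) is back-calculated from the
#'   published flow-rate table via [back_calculate_diameter()] and the preset is
#'   flagged as synthetic.
#'
#' @param name Preset name.
#' @return An [injection_system()].
#' @export
system_preset <- function(name = c("model3219", "model3255", "model3263")) {
  name <- match.arg(name)
  file <- switch(name,
    model3219 = "model3219.json",
    model3255 = "model3255.json",
    model3263 = "model3263_synthetic.json"
  )
  path <- system.file("extdata", "systems", file, package = "subflowr",
                      mustWork = TRUE)
  read_system_config(path)
}
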