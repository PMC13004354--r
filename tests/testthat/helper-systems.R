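# In-code builders for the standard injection setups, independent of the
# packaged JSON presets so the presets can be cross-checked against them.

water <- function() fluid_spec(1e-3)

psi <- function(x) convert_pressure(x, "psi")
mmHg <- function(x) convert_pressure(x, "mmHg")

extension_segment <- function() tubing_segment("extension", 0.5, 150, unit = "mm")
needle_segment <- function() tubing_segment("needle", 0.26, 35, unit = "mm")

make_3219 <- function() {
  injection_system(
    list(extension_segment(), needle_segment(),
         tubing_segment("41g tip 5 mm", 0.071, 5, unit = "mm")),
    min_pressure = psi(5), name = "model3219")
}

make_3255 <- function() {
  injection_system(
    list(extension_segment(), needle_segment(),
         tubing_segment("41g tip 2 mm", 0.071, 2, unit = "mm")),
    min_pressure = psi(5), name = "model3255")
}

make_partial <- function() {
  # everything but the distal tip, for back-calculation tests
  injection_system(list(extension_segment(), needle_segment()),
                   min_pressure = psi(5), name = "partial")
}

# Independent Poiseuille oracle, written out directly from the formula.
poiseuille <- function(d_m, l_m, mu = 1e-3) 128 * mu * l_m / (pi * d_m^4)

tip_diameter <- function(system) {
  system$segments[[length(system$segments)]]$inner_diameter
}
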