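# Shared fixtures, built once per test run. Seed 42 pins the toy complex
# used across module tests.

fx_spec <- fixture_spec(seed = 42)
fx_pigments <- make_toy_complex(fx_spec)
fx_library <- make_toy_spectral_library(fx_spec)

# a minimal hand-built chlorophyll-like pigment: Mg at `center`, Q axis
# NB->ND along `axis`, B axis NA->NC along `axis_b`
toy_chl <- function(site_id = "601", center = c(0, 0, 0),
                    axis = c(0, 0, 1), axis_b = c(1, 0, 0),
                    class = "CHL_A") {
  atoms <- data.frame(
    atom_name = c("MG", "NB", "ND", "NA", "NC"),
    element = c("MG", "N", "N", "N", "N"),
    x = c(center[1], center[1] - axis[1], center[1] + axis[1],
          center[1] - axis_b[1], center[1] + axis_b[1]),
    y = c(center[2], center[2] - axis[2], center[2] + axis[2],
          center[2] - axis_b[2], center[2] + axis_b[2]),
    z = c(center[3], center[3] - axis[3], center[3] + axis[3],
          center[3] - axis_b[3], center[3] + axis_b[3]),
    stringsAsFactors = FALSE)
  p <- pigmentnet:::new_pigment(site_id, "A", class, tolower(class), atoms)
  p$center <- pigment_center(p)
  p
}

# a narrow rectangular-ish irradiance of unit area centred at `center_nm`
unit_area_narrow_irradiance <- function(center_nm = 550, half_width = 1) {
  g <- seq(center_nm - 2 * half_width, center_nm + 2 * half_width, 0.1)
  v <- ifelse(abs(g - center_nm) <= half_width, 1 / (2 * half_width), 0)
  spectrum_new(g, v, "wavelength_nm", "irradiance_photon_flux")
}
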