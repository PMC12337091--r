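# Seeded synthetic fixtures: toy pigment geometries, Gaussian-band spectral
# libraries, shift tables and analytic irradiance curves, so every pipeline
# stage runs and is testable without any download. Band parameters are
# chosen so the qualitative orderings seen in real antenna complexes
# manifest (Soret/Q coupling ratio, Stokes-shift asymmetry of the overlap
# densities, accessory-pigment Soret-band energy sink); they are documented
# conventions, not fits.

# Run code under a seed without touching global random state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

#' Default band parameters for the synthetic spectral library
#'
#' Per class and band: peak wavelength (nm), Gaussian width sigma (cm^-1),
#' Stokes shift (cm^-1), transition-dipole magnitude (Debye) and peak molar
#' extinction (M^-1 cm^-1). Q bands sit in the 550-700 nm window and Soret
#' (B) bands in the blue, with Soret extinction exceeding Q extinction;
#' accessory-chlorophyll Soret bands are red-shifted relative to Chl a's so
#' they act as Soret-band energy sinks; the carotenoid is one broad bright
#' band overlapping the Chl Soret window, and its "Q" entries describe the
#' strongly relaxed state 0.8 eV below it.
#'
#' @return Nested list `params[[class]][[band]]`.
#' @export
default_band_parameters <- function() {
  list(
    CHL_A = list(
      Q = list(peak_nm = 662, width_cm1 = 320, stokes_cm1 = 250,
               dipole_d = 6.45, eps_peak = 9.0e4),
      B = list(peak_nm = 430, width_cm1 = 900, stokes_cm1 = 600,
               dipole_d = 12.9, eps_peak = 1.15e5)),
    CHL_B = list(
      Q = list(peak_nm = 645, width_cm1 = 320, stokes_cm1 = 250,
               dipole_d = 5.5, eps_peak = 6.0e4),
      B = list(peak_nm = 460, width_cm1 = 900, stokes_cm1 = 600,
               dipole_d = 11.0, eps_peak = 1.5e5)),
    CHL_C1 = list(
      Q = list(peak_nm = 630, width_cm1 = 320, stokes_cm1 = 250,
               dipole_d = 4.5, eps_peak = 4.0e4),
      B = list(peak_nm = 460, width_cm1 = 900, stokes_cm1 = 600,
               dipole_d = 12.0, eps_peak = 1.8e5)),
    CRT = list(
      Q = list(peak_nm = NA, width_cm1 = 1500, stokes_cm1 = 500,
               dipole_d = 3.0, eps_peak = 0),
      B = list(peak_nm = 490, width_cm1 = 1500, stokes_cm1 = 2000,
               dipole_d = 13.0, eps_peak = 1.4e5))
  )
}

#' Fixture specification for the synthetic complex
#'
#' Defaults describe a CP24-like monomer: 11 chlorophylls (6 Chl a + 5
#' Chl b) plus 3 carotenoids packed in a 40 Angstrom box with pigment
#' centers at least 10 Angstrom apart (typical nearest-neighbour Mg-Mg
#' distances in plant antenna complexes).
#'
#' @param seed Integer seed; the generators are pure functions of the spec.
#' @param n_chl_a,n_chl_b,n_chl_c1,n_crt Pigment counts.
#' @param box_ang Cubic box edge (Angstrom).
#' @param min_dist_ang Minimum inter-center distance (Angstrom).
#' @param band_parameters Nested list; see [default_band_parameters()].
#' @return Object of class `"pn_fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_chl_a = 6L, n_chl_b = 5L,
                         n_chl_c1 = 0L, n_crt = 3L, box_ang = 40,
                         min_dist_ang = 10,
                         band_parameters = default_band_parameters()) {
  stopifnot(n_chl_a >= 0, n_chl_b >= 0, n_chl_c1 >= 0, n_crt >= 0,
            min_dist_ang > 0, box_ang > 0)
  structure(list(seed = as.integer(seed), n_chl_a = as.integer(n_chl_a),
                 n_chl_b = as.integer(n_chl_b),
                 n_chl_c1 = as.integer(n_chl_c1),
                 n_crt = as.integer(n_crt), box_ang = box_ang,
                 min_dist_ang = min_dist_ang,
                 band_parameters = band_parameters),
            class = "pn_fixture_spec")
}

#' Gaussian band spectrum
#'
#' A Gaussian in the wavenumber domain, rendered on a wavelength grid
#' covering +/- 5 sigma around the peak at ~0.25 nm spacing.
#'
#' @param center_nm Peak wavelength (nm, > 0).
#' @param width_cm1 Gaussian sigma in cm^-1 (> 0).
#' @param amplitude Peak value (default 1).
#' @param value_kind Value semantics (default `"absorbance"`).
#' @return A `pn_spectrum` on a wavelength grid.
#' @export
make_gaussian_band <- function(center_nm, width_cm1, amplitude = 1,
                               value_kind = "absorbance") {
  stopifnot(center_nm > 0, width_cm1 > 0)
  nu0 <- 1e7 / center_nm
  nu_lo <- nu0 - 5 * width_cm1
  nu_hi <- nu0 + 5 * width_cm1
  if (nu_lo <= 0) nu_lo <- nu0 / 100
  lam <- seq(1e7 / nu_hi, 1e7 / nu_lo, by = 0.25)
  nu <- 1e7 / lam
  vals <- amplitude * exp(-(nu - nu0)^2 / (2 * width_cm1^2))
  spectrum_new(lam, vals, "wavelength_nm", value_kind)
}

# Synthetic atoms for one toy pigment: a Chl gets an Mg at the center plus
# four macrocycle-style nitrogens (NB->ND the Q axis, NA->NC the B axis);
# a Crt gets a straight polyene carbon chain whose ends (C1, C99) define
# both axes and whose carbons define the centroid.
toy_pigment_atoms <- function(class, center, axis_u, axis_w) {
  if (class == "CRT") {
    ts <- seq(-7, 7, length.out = 9L)
    xyz <- t(vapply(ts, function(t) center + t * axis_u, numeric(3)))
    nm <- c("C1", paste0("C", 2:8), "C99")
    return(data.frame(atom_name = nm, element = "C",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE))
  }
  pts <- rbind(MG = center,
               NB = center - 2 * axis_u, ND = center + 2 * axis_u,
               `NA` = center - 2 * axis_w, NC = center + 2 * axis_w)
  data.frame(atom_name = c("MG", "NB", "ND", "NA", "NC"),
             element = c("MG", "N", "N", "N", "N"),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a toy pigment complex
#'
#' Seeded rejection sampling of pigment centers in a cubic box honouring a
#' minimum inter-center distance; each pigment receives a random orientation
#' realized as synthetic atoms, so the default axis table applies. The same
#' spec (seed included) always yields an identical complex.
#'
#' @param spec A `pn_fixture_spec`.
#' @param max_tries Rejection-sampling retry bound per pigment.
#' @return List of `pn_pigment` (Chl a, then Chl b, then Chl c1, then Crt).
#' @export
make_toy_complex <- function(spec, max_tries = 5000L) {
  classes <- c(rep("CHL_A", spec$n_chl_a), rep("CHL_B", spec$n_chl_b),
               rep("CHL_C1", spec$n_chl_c1), rep("CRT", spec$n_crt))
  if (!length(classes)) stop("fixture spec contains zero pigments")
  subtypes <- c(CHL_A = "chl_a", CHL_B = "chl_b", CHL_C1 = "chl_c1",
                CRT = "lutein")
  with_seed(spec$seed, {
    centers <- matrix(NA_real_, length(classes), 3L)
    for (i in seq_along(classes)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- stats::runif(3, 0, spec$box_ang)
        if (i == 1L ||
            min(sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                                matrix(cand, i - 1L, 3L,
                                       byrow = TRUE))^2))) >=
              spec$min_dist_ang) {
          centers[i, ] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("packing infeasible: could not place pigment ", i,
             " after ", max_tries, " tries")
    }
    pigments <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      w0 <- stats::rnorm(3)
      w <- w0 - sum(w0 * u) * u
      w <- w / sqrt(sum(w^2))
      p <- new_pigment(site_id = sprintf("%d", 600L + i),
                       chain_id = "A",
                       pigment_class = classes[i],
                       subtype = subtypes[[classes[i]]],
                       atoms = toy_pigment_atoms(classes[i], centers[i, ],
                                                 u, w),
                       monomer_index = 1L)
      p$center <- pigment_center(p)
      pigments[[i]] <- p
    }
    pigments
  })
}

#' Generate the synthetic spectral library
#'
#' Gaussian Q and Soret (B) absorption bands per class with Stokes-shifted
#' emissions and matching extinction spectra, built from the spec's band
#' parameters. The carotenoid contributes one broad bright band in the
#' Soret window; its relaxed-state ("Q") spectra are that band shifted
#' 0.8 eV to lower energy. Peak positions and dipole magnitudes are stored
#' alongside the spectra.
#'
#' @param spec A `pn_fixture_spec`.
#' @return A `pn_spectral_library`.
#' @export
make_toy_spectral_library <- function(spec = fixture_spec()) {
  lib <- spectral_library()
  for (class in names(spec$band_parameters)) {
    pars <- spec$band_parameters[[class]]
    for (band in c("Q", "B")) {
      p <- pars[[band]]
      if (class == "CRT" && band == "Q") {
        # relaxed Crt state: bright band shifted down by 0.8 eV
        pb <- pars$B
        nu_q <- 1e7 / pb$peak_nm - 0.8 * .CM1_PER_EV
        peak_nm <- 1e7 / nu_q
        width <- pb$width_cm1
        stokes <- p$stokes_cm1
        dip <- p$dipole_d
        eps <- p$eps_peak
      } else {
        peak_nm <- p$peak_nm
        width <- p$width_cm1
        stokes <- p$stokes_cm1
        dip <- p$dipole_d
        eps <- p$eps_peak
      }
      ab <- make_gaussian_band(peak_nm, width, 1, "absorbance")
      em <- approximate_emission(ab, stokes_shift_cm1 = stokes)
      lib <- spectral_library_set(lib, class, band, "absorption", ab,
                                  peak_nm = peak_nm, dipole_d = dip)
      lib <- spectral_library_set(lib, class, band, "emission", em)
      if (eps > 0) {
        ex <- make_gaussian_band(peak_nm, width, eps, "extinction_M1cm1")
        lib <- spectral_library_set(lib, class, band, "extinction", ex)
      }
    }
  }
  lib
}

#' Dipole set for a pigment list from a spectral library
#'
#' Builds one `pn_dipole` per pigment for a band: direction from the axis
#' table, magnitude from the library, origin at the pigment center.
#'
#' @param pigments List of `pn_pigment`.
#' @param library A `pn_spectral_library` carrying dipole magnitudes.
#' @param band `"Q"` or `"B"`.
#' @param axis_table Axis table; see [default_axis_table()].
#' @return Named list of `pn_dipole` keyed by `paste(chain_id, site_id)`.
#' @export
dipoles_from_library <- function(pigments, library, band,
                                 axis_table = default_axis_table()) {
  out <- lapply(pigments, function(p) {
    transition_dipole(
      site_id = p$site_id, band = band,
      direction = dipole_axis(p, band, axis_table),
      magnitude = spectral_library_dipole(library, p$pigment_class, band),
      origin = if (is.null(p$center)) pigment_center(p) else p$center)
  })
  names(out) <- vapply(pigments, function(p) paste(p$chain_id, p$site_id),
                       "")
  out
}

#' Generate a synthetic site-shift table
#'
#' Seeded small Gaussian shifts (sd 0.02 eV, well inside the usual +/-0.1 eV
#' protein-pocket range) for each site and band.
#'
#' @param pigments List of `pn_pigment`.
#' @param seed Integer seed.
#' @param sd_ev Shift standard deviation in eV.
#' @return data.frame with site_id, band, shift_cm1.
#' @export
make_toy_shift_table <- function(pigments, seed = 1L, sd_ev = 0.02) {
  ids <- vapply(pigments, function(p) p$site_id, "")
  with_seed(seed + 7L, {
    do.call(rbind, lapply(c("Q", "B"), function(band) {
      data.frame(site_id = ids, band = band,
                 shift_cm1 = stats::rnorm(length(ids),
                                          0, sd_ev * .CM1_PER_EV),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Analytic solar irradiance fixtures
#'
#' `"surface"`: a 5800 K blackbody-shaped photon flux over 300-850 nm,
#' standing in for sea-level noon sunlight. `"depth"`: the surface curve
#' attenuated through 100 m of water with a diffuse attenuation coefficient
#' rising with wavelength (red light extinguished first), leaving a
#' blue-dominated spectrum.
#'
#' @param kind `"surface"` or `"depth"`.
#' @param depth_m Depth for the `"depth"` scene (default 100).
#' @return Irradiance `pn_spectrum` (relative photon-flux units).
#' @export
make_toy_irradiance <- function(kind = c("surface", "depth"),
                                depth_m = 100) {
  kind <- match.arg(kind)
  lam <- seq(300, 850, 1)
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kB <- 1.380649e-23
  T <- 5800
  lm <- lam * 1e-9
  # spectral photon flux ~ B_lambda / (hc/lambda) up to a constant
  flux <- 1 / (lm^4 * (exp(h * c0 / (lm * kB * T)) - 1))
  flux <- flux / max(flux)
  surface <- spectrum_new(lam, flux, "wavelength_nm",
                          "irradiance_photon_flux",
                          label = "synthetic surface, noon")
  if (kind == "surface") return(surface)
  K <- spectrum_new(lam, 0.02 + 0.004 * pmax((lam - 450) / 100, 0)^2,
                    "wavelength_nm", "absorbance", label = "toy K(lambda)")
  attenuate_irradiance(surface, depth_m, K)
}
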