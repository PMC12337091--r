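# Lambert-Beer absorbance of a pigment ensemble under a solar spectrum and
# per-class contribution analysis.
#
# A(lambda) = cl_factor * sum_g n_g eps_g(lambda); the absorbed-photon score
# over a window is P = int I(lambda) (1 - 10^-A) dlambda. Contributions of
# a class are fractions of the wild-type absorbed photons, under either a
# remove variant (carotenoids: they are simply added on top of the Chls) or
# a substitute-by-Chl-a variant (accessory chlorophylls: they replace
# Chl a sites).

#' Pigment census
#'
#' @param counts Named integer vector: pigment class (or subtype) -> count
#'   per complex.
#' @param cl_factor Dimensionless concentration x path-length scaling of
#'   the absorbance (no molar units are claimed).
#' @return Object of class `"pn_census"`.
#' @export
pigment_census <- function(counts, cl_factor = 1e-6) {
  counts <- unlist(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("census counts must be non-negative integers")
  structure(list(counts = counts, cl_factor = cl_factor),
            class = "pn_census")
}

#' Census from a pigment list
#'
#' @param pigments List of `pn_pigment`.
#' @param cl_factor See [pigment_census()].
#' @return A `pn_census` with per-class counts.
#' @export
census_from_pigments <- function(pigments, cl_factor = 1e-6) {
  cls <- vapply(pigments, function(p) p$pigment_class, "")
  pigment_census(table(cls), cl_factor = cl_factor)
}

# Total extinction of a class over both bands on a target grid (zero-filled
# outside each band's support).
class_extinction_on_grid <- function(library, class, grid) {
  total <- numeric(length(grid))
  found <- FALSE
  for (band in c("Q", "B")) {
    s <- tryCatch(spectral_library_get(library, class, band, "extinction"),
                  error = function(e) NULL)
    if (is.null(s)) next
    found <- TRUE
    total <- total + resample_fill0(s, grid)$values
  }
  if (!found)
    stop("no extinction spectrum in library for class ", class)
  total
}

#' Ensemble absorbance of a pigment census
#'
#' @param census A `pn_census`.
#' @param library A `pn_spectral_library` with extinction spectra for every
#'   counted class.
#' @param grid Wavelength grid (nm) for the result (default 350-800 nm at
#'   1 nm).
#' @return Absorbance `pn_spectrum` `A(lambda) = cl * sum_g n_g eps_g`.
#' @export
ensemble_absorbance <- function(census, library, grid = seq(350, 800, 1)) {
  A <- numeric(length(grid))
  for (g in names(census$counts)) {
    n_g <- census$counts[[g]]
    if (n_g == 0) next
    A <- A + n_g * class_extinction_on_grid(library, g, grid)
  }
  spectrum_new(grid, census$cl_factor * A, "wavelength_nm", "absorbance",
               label = "ensemble")
}

#' Absorbed-photon score under an irradiance spectrum
#'
#' `P = int_window I(lambda) (1 - 10^(-A(lambda))) dlambda`, trapezoidal
#' on the irradiance grid restricted to the window; monotone and concave
#' in the absorbance scaling.
#'
#' @param absorbance Absorbance `pn_spectrum`.
#' @param irradiance Irradiance `pn_spectrum` (photon-flux units).
#' @param window Length-2 wavelength window (nm) inside both grids.
#' @return Scalar score (irradiance units x nm).
#' @export
absorbed_photons <- function(absorbance, irradiance,
                             window = c(350, 800)) {
  stopifnot(length(window) == 2L)
  lo <- min(window); hi <- max(window)
  if (window[1] >= window[2])
    stop("absorbed_photons: malformed window (lo >= hi)")
  keep <- irradiance$grid >= lo & irradiance$grid <= hi
  if (sum(keep) < 2L)
    stop("absorbed_photons: window contains fewer than 2 irradiance points")
  g <- irradiance$grid[keep]
  I <- irradiance$values[keep]
  A <- resample_fill0(absorbance, g)$values
  y <- I * (1 - 10^(-A))
  sum(diff(g) * (y[-length(y)] + y[-1]) / 2)
}

# Variant census for a class: remove it, or substitute its counts into the
# Chl a pool.
variant_census <- function(census, class, mode) {
  counts <- census$counts
  if (!class %in% names(counts))
    stop("class ", class, " not present in census")
  if (mode == "remove") {
    counts[[class]] <- 0L
  } else {
    counts[["CHL_A"]] <- (if ("CHL_A" %in% names(counts))
      counts[["CHL_A"]] else 0L) + counts[[class]]
    counts[[class]] <- 0L
  }
  pigment_census(counts, cl_factor = census$cl_factor)
}

#' Absorption contribution of one pigment class
#'
#' `contribution(g) = [P(WT) - P(variant)] / P(WT)` where the variant
#' either removes class g (the carotenoid convention: Crts are additions on
#' top of the chlorophylls) or replaces g's counts by Chl a counts (the
#' accessory-chlorophyll convention: Chls b/c occupy sites a Chl a could).
#'
#' @param census Wild-type `pn_census`.
#' @param library Spectral library with extinction spectra.
#' @param irradiance Irradiance `pn_spectrum`.
#' @param window Wavelength window (nm).
#' @param class Class to perturb.
#' @param mode `"remove"` or `"substitute_chl_a"`.
#' @param grid Absorbance evaluation grid.
#' @return Scalar fraction of wild-type absorbed photons (can be negative
#'   in substitute mode if the variant absorbs more).
#' @export
class_contribution <- function(census, library, irradiance,
                               window = c(350, 800), class,
                               mode = c("remove", "substitute_chl_a"),
                               grid = seq(350, 800, 1)) {
  mode <- match.arg(mode)
  if (!class %in% names(census$counts) || census$counts[[class]] == 0)
    return(0)
  p_wt <- absorbed_photons(ensemble_absorbance(census, library, grid),
                           irradiance, window)
  if (p_wt <= 0)
    stop("class_contribution: wild-type absorbed photons is zero; undefined")
  vc <- variant_census(census, class, mode)
  p_var <- absorbed_photons(ensemble_absorbance(vc, library, grid),
                            irradiance, window)
  (p_wt - p_var) / p_wt
}

#' Attenuate a surface irradiance to depth
#'
#' `I(lambda, z) = I0(lambda) exp(-K(lambda) z)` with K the diffuse
#' attenuation coefficient (per m). K is resampled onto the irradiance
#' grid (zero outside its support).
#'
#' @param surface Surface irradiance `pn_spectrum`.
#' @param depth_m Depth in m (>= 0).
#' @param attenuation `pn_spectrum` of K(lambda) in 1/m.
#' @return Attenuated irradiance `pn_spectrum`.
#' @export
attenuate_irradiance <- function(surface, depth_m, attenuation) {
  if (depth_m < 0) stop("depth must be >= 0")
  K <- resample_fill0(attenuation, surface$grid)$values
  spectrum_new(surface$grid, surface$values * exp(-K * depth_m),
               "wavelength_nm", "irradiance_photon_flux",
               label = paste0(surface$label %||% "surface",
                              " @ ", depth_m, " m"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
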