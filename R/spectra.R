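# Spectrum container and spectral-overlap machinery.
#
# A spectrum is a light S3 object: a strictly increasing grid (wavelength in
# nm or wavenumber in cm^-1) with non-negative values. The density of
# interacting states rho between a donor emission and an acceptor absorption
# is computed as the wavenumber-domain overlap of the two area-normalized
# line shapes, in units of cm, which is the form that feeds the golden-rule
# rate k = 4 pi^2 c V^2 rho.

#' Construct a spectrum
#'
#' @param grid Numeric vector, strictly increasing; wavelength (nm) or
#'   wavenumber (cm^-1) axis.
#' @param values Non-negative numeric vector, same length as `grid`.
#' @param axis_kind One of `"wavelength_nm"`, `"wavenumber_cm1"`.
#' @param value_kind One of `"absorbance"`, `"extinction_M1cm1"`,
#'   `"emission"`, `"irradiance_photon_flux"`.
#' @param label Optional character label (e.g. a scene description for
#'   irradiance spectra).
#' @return Object of class `"pn_spectrum"`.
#' @export
#' @examples
#' s <- spectrum_new(400:700, rep(1, 301))
#' spectrum_area(s)
spectrum_new <- function(grid, values,
                         axis_kind = c("wavelength_nm", "wavenumber_cm1"),
                         value_kind = c("absorbance", "extinction_M1cm1",
                                        "emission", "irradiance_photon_flux"),
                         label = NULL) {
  axis_kind <- match.arg(axis_kind)
  value_kind <- match.arg(value_kind)
  grid <- as.numeric(grid)
  values <- as.numeric(values)
  if (length(grid) < 2L)
    stop("spectrum grid must have length >= 2")
  if (length(values) != length(grid))
    stop("grid and values must have equal length")
  if (any(!is.finite(grid)) || any(!is.finite(values)))
    stop("spectrum grid and values must be finite")
  if (any(diff(grid) <= 0))
    stop("spectrum grid must be strictly increasing")
  if (any(values < 0))
    stop("spectrum values must be non-negative")
  structure(list(grid = grid, values = values, axis_kind = axis_kind,
                 value_kind = value_kind, label = label),
            class = "pn_spectrum")
}

#' @export
print.pn_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s on %s [%g, %g], %d points%s\n",
              x$value_kind, x$axis_kind, min(x$grid), max(x$grid),
              length(x$grid),
              if (is.null(x$label)) "" else paste0(" (", x$label, ")")))
  invisible(x)
}

#' Trapezoidal area under a spectrum
#'
#' @param spectrum A `pn_spectrum`.
#' @return Scalar integral of values over the grid.
#' @export
spectrum_area <- function(spectrum) {
  g <- spectrum$grid; v <- spectrum$values
  sum(diff(g) * (v[-length(v)] + v[-1]) / 2)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; the target grid must lie inside the source range
#' (no extrapolation). Interpolated values are clipped at zero.
#'
#' @param spectrum A `pn_spectrum`.
#' @param target_grid Strictly increasing numeric vector within the source
#'   grid's range.
#' @return A `pn_spectrum` on `target_grid`.
#' @export
resample <- function(spectrum, target_grid) {
  target_grid <- as.numeric(target_grid)
  if (min(target_grid) < min(spectrum$grid) - 1e-9 ||
      max(target_grid) > max(spectrum$grid) + 1e-9)
    stop(sprintf("resample: target grid [%g, %g] outside source range [%g, %g]",
                 min(target_grid), max(target_grid),
                 min(spectrum$grid), max(spectrum$grid)))
  v <- stats::approx(spectrum$grid, spectrum$values, xout = target_grid,
                     rule = 1)$y
  v[is.na(v)] <- 0   # only possible at range edges within tolerance
  if (length(target_grid) == 1L)  # point query: skip the length-2 invariant
    return(structure(list(grid = target_grid, values = max(v, 0),
                          axis_kind = spectrum$axis_kind,
                          value_kind = spectrum$value_kind,
                          label = spectrum$label),
                     class = "pn_spectrum"))
  spectrum_new(target_grid, pmax(v, 0), spectrum$axis_kind,
               spectrum$value_kind, spectrum$label)
}

# Resample with zero fill outside the source support; used where spectra with
# different supports are summed (ensemble absorbance) or overlapped.
resample_fill0 <- function(spectrum, target_grid) {
  v <- stats::approx(spectrum$grid, spectrum$values, xout = target_grid,
                     rule = 1)$y
  v[is.na(v)] <- 0
  spectrum_new(as.numeric(target_grid), pmax(v, 0), spectrum$axis_kind,
               spectrum$value_kind, spectrum$label)
}

#' Convert a wavelength spectrum to the wavenumber domain
#'
#' Maps the axis via nu = 1e7 / lambda (nm to cm^-1) and re-sorts the grid
#' increasing. With `jacobian = TRUE` values that are densities per nm are
#' multiplied by lambda^2/1e7 so integrals are conserved under the change of
#' variables; with `jacobian = FALSE` the values are carried over unchanged
#' (shape-only conversion, appropriate for absorbance/extinction read at
#' fixed wavelengths).
#'
#' @param spectrum A `pn_spectrum` with `axis_kind = "wavelength_nm"`.
#' @param jacobian Logical; apply the lambda^2/1e7 density Jacobian.
#' @return A `pn_spectrum` on a wavenumber grid.
#' @export
to_wavenumber <- function(spectrum, jacobian = FALSE) {
  if (spectrum$axis_kind != "wavelength_nm")
    stop("to_wavenumber: spectrum is not on a wavelength axis")
  if (any(spectrum$grid <= 0))
    stop("to_wavenumber: wavelengths must be positive")
  nu <- 1e7 / spectrum$grid
  v <- spectrum$values
  if (jacobian) v <- v * spectrum$grid^2 / 1e7
  o <- order(nu)
  spectrum_new(nu[o], v[o], "wavenumber_cm1", spectrum$value_kind,
               spectrum$label)
}

#' Normalize a spectrum to unit area
#'
#' @param spectrum A `pn_spectrum` with positive trapezoidal area.
#' @return A `pn_spectrum` integrating to 1 on its own grid.
#' @export
normalize_area <- function(spectrum) {
  a <- spectrum_area(spectrum)
  if (a <= 0)
    stop("normalize_area: spectrum has zero area")
  spectrum_new(spectrum$grid, spectrum$values / a, spectrum$axis_kind,
               spectrum$value_kind, spectrum$label)
}

# Internal: bring a spectrum to the wavenumber domain as an area-normalized
# line shape. Wavelength-domain inputs are treated as densities per nm
# (jacobian on) so the normalized shape is grid-convention independent.
lineshape_wavenumber <- function(spectrum) {
  s <- if (spectrum$axis_kind == "wavelength_nm")
    to_wavenumber(spectrum, jacobian = TRUE) else spectrum
  normalize_area(s)
}

#' Density of interacting states between two pigments
#'
#' Computes rho = integral of the area-normalized acceptor absorption line
#' shape times the area-normalized donor emission line shape over their
#' common wavenumber grid (trapezoidal; common grid = intersection of
#' supports at the finer spacing). Units: cm. This quantity enters the
#' golden-rule EET rate as k = 4 pi^2 c V^2 rho.
#'
#' @param acceptor_abs Acceptor absorption spectrum (`pn_spectrum`).
#' @param donor_em Donor emission spectrum (`pn_spectrum`).
#' @return Scalar rho >= 0 in cm. Disjoint supports give 0 with a warning.
#' @export
#' @examples
#' g <- make_gaussian_band(660, 300)
#' density_of_states(g, g)  # self-overlap
density_of_states <- function(acceptor_abs, donor_em) {
  a <- lineshape_wavenumber(acceptor_abs)
  f <- lineshape_wavenumber(donor_em)
  lo <- max(min(a$grid), min(f$grid))
  hi <- min(max(a$grid), max(f$grid))
  if (lo >= hi) {
    warning("density_of_states: zero spectral overlap between the line shapes")
    return(0)
  }
  step <- min(stats::median(diff(a$grid)), stats::median(diff(f$grid)))
  grid <- seq(lo, hi, by = step)
  if (length(grid) < 2L) grid <- c(lo, hi)
  av <- resample_fill0(a, grid)$values
  fv <- resample_fill0(f, grid)$values
  prod_v <- av * fv
  rho <- sum(diff(grid) * (prod_v[-length(prod_v)] + prod_v[-1]) / 2)
  if (rho <= 0)
    warning("density_of_states: zero spectral overlap between the line shapes")
  max(rho, 0)
}

#' Diagnostic lambda^4-weighted overlap ratio
#'
#' The wavelength-domain ratio
#' `int a(l) F(l) l^4 dl / int a(l) F(l) dl`, retained as a diagnostic of the
#' lambda^4 weighting that depresses B-band overlaps relative to Q-band ones.
#' Not used by the rate kernel; [density_of_states()] is.
#'
#' @param acceptor_abs,donor_em `pn_spectrum` objects on wavelength axes.
#' @return Scalar in nm^4, or `NA` if the supports are disjoint.
#' @export
rho_lambda4_ratio <- function(acceptor_abs, donor_em) {
  stopifnot(acceptor_abs$axis_kind == "wavelength_nm",
            donor_em$axis_kind == "wavelength_nm")
  lo <- max(min(acceptor_abs$grid), min(donor_em$grid))
  hi <- min(max(acceptor_abs$grid), max(donor_em$grid))
  if (lo >= hi) return(NA_real_)
  grid <- seq(lo, hi, length.out = 2048L)
  av <- resample_fill0(acceptor_abs, grid)$values
  fv <- resample_fill0(donor_em, grid)$values
  trap <- function(y) sum(diff(grid) * (y[-length(y)] + y[-1]) / 2)
  denom <- trap(av * fv)
  if (denom <= 0) return(NA_real_)
  trap(av * fv * grid^4) / denom
}

#' Approximate an emission line shape from an absorption band
#'
#' Shifts the absorption line shape to lower energy by a Stokes shift;
#' optionally mirrors it about its 0-0 position (taken as the line-shape
#' maximum) first. Used where no experimental emission spectrum exists,
#' notably for the Soret band. The result is area-normalized.
#'
#' @param abs_spectrum Absorption `pn_spectrum` (nm or cm^-1 axis).
#' @param stokes_shift_cm1 Non-negative Stokes shift in cm^-1.
#' @param mirror Logical; reflect the shape about its peak before shifting.
#' @return Emission `pn_spectrum` on a wavenumber grid, unit area.
#' @export
approximate_emission <- function(abs_spectrum, stokes_shift_cm1 = 0,
                                 mirror = FALSE) {
  if (stokes_shift_cm1 < 0)
    stop("approximate_emission: Stokes shift must be >= 0")
  s <- lineshape_wavenumber(abs_spectrum)
  grid <- s$grid
  values <- s$values
  if (mirror) {
    pivot <- grid[which.max(values)]
    grid <- rev(2 * pivot - grid)
    values <- rev(values)
  }
  grid <- grid - stokes_shift_cm1
  out <- spectrum_new(grid, values, "wavenumber_cm1", "emission",
                      abs_spectrum$label)
  normalize_area(out)
}

#' Transition-dipole strength from an extinction band
#'
#' Integrates the extinction coefficient over a wavelength window as
#' `|mu|^2 = C_cal / n * int eps(nu)/nu dnu` and returns |mu| in Debye.
#' `C_cal` is the standard integrated-absorption calibration constant
#' 9.186e-3 D^2 M cm per (the dimensionless integral), fixed once; see the
#' methods vignette for the convention and its refractive-index handling.
#'
#' @param extinction Extinction `pn_spectrum` (M^-1 cm^-1 vs nm).
#' @param band_window Length-2 numeric `(nm_lo, nm_hi)` inside the grid.
#' @param n Refractive index of the medium (default 1.4).
#' @param c_cal Calibration constant (D^2 per unit of the reduced integral).
#' @return Dipole strength |mu| in Debye.
#' @export
dipole_strength_from_band <- function(extinction, band_window, n = 1.4,
                                      c_cal = 9.186e-3) {
  stopifnot(length(band_window) == 2L)
  lo <- min(band_window); hi <- max(band_window)
  if (hi <= lo) stop("dipole_strength_from_band: empty band window")
  keep <- extinction$grid >= lo & extinction$grid <= hi
  if (sum(keep) < 2L)
    stop("dipole_strength_from_band: window contains fewer than 2 grid points")
  sub <- spectrum_new(extinction$grid[keep],
                      extinction$values[keep] + 0,  # copy
                      extinction$axis_kind, extinction$value_kind)
  if (all(sub$values == 0)) return(0)
  w <- to_wavenumber(sub, jacobian = FALSE)
  y <- w$values / w$grid
  integral <- sum(diff(w$grid) * (y[-length(y)] + y[-1]) / 2)
  sqrt(c_cal * integral / n)
}

#' Read a two-column spectrum file
#'
#' Delimited text: first column wavelength (nm), second column value.
#' Lines starting with `#` are comments. Rows are sorted by wavelength and
#' duplicate wavelengths averaged.
#'
#' @param path File path.
#' @param value_kind Value semantics; see [spectrum_new()].
#' @param label Optional label.
#' @return A `pn_spectrum`.
#' @export
read_spectrum <- function(path, value_kind = "absorbance", label = NULL) {
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("wavelength_nm", "value"))
  if (nrow(d) < 2L) stop("read_spectrum: fewer than 2 data rows in ", path)
  agg <- stats::aggregate(value ~ wavelength_nm, data = d, FUN = mean)
  agg <- agg[order(agg$wavelength_nm), ]
  spectrum_new(agg$wavelength_nm, pmax(agg$value, 0), "wavelength_nm",
               value_kind, label)
}

#' Write a spectrum as two-column delimited text
#'
#' @param spectrum A `pn_spectrum`.
#' @param path Output path.
#' @param header Optional comment lines (without leading `#`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in c(header, paste("axis:", spectrum$axis_kind),
              paste("values:", spectrum$value_kind)))
    writeLines(paste("#", h), con)
  utils::write.table(
    data.frame(x = formatC(spectrum$grid, format = "g", digits = 10),
               y = formatC(spectrum$values, format = "g", digits = 10)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
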