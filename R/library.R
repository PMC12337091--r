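# Spectral library: per-class (or subtype), per-band spectra and band peak
# positions. Roles: absorption (line shape for rho), emission (donor side),
# extinction (M^-1 cm^-1, for dipole strengths and Lambert-Beer absorbance).

#' Construct an empty spectral library
#'
#' @return Object of class `"pn_spectral_library"`.
#' @export
spectral_library <- function() {
  structure(list(spectra = list(), peaks = list(), dipoles = list()),
            class = "pn_spectral_library")
}

.lib_key <- function(class, band, role) paste(class, band, role, sep = "|")

#' Insert a spectrum into a library
#'
#' @param library A `pn_spectral_library`.
#' @param class Pigment class or subtype key.
#' @param band `"Q"` or `"B"`.
#' @param role `"absorption"`, `"emission"` or `"extinction"`.
#' @param spectrum A `pn_spectrum`.
#' @param peak_nm Optional band peak position (nm), stored per (class, band).
#' @param dipole_d Optional transition-dipole magnitude (Debye) per
#'   (class, band).
#' @return The updated library.
#' @export
spectral_library_set <- function(library, class, band, role, spectrum,
                                 peak_nm = NULL, dipole_d = NULL) {
  stopifnot(inherits(library, "pn_spectral_library"),
            inherits(spectrum, "pn_spectrum"),
            role %in% c("absorption", "emission", "extinction"))
  library$spectra[[.lib_key(class, band, role)]] <- spectrum
  if (!is.null(peak_nm)) library$peaks[[paste(class, band)]] <- peak_nm
  if (!is.null(dipole_d)) library$dipoles[[paste(class, band)]] <- dipole_d
  library
}

#' Fetch a spectrum from a library
#'
#' @inheritParams spectral_library_set
#' @return The stored `pn_spectrum`; error naming the missing entry
#'   otherwise.
#' @export
spectral_library_get <- function(library, class, band, role) {
  s <- library$spectra[[.lib_key(class, band, role)]]
  if (is.null(s))
    stop("spectral library has no ", role, " spectrum for class ", class,
         " band ", band)
  s
}

#' Band peak position stored in a library
#'
#' @param library A `pn_spectral_library`.
#' @param class,band Lookup keys.
#' @return Peak wavelength in nm.
#' @export
spectral_library_peak <- function(library, class, band) {
  p <- library$peaks[[paste(class, band)]]
  if (is.null(p))
    stop("spectral library has no peak position for class ", class,
         " band ", band)
  p
}

#' Dipole magnitude stored in a library
#'
#' @param library A `pn_spectral_library`.
#' @param class,band Lookup keys.
#' @return Dipole strength in Debye.
#' @export
spectral_library_dipole <- function(library, class, band) {
  d <- library$dipoles[[paste(class, band)]]
  if (is.null(d))
    stop("spectral library has no dipole magnitude for class ", class,
         " band ", band)
  d
}

#' @export
print.pn_spectral_library <- function(x, ...) {
  cat(sprintf("<spectral library> %d spectra, %d peak entries, %d dipole entries\n",
              length(x$spectra), length(x$peaks), length(x$dipoles)))
  if (length(x$spectra))
    cat(paste(" ", names(x$spectra), collapse = "\n"), "\n")
  invisible(x)
}

#' Load a spectral library from a manifest
#'
#' The manifest is a YAML (or already-parsed list) of entries with fields
#' `class`, `band`, `role`, `path`, and optional `peak_nm`, `dipole_d`,
#' `value_kind`. Paths are resolved relative to the manifest file.
#'
#' @param manifest_path Path to a YAML manifest, or a list of entries.
#' @param base_dir Directory against which relative paths resolve
#'   (defaults to the manifest's directory).
#' @return A `pn_spectral_library`.
#' @export
read_spectral_library <- function(manifest_path, base_dir = NULL) {
  if (is.character(manifest_path)) {
    entries <- yaml::read_yaml(manifest_path)
    if (is.null(base_dir)) base_dir <- dirname(manifest_path)
  } else {
    entries <- manifest_path
    if (is.null(base_dir)) base_dir <- "."
  }
  lib <- spectral_library()
  for (e in entries) {
    vk <- if (!is.null(e$value_kind)) e$value_kind
          else if (e$role == "extinction") "extinction_M1cm1"
          else if (e$role == "emission") "emission" else "absorbance"
    p <- if (file.exists(e$path)) e$path else file.path(base_dir, e$path)
    sp <- read_spectrum(p, value_kind = vk,
                        label = paste(e$class, e$band, e$role))
    lib <- spectral_library_set(lib, e$class, e$band, e$role, sp,
                                peak_nm = e$peak_nm, dipole_d = e$dipole_d)
  }
  lib
}
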