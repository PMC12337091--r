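# Golden-rule EET rates and efficiencies.
#
# k_FRET = 2 pi / hbar |V|^2 rho realized in spectroscopic units as
# k = 4 pi^2 c V^2 rho (V in cm^-1, rho in cm, c in cm/s, k returned in
# ns^-1). Efficiencies are branching ratios of summed EET rates against
# summed EET plus internal-conversion (IC) rates.

#' Golden-rule FRET rate
#'
#' @param v_cm1 Coupling V in cm^-1 (sign irrelevant; enters squared).
#' @param rho_cm Density of interacting states in cm (>= 0).
#' @return Rate in ns^-1.
#' @export
#' @examples
#' fret_rate(38, 450.05e-6)  # ~769 ns^-1
fret_rate <- function(v_cm1, rho_cm) {
  if (any(rho_cm < 0)) stop("fret_rate: rho must be >= 0")
  4 * pi^2 * .SPEED_OF_LIGHT_CM_S * v_cm1^2 * rho_cm * 1e-9
}

#' Default internal-conversion lifetimes
#'
#' Q-band Chl a lifetime 6.3 ns (Q -> S0); B-band lifetime 100 fs for all
#' Chl classes (B -> Q; the low end of reported values, biasing against
#' EET); carotenoid S2 decay 0.15 ps (sub-ps range). All overridable.
#'
#' @return Nested named list: `model[[class]][[band]]` = tau in ns.
#' @export
default_ic_model <- function() {
  chl <- list(Q = 6.3, B = 100e-6)
  list(CHL_A = chl, CHL_B = chl, CHL_C1 = chl,
       CRT = list(Q = 150e-6, B = 150e-6))
}

#' Internal-conversion rate for a class and band
#'
#' @param ic_model Nested list from [default_ic_model()] (tau in ns).
#' @param pigment_class,band Lookup keys.
#' @return 1/tau in ns^-1.
#' @export
ic_rate <- function(ic_model, pigment_class, band) {
  tau <- ic_model[[pigment_class]][[band]]
  if (is.null(tau))
    stop("no IC lifetime configured for class ", pigment_class,
         " band ", band)
  if (tau <= 0) stop("IC lifetime must be positive")
  1 / tau
}

#' EET efficiency against internal conversion
#'
#' `E = sum(k_FRET) / (sum(k_FRET) + sum(k_IC))`; all EET channels compete
#' with the donor's IC process(es).
#'
#' @param fret_rates Numeric vector of EET rates (ns^-1, >= 0).
#' @param ic_rates Non-empty numeric vector of IC rates (ns^-1, >= 0).
#' @return Efficiency in [0, 1); strictly < 1 when any IC rate is positive.
#' @export
#' @examples
#' eet_efficiency(768, 1 / 6.3)            # > 0.999
#' eet_efficiency(1855, 1 / 100e-6)        # ~0.156
#' eet_efficiency(rep(1855, 10), 1e4)      # ~0.650
eet_efficiency <- function(fret_rates, ic_rates) {
  if (!length(ic_rates)) stop("eet_efficiency: no IC rates supplied")
  if (any(fret_rates < 0) || any(ic_rates < 0))
    stop("eet_efficiency: rates must be >= 0")
  tot_f <- sum(fret_rates)
  tot <- tot_f + sum(ic_rates)
  if (tot == 0) stop("eet_efficiency: all rates are zero; undefined")
  tot_f / tot
}

# rho per ordered (donor class, acceptor class) pair from a spectral
# library, cached at class granularity: per-site spectra are out of scope.
class_pair_rho <- function(library, donor_class, acceptor_class, band) {
  em <- spectral_library_get(library, donor_class, band, "emission")
  ab <- spectral_library_get(library, acceptor_class, band, "absorption")
  suppressWarnings(density_of_states(ab, em))
}

#' Per-donor-site EET rates and efficiencies
#'
#' For every donor site, computes the golden-rule rate to every other site
#' from the pair's coupling and the class-level density of states, and the
#' efficiency of the summed EET channels against the donor's single IC
#' rate.
#'
#' @param coupling A `pn_coupling` (fixes band and site order).
#' @param library A `pn_spectral_library` with absorption and emission
#'   spectra for every class in play.
#' @param ic_model Nested lifetime list; see [default_ic_model()].
#' @return List with `rates` (data.frame: donor, acceptor, donor_class,
#'   acceptor_class, band, v_cm1, rho_cm, k_ns1) and `efficiency`
#'   (data.frame: donor, donor_class, k_eet_total_ns1, k_ic_ns1,
#'   efficiency).
#' @export
site_eet_summary <- function(coupling, library, ic_model = default_ic_model()) {
  ids <- coupling$site_ids
  cls <- coupling$classes
  band <- coupling$band
  N <- length(ids)
  rho_cache <- new.env(parent = emptyenv())
  get_rho <- function(dc, ac) {
    key <- paste(dc, ac, sep = "->")
    if (is.null(rho_cache[[key]]))
      rho_cache[[key]] <- class_pair_rho(library, dc, ac, band)
    rho_cache[[key]]
  }
  rows <- list()
  eff <- list()
  for (i in seq_len(N)) {
    ks <- numeric(0)
    for (j in seq_len(N)) {
      if (i == j) next
      rho <- get_rho(cls[i], cls[j])
      k <- fret_rate(coupling$V[i, j], rho)
      rows[[length(rows) + 1L]] <- data.frame(
        donor = ids[i], acceptor = ids[j], donor_class = cls[i],
        acceptor_class = cls[j], band = band,
        v_cm1 = coupling$V[i, j], rho_cm = rho, k_ns1 = k,
        stringsAsFactors = FALSE)
      ks <- c(ks, k)
    }
    kic <- ic_rate(ic_model, cls[i], band)
    e <- if (length(ks) && (sum(ks) + kic) > 0)
      eet_efficiency(ks, kic) else 0
    eff[[length(eff) + 1L]] <- data.frame(
      donor = ids[i], donor_class = cls[i],
      k_eet_total_ns1 = sum(ks), k_ic_ns1 = kic, efficiency = e,
      stringsAsFactors = FALSE)
  }
  list(rates = do.call(rbind, rows), efficiency = do.call(rbind, eff))
}

#' Write a rate table as delimited text
#'
#' @param rates data.frame from [site_eet_summary()]`$rates`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
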