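# The central model object: one call builds the band-resolved coupling
# matrices, golden-rule rate tables and per-donor EET efficiencies, the
# excitonic Hamiltonians and their delocalization scores for a pigment
# complex, under a spectral library, site-shift table and IC lifetime
# model.

#' Fit the semiempirical Forster/exciton model to a pigment complex
#'
#' For each requested band this computes: transition dipoles (axis-table
#' directions, library magnitudes), the screened point-dipole coupling
#' matrix, class-pair coupling averages, golden-rule EET rates and
#' per-donor efficiencies against internal conversion, site energies
#' (experimental band maxima plus site shifts), the excitonic Hamiltonian
#' and its eigendecomposition with per-exciton inverse participation
#' ratios.
#'
#' @param pigments List of `pn_pigment`, e.g. from [parse_pigment_sites()]
#'   or [make_toy_complex()].
#' @param library A `pn_spectral_library`.
#' @param shifts Optional site-shift data.frame (site_id, band, shift_cm1);
#'   missing sites get zero shift, B-band entries fall back to Q-band ones.
#' @param bands Character subset of `c("Q", "B")`.
#' @param n Refractive index of the medium (default 1.4).
#' @param ic_model Nested IC lifetime list; see [default_ic_model()].
#' @param axis_table Axis table; see [default_axis_table()].
#' @param crt_q_participation Logical; let relaxed carotenoid states enter
#'   the Q-band Hamiltonian (default TRUE, flagged in reports).
#' @param multimer_order Integer q >= 1 used for class-pair average scaling.
#' @param label Configuration label carried into reports (default `"WT"`).
#' @return Object of class `"eet_model"` with one entry per band
#'   (`coupling`, `class_averages`, `rates`, `efficiency`,
#'   `site_energies`, `hamiltonian`, `excitons`) plus the call inputs.
#' @export
#' @examples
#' spec <- fixture_spec(seed = 42)
#' fit <- eet_model(make_toy_complex(spec), make_toy_spectral_library(spec))
#' summary(fit)
eet_model <- function(pigments, library, shifts = NULL,
                      bands = c("Q", "B"), n = 1.4,
                      ic_model = default_ic_model(),
                      axis_table = default_axis_table(),
                      crt_q_participation = TRUE,
                      multimer_order = 1L, label = "WT") {
  stopifnot(length(pigments) >= 1L, all(bands %in% c("Q", "B")))
  lbl <- attr(pigments, "label")
  if (!is.null(lbl)) label <- lbl
  per_band <- list()
  for (band in bands) {
    pigs <- pigments
    if (band == "Q" && !crt_q_participation) {
      pigs <- Filter(function(p) p$pigment_class != "CRT", pigments)
      if (!length(pigs))
        stop("no pigments left in the Q band network without Crts")
    }
    dip <- dipoles_from_library(pigs, library, band, axis_table)
    cm <- coupling_matrix(pigs, dip, band, n = n)
    eps <- vapply(seq_along(pigs), function(i) {
      p <- pigs[[i]]
      site_energy(p$pigment_class, band, library,
                  shift_cm1 = lookup_shift(shifts, p$site_id, band),
                  crt_rule = TRUE)
    }, numeric(1))
    ham <- build_hamiltonian(eps, cm)
    kin <- site_eet_summary(cm, library, ic_model)
    per_band[[band]] <- list(
      coupling = cm,
      class_averages = class_pair_averages(cm, q = multimer_order),
      rates = kin$rates,
      efficiency = kin$efficiency,
      site_energies = stats::setNames(eps, cm$site_ids),
      hamiltonian = ham,
      excitons = diagonalize(ham))
  }
  structure(list(bands = per_band, pigments = pigments, library = library,
                 shifts = shifts, n = n, ic_model = ic_model,
                 multimer_order = as.integer(multimer_order),
                 crt_q_participation = crt_q_participation,
                 label = label),
            class = "eet_model")
}

#' @export
print.eet_model <- function(x, ...) {
  cls <- vapply(x$pigments, function(p) p$pigment_class, "")
  cat(sprintf("Semiempirical Forster/exciton model ('%s'): %d pigments (%s), n = %.2f\n",
              x$label, length(x$pigments),
              paste(sprintf("%d %s", as.vector(table(cls)),
                            names(table(cls))), collapse = ", "),
              x$n))
  for (band in names(x$bands)) {
    b <- x$bands[[band]]
    off <- b$coupling$V[upper.tri(b$coupling$V)]
    cat(sprintf("  band %s: mean |V| = %.2f cm^-1, mean E_EET = %.3f, mean IPR^-1 = %.2f\n",
                band, if (length(off)) mean(abs(off)) else 0,
                mean(b$efficiency$efficiency), mean(b$excitons$ipr_inv)))
  }
  invisible(x)
}

#' Summarize a fitted Forster/exciton model
#'
#' @param object An `eet_model`.
#' @param ... Unused.
#' @return Object of class `"summary.eet_model"`: per-band class-pair
#'   coupling averages, efficiency table, exciton energy range and
#'   mean/max IPR^-1.
#' @export
summary.eet_model <- function(object, ...) {
  out <- lapply(names(object$bands), function(band) {
    b <- object$bands[[band]]
    list(band = band,
         class_averages = b$class_averages,
         efficiency = b$efficiency,
         energy_range = range(b$excitons$energies),
         mean_ipr_inv = mean(b$excitons$ipr_inv),
         sem_ipr_inv = stats::sd(b$excitons$ipr_inv) /
           sqrt(length(b$excitons$ipr_inv)),
         max_ipr_inv = max(b$excitons$ipr_inv))
  })
  names(out) <- names(object$bands)
  structure(list(label = object$label, n_pigments = length(object$pigments),
                 bands = out),
            class = "summary.eet_model")
}

#' @export
print.summary.eet_model <- function(x, ...) {
  cat(sprintf("Configuration '%s', %d pigments\n", x$label, x$n_pigments))
  for (b in x$bands) {
    cat(sprintf("\nBand %s\n", b$band))
    cat(sprintf("  exciton energies: %.0f .. %.0f cm^-1; mean IPR^-1 = %.2f (SEM %.2f, max %.2f)\n",
                b$energy_range[1], b$energy_range[2], b$mean_ipr_inv,
                b$sem_ipr_inv, b$max_ipr_inv))
    cat("  class-pair average couplings (cm^-1):\n")
    ca <- b$class_averages
    for (i in seq_len(nrow(ca)))
      cat(sprintf("    %-7s - %-7s  %8.2f  (SEM %.2f, %d pairs)\n",
                  ca$class_1[i], ca$class_2[i], ca$mean_v[i], ca$sem[i],
                  ca$n_pairs[i]))
    cat(sprintf("  donor EET efficiencies: mean %.3f, min %.3f, max %.3f\n",
                mean(b$efficiency$efficiency), min(b$efficiency$efficiency),
                max(b$efficiency$efficiency)))
  }
  invisible(x)
}

#' Site energies of a fitted model
#'
#' @param object An `eet_model`.
#' @param band Band to extract (default first fitted).
#' @param ... Unused.
#' @return Named numeric vector of site energies (cm^-1).
#' @export
coef.eet_model <- function(object, band = names(object$bands)[1], ...) {
  object$bands[[band]]$site_energies
}

#' Plot a fitted Forster/exciton model
#'
#' Base-graphics panel per band: exciton energies (ascending) with point
#' size scaled by delocalization (IPR^-1).
#'
#' @param x An `eet_model`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.eet_model <- function(x, ...) {
  nb <- length(x$bands)
  old <- graphics::par(mfrow = c(1, nb))
  on.exit(graphics::par(old))
  for (band in names(x$bands)) {
    e <- x$bands[[band]]$excitons
    graphics::plot(seq_along(e$energies), e$energies,
                   cex = 0.5 + e$ipr_inv / max(e$ipr_inv) * 1.5,
                   xlab = "exciton (ascending)",
                   ylab = expression(energy ~ (cm^-1)),
                   main = sprintf("band %s ('%s')", band, x$label), ...)
  }
  invisible(x)
}

#' Refit a model under a pigment-configuration variant
#'
#' @param object A fitted `eet_model`.
#' @param config A configuration directive; see
#'   [standard_configurations()].
#' @return A new `eet_model` fitted to the perturbed pigment set, labelled
#'   by the configuration.
#' @export
refit_configuration <- function(object, config) {
  eet_model(apply_configuration(object$pigments, config), object$library,
            shifts = object$shifts, bands = names(object$bands),
            n = object$n, ic_model = object$ic_model,
            crt_q_participation = object$crt_q_participation,
            multimer_order = object$multimer_order)
}
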