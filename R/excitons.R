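# Excitonic Hamiltonians, delocalization scoring, and pigment-configuration
# perturbation experiments.
#
# H has the site excitation energies on the diagonal and the Forster
# couplings off-diagonal (all cm^-1). Eigenvectors give per-pigment weights
# (squared coefficients); delocalization per exciton is scored by the
# inverse participation ratio IPR^-1 = 1 / sum(c_i^4), ranging from 1
# (localized) to N (uniform).

#' Site excitation energy for a class and band
#'
#' Chlorophylls: 1e7 / lambda_max(nm) plus the site shift. Carotenoids,
#' band B: the energy of the lowest-energy peak of the bright carotenoid
#' band (approximately the 0-0 excitation). Carotenoids, band Q with
#' `crt_rule = TRUE`: that value minus 0.8 eV, modelling the strongly
#' relaxed carotenoid state that can mix into the Q-band energy range.
#'
#' @param pigment_class Class key.
#' @param band `"Q"` or `"B"`.
#' @param library A `pn_spectral_library` holding band peak positions.
#' @param shift_cm1 Site shift in cm^-1 (use [shift_to_cm1()] for eV input).
#' @param crt_rule Logical; apply the 0.8 eV relaxation rule for Crt Q
#'   energies.
#' @return Site energy in cm^-1.
#' @export
#' @examples
#' # 662 nm, no shift -> ~15106 cm^-1
site_energy <- function(pigment_class, band, library, shift_cm1 = 0,
                        crt_rule = TRUE) {
  if (pigment_class == "CRT") {
    e_b <- 1e7 / spectral_library_peak(library, "CRT", "B")
    e <- if (band == "Q" && crt_rule) e_b - 0.8 * .CM1_PER_EV else e_b
    return(e + shift_cm1)
  }
  peak <- spectral_library_peak(library, pigment_class, band)
  1e7 / peak + shift_cm1
}

#' Convert a site shift to cm^-1
#'
#' @param value Shift magnitude.
#' @param unit `"cm1"` or `"eV"` (converted at 8065.544 cm^-1/eV).
#' @return Shift in cm^-1.
#' @export
shift_to_cm1 <- function(value, unit = c("cm1", "eV")) {
  unit <- match.arg(unit)
  if (unit == "eV") value * .CM1_PER_EV else value
}

#' Read a site-shift table
#'
#' Delimited text with columns `site_id`, `band`, `shift`, optional `unit`
#' (`cm1` default, `eV` accepted). Shifts larger than 0.1 eV in magnitude
#' draw a warning (site energies far outside the usual protein-pocket
#' range), never an error. When a site lacks a B-band entry its Q-band
#' shift is reused (the default adopted where no B-band source exists).
#'
#' @param path File path.
#' @return data.frame with site_id, band, shift_cm1.
#' @export
read_shift_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("site_id", "band", "shift")
  if (!all(need %in% names(d)))
    stop("shift table must have columns: ", paste(need, collapse = ", "))
  unit <- if ("unit" %in% names(d)) d$unit else rep("cm1", nrow(d))
  d$shift_cm1 <- mapply(shift_to_cm1, d$shift, unit)
  big <- abs(d$shift_cm1) > 0.1 * .CM1_PER_EV
  if (any(big))
    warning("site shift(s) exceed 0.1 eV in magnitude: ",
            paste(d$site_id[big], collapse = ", "))
  d$site_id <- as.character(d$site_id)
  d[c("site_id", "band", "shift_cm1")]
}

# Shift lookup with the B-falls-back-to-Q default.
lookup_shift <- function(shifts, site_id, band) {
  if (is.null(shifts)) return(0)
  hit <- shifts[shifts$site_id == site_id & shifts$band == band, ]
  if (nrow(hit)) return(hit$shift_cm1[1])
  if (band == "B") {
    hit <- shifts[shifts$site_id == site_id & shifts$band == "Q", ]
    if (nrow(hit)) return(hit$shift_cm1[1])
  }
  0
}

#' Build an excitonic Hamiltonian
#'
#' @param site_energies Numeric vector of site energies (cm^-1), in the
#'   coupling matrix's site order.
#' @param coupling A `pn_coupling`.
#' @return Object of class `"pn_hamiltonian"`: symmetric matrix `H`
#'   (diagonal = site energies, off-diagonal = couplings), `band`,
#'   `site_ids`, `classes`.
#' @export
build_hamiltonian <- function(site_energies, coupling) {
  N <- length(coupling$site_ids)
  if (length(site_energies) != N)
    stop("site-energy vector length (", length(site_energies),
         ") does not match coupling site order (", N, ")")
  if (any(!is.finite(site_energies)))
    stop("site energies must be finite")
  H <- coupling$V
  diag(H) <- site_energies
  H <- (H + t(H)) / 2
  structure(list(H = H, band = coupling$band,
                 site_ids = coupling$site_ids, classes = coupling$classes),
            class = "pn_hamiltonian")
}

#' Diagonalize an excitonic Hamiltonian
#'
#' Eigenvalues ascending; per-exciton pigment weights are the squared
#' eigenvector coefficients (each row sums to 1). Sign convention: the
#' largest-magnitude coefficient of each eigenvector is made positive;
#' within numerically degenerate blocks excitons are ordered by their
#' leading-weight site index, so reports are reproducible.
#'
#' @param hamiltonian A `pn_hamiltonian`.
#' @return Object of class `"pn_excitons"`: `energies` (cm^-1),
#'   `weights` (excitons x sites), `ipr_inv` per exciton, `site_ids`,
#'   `classes`, `band`.
#' @export
diagonalize <- function(hamiltonian) {
  H <- hamiltonian$H
  if (any(!is.finite(H))) stop("Hamiltonian has non-finite entries")
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  N <- length(vals)
  for (k in seq_len(N)) {
    lead <- which.max(abs(vecs[, k]))
    if (vecs[lead, k] < 0) vecs[, k] <- -vecs[, k]
  }
  # stable order inside degenerate blocks: by leading-weight site index
  if (N > 1L) {
    i <- 1L
    while (i < N) {
      j <- i
      while (j < N && abs(vals[j + 1L] - vals[i]) < 1e-9 * max(1, abs(vals[i])))
        j <- j + 1L
      if (j > i) {
        block <- i:j
        lead_idx <- apply(abs(vecs[, block, drop = FALSE]), 2, which.max)
        block_ord <- block[order(lead_idx)]
        vecs[, block] <- vecs[, block_ord]
        vals[block] <- vals[block_ord]
      }
      i <- j + 1L
    }
  }
  W <- t(vecs^2)
  dimnames(W) <- list(paste0("exciton_", seq_len(N)), hamiltonian$site_ids)
  structure(list(energies = vals, weights = W,
                 ipr_inv = apply(W, 1, ipr_inverse),
                 site_ids = hamiltonian$site_ids,
                 classes = hamiltonian$classes,
                 band = hamiltonian$band),
            class = "pn_excitons")
}

#' @export
print.pn_excitons <- function(x, ...) {
  cat(sprintf("<excitons> band %s, %d states, energies [%.1f, %.1f] cm^-1, mean IPR^-1 %.2f\n",
              x$band, length(x$energies), min(x$energies), max(x$energies),
              mean(x$ipr_inv)))
  invisible(x)
}

#' Inverse participation ratio of one exciton
#'
#' `IPR^-1 = 1 / sum(w_i^2)` where `w_i = c_i^2` are the pigment weights;
#' ranges from 1 (fully localized) to N (uniform over N pigments).
#'
#' @param weights Numeric weight vector summing to 1 (tolerance 1e-6).
#' @return Scalar in [1, N].
#' @export
#' @examples
#' ipr_inverse(c(0.5, 0.5, 0))  # 2
ipr_inverse <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-6)
    stop("ipr_inverse: weights must sum to 1 (got ", sum(weights), ")")
  if (any(weights < -1e-12)) stop("ipr_inverse: negative weight")
  1 / sum(weights^2)
}

#' Pigments carrying an exciton above a weight threshold
#'
#' The "exciton on pigment" assignment: sites with weight `c_i^2` at or
#' above the threshold (default 0.1).
#'
#' @param excitons A `pn_excitons`.
#' @param k Exciton index (ascending energy order).
#' @param threshold Minimum weight (default 0.1).
#' @return Character vector of site ids.
#' @export
exciton_sites <- function(excitons, k, threshold = 0.1) {
  w <- excitons$weights[k, ]
  names(w)[w >= threshold]
}

#' Standard pigment-configuration variants
#'
#' @return Named list of configuration directives: `WT` (unchanged),
#'   `ALL_CHL_A` (every Chl class replaced by Chl a), `NO_CRT` (carotenoids
#'   removed), `ALL_CHL_A_NO_CRT` (both).
#' @export
standard_configurations <- function() {
  list(
    WT = list(label = "WT", substitute = NULL, remove = character()),
    ALL_CHL_A = list(label = "ALL_CHL_A",
                     substitute = c(CHL_B = "CHL_A", CHL_C1 = "CHL_A"),
                     remove = character()),
    NO_CRT = list(label = "NO_CRT", substitute = NULL, remove = "CRT"),
    ALL_CHL_A_NO_CRT = list(label = "ALL_CHL_A_NO_CRT",
                            substitute = c(CHL_B = "CHL_A",
                                           CHL_C1 = "CHL_A"),
                            remove = "CRT")
  )
}

#' Apply a pigment-configuration perturbation
#'
#' Substitutions keep each site's geometry, center and axis atoms, swapping
#' only the spectral identity (class, hence site-energy source, dipole
#' magnitudes, rho class and IC lifetime). Removals drop sites of the
#' listed classes from the network entirely.
#'
#' @param pigments List of `pn_pigment` objects.
#' @param config A directive list with `label`, optional named character
#'   vector `substitute` (source class -> target class) and character
#'   vector `remove`; see [standard_configurations()].
#' @return Modified pigment list with attribute `label`.
#' @export
apply_configuration <- function(pigments, config) {
  subs <- config$substitute
  if (!is.null(subs) && any(names(subs) == subs))
    stop("configuration substitutes a class into itself")
  out <- list()
  for (p in pigments) {
    if (p$pigment_class %in% config$remove) next
    if (!is.null(subs) && p$pigment_class %in% names(subs)) {
      p$pigment_class <- subs[[p$pigment_class]]
      p$subtype <- tolower(p$pigment_class)
    }
    out[[length(out) + 1L]] <- p
  }
  if (!length(out))
    stop("configuration '", config$label, "' removes every pigment")
  attr(out, "label") <- config$label
  out
}
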