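# Point-dipole Forster couplings.
#
# V_ij = C_dip * kappa_ij * |mu_i||mu_j| / (n^2 R_ij^3), mu in Debye, R in
# nm, V in cm^-1, screened by the squared refractive index (default 1.4).
# kappa is the usual orientation factor in [-2, 2].

#' Construct a transition dipole
#'
#' @param site_id Site identifier.
#' @param band `"Q"` or `"B"`.
#' @param direction Length-3 vector; normalized internally.
#' @param magnitude Dipole strength in Debye (>= 0).
#' @param origin Length-3 xyz in Angstrom (the pigment center).
#' @return Object of class `"pn_dipole"`.
#' @export
transition_dipole <- function(site_id, band, direction, magnitude, origin) {
  stopifnot(band %in% c("Q", "B"), length(direction) == 3L,
            length(origin) == 3L, magnitude >= 0)
  nv <- sqrt(sum(direction^2))
  if (nv == 0) stop("transition dipole direction has zero length")
  structure(list(site_id = site_id, band = band,
                 direction = direction / nv,
                 magnitude = magnitude, origin = as.numeric(origin)),
            class = "pn_dipole")
}

#' Orientation factor kappa
#'
#' `kappa = u_i . u_j - 3 (u_i . r_hat)(u_j . r_hat)`, bounded in [-2, 2]
#' for unit inputs.
#'
#' @param u_i,u_j Unit 3-vectors (normalized internally).
#' @param r_ij Separation vector (any units; only the direction enters).
#' @return Scalar kappa.
#' @export
#' @examples
#' orientation_factor(c(0, 0, 1), c(0, 0, 1), c(0, 0, 5))  # -2
orientation_factor <- function(u_i, u_j, r_ij) {
  rn <- sqrt(sum(r_ij^2))
  if (rn == 0) stop("orientation_factor: zero separation vector")
  u_i <- u_i / sqrt(sum(u_i^2))
  u_j <- u_j / sqrt(sum(u_j^2))
  rh <- r_ij / rn
  sum(u_i * u_j) - 3 * sum(u_i * rh) * sum(u_j * rh)
}

#' Screened point-dipole coupling between two transition dipoles
#'
#' @param d_i,d_j `pn_dipole` objects of the same band with distinct origins.
#' @param n Refractive index of the medium (default 1.4).
#' @return Signed coupling V in cm^-1 (sign follows kappa).
#' @export
point_dipole_coupling <- function(d_i, d_j, n = 1.4) {
  if (d_i$band != d_j$band)
    stop("point_dipole_coupling: band mismatch (", d_i$band, " vs ",
         d_j$band, ")")
  r <- d_j$origin - d_i$origin
  r_ang <- sqrt(sum(r^2))
  if (r_ang == 0)
    stop("point_dipole_coupling: coincident origins for sites ",
         d_i$site_id, " and ", d_j$site_id)
  kappa <- orientation_factor(d_i$direction, d_j$direction, r)
  r_nm <- r_ang / 10
  .C_DIP_CM1_NM3_D2 * kappa * d_i$magnitude * d_j$magnitude /
    (n^2 * r_nm^3)
}

#' Pairwise coupling matrix for a pigment set
#'
#' @param pigments List of `pn_pigment` objects (defines site order).
#' @param dipoles Named list of `pn_dipole` keyed by
#'   `paste(chain_id, site_id)`; or a function `(pigment) -> pn_dipole`.
#' @param band `"Q"` or `"B"`.
#' @param n Refractive index.
#' @return Object of class `"pn_coupling"`: symmetric matrix `V` (cm^-1,
#'   zero diagonal), `band`, `site_ids`, `classes`.
#' @export
coupling_matrix <- function(pigments, dipoles, band, n = 1.4) {
  N <- length(pigments)
  keys <- vapply(pigments, function(p) paste(p$chain_id, p$site_id), "")
  dlist <- if (is.function(dipoles)) lapply(pigments, dipoles) else {
    missing <- setdiff(keys, names(dipoles))
    if (length(missing))
      stop("missing transition dipole for site(s): ",
           paste(missing, collapse = ", "))
    dipoles[keys]
  }
  V <- matrix(0, N, N, dimnames = list(keys, keys))
  if (N > 1L) for (i in 1:(N - 1L)) for (j in (i + 1L):N) {
    v <- point_dipole_coupling(dlist[[i]], dlist[[j]], n = n)
    V[i, j] <- v
    V[j, i] <- v
  }
  structure(list(V = V, band = band, site_ids = keys,
                 classes = vapply(pigments, function(p) p$pigment_class, ""),
                 monomer_index = vapply(pigments,
                                        function(p) p$monomer_index, 1L),
                 n = n),
            class = "pn_coupling")
}

#' @export
print.pn_coupling <- function(x, ...) {
  off <- x$V[upper.tri(x$V)]
  cat(sprintf("<coupling matrix> band %s, %d sites, mean |V| %.3g cm^-1, max |V| %.3g cm^-1\n",
              x$band, length(x$site_ids),
              if (length(off)) mean(abs(off)) else 0,
              if (length(off)) max(abs(off)) else 0))
  invisible(x)
}

# Canonical order for class-pair reports: CRT first, then Chl a/b/c1.
.CLASS_ORDER <- c("CRT", "CHL_A", "CHL_B", "CHL_C1")

#' Class-pair average couplings with multimer scaling
#'
#' For each unordered pair of pigment classes, averages the couplings over
#' all cross-pairs in the full assembly and multiplies by the multimeric
#' order `q` (3 for a trimer, 4 for a tetramer), making multimer averages
#' comparable to monomeric complexes despite the many near-zero
#' inter-subunit pairs. Same-class pairs use all within-class pairs.
#'
#' @param coupling A `pn_coupling`.
#' @param q Multimeric order, integer >= 1 (1 for monomers).
#' @param mode `"absolute"` (default; mean |V|, matching positive bar-style
#'   reports) or `"signed"` (diagnostic).
#' @return data.frame with class_1, class_2, n_pairs, mean_v (scaled,
#'   cm^-1), sem (scaled standard error of the mean), in canonical class
#'   order.
#' @export
class_pair_averages <- function(coupling, q = 1L, mode = c("absolute",
                                                           "signed")) {
  mode <- match.arg(mode)
  stopifnot(q >= 1L)
  cls <- coupling$classes
  present <- intersect(.CLASS_ORDER, unique(cls))
  out <- list()
  for (a_idx in seq_along(present)) for (b_idx in a_idx:length(present)) {
    ca <- present[a_idx]; cb <- present[b_idx]
    ia <- which(cls == ca); ib <- which(cls == cb)
    if (ca == cb) {
      if (length(ia) < 2L) next
      pairs <- t(utils::combn(ia, 2L))
    } else {
      pairs <- as.matrix(expand.grid(ia, ib))
    }
    v <- coupling$V[cbind(pairs[, 1], pairs[, 2])]
    if (mode == "absolute") v <- abs(v)
    m <- mean(v) * q
    sem <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) * q else 0
    out[[length(out) + 1L]] <- data.frame(
      class_1 = ca, class_2 = cb, n_pairs = length(v),
      mean_v = m, sem = sem, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(class_1 = character(), class_2 = character(),
                      n_pairs = integer(), mean_v = numeric(),
                      sem = numeric()))
  res <- do.call(rbind, out)
  attr(res, "band") <- coupling$band
  attr(res, "multimer_order") <- as.integer(q)
  attr(res, "mode") <- mode
  res
}
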