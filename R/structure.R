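# Pigment extraction from structure files.
#
# Pigments are hetero-residues (chlorophylls, carotenoids) pulled from a
# PDB or mmCIF structure via a residue map. Geometric conventions: a Chl's
# center is its Mg coordinate; a Crt's center is the unweighted centroid of
# its conjugated polyene carbons (equal masses, so centroid = center of
# mass). Transition-dipole axes run along named atom pairs (Qy / Bx style),
# configurable through an axis table.

.PIGMENT_CLASSES <- c("CHL_A", "CHL_B", "CHL_C1", "CRT")

#' Default residue-name map
#'
#' Maps common wwPDB chemical-component identifiers to pigment classes:
#' CLA -> Chl a, CHL -> Chl b, KC1/KC2 -> Chl c1, and the usual carotenoid
#' codes (LUT lutein, XAT violaxanthin, NEX neoxanthin, BCR beta-carotene,
#' DD6 diadinoxanthin, A86/FXA fucoxanthin) -> CRT with a subtype label.
#' This is a convention, not a claim about any particular deposition;
#' override or extend it per run.
#'
#' @return data.frame with columns `residue`, `pigment_class`, `subtype`.
#' @export
default_residue_map <- function() {
  data.frame(
    residue = c("CLA", "CHL", "KC1", "KC2",
                "LUT", "XAT", "NEX", "BCR", "DD6", "A86", "FXA"),
    pigment_class = c("CHL_A", "CHL_B", "CHL_C1", "CHL_C1",
                      rep("CRT", 7L)),
    subtype = c("chl_a", "chl_b", "chl_c1", "chl_c2",
                "lutein", "violaxanthin", "neoxanthin", "beta-carotene",
                "diadinoxanthin", "fucoxanthin", "fucoxanthin"),
    stringsAsFactors = FALSE
  )
}

#' Default transition-dipole axis table
#'
#' Ships placeholder conventions: chlorophyll Q axes along the NB->ND
#' macrocycle nitrogen trans-axis and B axes along NA->NC; carotenoid axes
#' along the polyene chain ends. Curated per-pigment atom pairs should be
#' loaded with [read_axis_table()] to override these defaults.
#'
#' @return data.frame with columns `pigment_class`, `band`, `atom_from`,
#'   `atom_to`.
#' @export
default_axis_table <- function() {
  data.frame(
    pigment_class = c("CHL_A", "CHL_A", "CHL_B", "CHL_B",
                      "CHL_C1", "CHL_C1", "CRT", "CRT"),
    band = rep(c("Q", "B"), 4L),
    atom_from = c("NB", "NA", "NB", "NA", "NB", "NA", "C1", "C1"),
    atom_to = c("ND", "NC", "ND", "NC", "ND", "NC", "C99", "C99"),
    stringsAsFactors = FALSE
  )
}

#' Read an axis table from delimited text
#'
#' Expected columns: pigment_class, band, atom_from, atom_to. Comment lines
#' start with `#`. The literal atom name "NA" is preserved (not parsed as
#' missing).
#'
#' @param path File path.
#' @return data.frame in [default_axis_table()] layout.
#' @export
read_axis_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  need <- c("pigment_class", "band", "atom_from", "atom_to")
  if (!all(need %in% names(d)))
    stop("axis table must have columns: ", paste(need, collapse = ", "))
  bad <- d$atom_from == d$atom_to
  if (any(bad))
    stop("axis table has identical atom pairs for: ",
         paste(d$pigment_class[bad], d$band[bad], collapse = "; "))
  d[need]
}

#' Read a residue map from delimited text
#'
#' Expected columns: residue, pigment_class, subtype.
#'
#' @param path File path.
#' @return data.frame in [default_residue_map()] layout.
#' @export
read_residue_map <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE, na.strings = "",
                         colClasses = "character")
  need <- c("residue", "pigment_class", "subtype")
  if (!all(need %in% names(d)))
    stop("residue map must have columns: ", paste(need, collapse = ", "))
  if (!all(d$pigment_class %in% .PIGMENT_CLASSES))
    stop("unknown pigment_class in residue map; allowed: ",
         paste(.PIGMENT_CLASSES, collapse = ", "))
  d[need]
}

new_pigment <- function(site_id, chain_id, pigment_class, subtype, atoms,
                        monomer_index = 1L) {
  stopifnot(pigment_class %in% .PIGMENT_CLASSES, nrow(atoms) > 0L)
  structure(list(site_id = site_id, chain_id = chain_id,
                 pigment_class = pigment_class, subtype = subtype,
                 atoms = atoms, center = NULL,
                 monomer_index = as.integer(monomer_index)),
            class = "pn_pigment")
}

#' @export
print.pn_pigment <- function(x, ...) {
  cat(sprintf("<pigment> %s chain %s class %s (%s), %d atoms\n",
              x$site_id, x$chain_id, x$pigment_class, x$subtype,
              nrow(x$atoms)))
  invisible(x)
}

#' Parse pigment sites from a structure file
#'
#' Reads a PDB or mmCIF file (dispatched on extension, or forced with
#' `format`), selects hetero-residues present in `residue_map`, and returns
#' one pigment per matched residue with its atoms, class, subtype, computed
#' center and a monomer index derived from chain grouping. Unmatched
#' hetero-residue names are collected in the `skipped` attribute, never
#' raised.
#'
#' @param path Structure file (.pdb or .cif).
#' @param residue_map data.frame from [default_residue_map()] /
#'   [read_residue_map()].
#' @param chain_filter Optional character vector of chain IDs to keep.
#' @param format `"auto"`, `"pdb"` or `"cif"`.
#' @return List of `pn_pigment` objects, ordered by chain then residue
#'   number, with attribute `skipped` (character vector of unmatched
#'   residue names).
#' @export
parse_pigment_sites <- function(path, residue_map = default_residue_map(),
                                chain_filter = NULL, format = "auto") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("unreadable structure file (", format, "): ",
                             conditionMessage(e)))
  at <- parsed$atom
  het <- at[at$type == "HETATM" | at$resid %in% residue_map$residue, ,
            drop = FALSE]
  if (!is.null(chain_filter))
    het <- het[het$chain %in% chain_filter, , drop = FALSE]
  matched <- het[het$resid %in% residue_map$residue, , drop = FALSE]
  skipped <- sort(unique(het$resid[!het$resid %in% residue_map$residue]))
  if (nrow(matched) == 0L)
    stop("no pigment residues matched the residue map in ", path)
  key <- paste(matched$chain, matched$resno, matched$resid, sep = "|")
  ord_keys <- unique(key[order(matched$chain, matched$resno)])
  chains <- sort(unique(matched$chain))
  pigments <- vector("list", length(ord_keys))
  for (i in seq_along(ord_keys)) {
    rows <- matched[key == ord_keys[i], , drop = FALSE]
    map_row <- residue_map[residue_map$residue == rows$resid[1], ][1, ]
    atoms <- data.frame(atom_name = rows$elety,
                        element = ifelse(is.na(rows$elesy) | rows$elesy == "",
                                         substr(gsub("[0-9']", "", rows$elety),
                                                1, 1),
                                         rows$elesy),
                        x = rows$x, y = rows$y, z = rows$z,
                        stringsAsFactors = FALSE)
    p <- new_pigment(site_id = paste0(rows$resno[1]),
                     chain_id = rows$chain[1],
                     pigment_class = map_row$pigment_class,
                     subtype = map_row$subtype,
                     atoms = atoms,
                     monomer_index = match(rows$chain[1], chains))
    p$center <- pigment_center(p)
    pigments[[i]] <- p
  }
  attr(pigments, "skipped") <- skipped
  pigments
}

# Conjugated-chain carbon selector for Crt centers: every carbon atom of the
# pigment by default (polyene chain), configurable by name list.
crt_conjugated_atoms <- function(pigment, conjugated_names = NULL) {
  a <- pigment$atoms
  if (!is.null(conjugated_names))
    return(a[a$atom_name %in% conjugated_names, , drop = FALSE])
  a[toupper(substr(a$element, 1, 1)) == "C", , drop = FALSE]
}

#' Geometric center of a pigment
#'
#' Chlorophyll classes: the Mg coordinate, exactly. Carotenoids: the
#' unweighted centroid of the conjugated carbon atoms (all carbons by
#' default; configurable name list).
#'
#' @param pigment A `pn_pigment`.
#' @param conjugated_names Optional character vector naming the Crt
#'   conjugated atoms.
#' @return Length-3 numeric xyz in Angstrom.
#' @export
pigment_center <- function(pigment, conjugated_names = NULL) {
  a <- pigment$atoms
  if (pigment$pigment_class == "CRT") {
    cc <- crt_conjugated_atoms(pigment, conjugated_names)
    if (nrow(cc) == 0L)
      stop("center undefined for Crt site ", pigment$site_id,
           ": no conjugated carbon atoms found")
    return(c(mean(cc$x), mean(cc$y), mean(cc$z)))
  }
  mg <- a[toupper(a$element) == "MG" | toupper(a$atom_name) == "MG", ,
          drop = FALSE]
  if (nrow(mg) != 1L)
    stop("center undefined for Chl site ", pigment$site_id,
         ": expected exactly one Mg atom, found ", nrow(mg))
  c(mg$x[1], mg$y[1], mg$z[1])
}

#' Transition-dipole axis of a pigment
#'
#' Unit vector from the first to the second atom named in the axis table for
#' the pigment's class and band. The sign convention (first -> second) is
#' fixed; couplings and rates are invariant under a joint sign flip.
#'
#' @param pigment A `pn_pigment`.
#' @param band `"Q"` or `"B"`.
#' @param axis_table data.frame from [default_axis_table()] or
#'   [read_axis_table()]. Rows with `pigment_class` equal to the pigment's
#'   site_id take precedence over class-level rows, allowing per-site
#'   overrides.
#' @return Unit length-3 numeric vector.
#' @export
dipole_axis <- function(pigment, band, axis_table = default_axis_table()) {
  row <- axis_table[axis_table$pigment_class == pigment$site_id &
                      axis_table$band == band, , drop = FALSE]
  if (nrow(row) == 0L)
    row <- axis_table[axis_table$pigment_class == pigment$pigment_class &
                        axis_table$band == band, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("no axis-table entry for class ", pigment$pigment_class,
         " band ", band)
  row <- row[1, ]
  a <- pigment$atoms
  from <- a[a$atom_name == row$atom_from, , drop = FALSE]
  to <- a[a$atom_name == row$atom_to, , drop = FALSE]
  if (nrow(from) == 0L || nrow(to) == 0L)
    stop("axis atoms ", row$atom_from, "/", row$atom_to,
         " missing on site ", pigment$site_id)
  v <- c(to$x[1] - from$x[1], to$y[1] - from$y[1], to$z[1] - from$z[1])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-6)
    stop("degenerate dipole axis on site ", pigment$site_id,
         ": atoms ", row$atom_from, " and ", row$atom_to, " coincide")
  v / nv
}

#' Export a pigment inventory as a data frame
#'
#' @param pigments List of `pn_pigment` objects.
#' @return data.frame with site_id, chain, class, subtype, center x/y/z and
#'   monomer index; one row per pigment.
#' @export
pigment_table <- function(pigments) {
  do.call(rbind, lapply(pigments, function(p) {
    ctr <- if (is.null(p$center)) pigment_center(p) else p$center
    data.frame(site_id = p$site_id, chain_id = p$chain_id,
               pigment_class = p$pigment_class, subtype = p$subtype,
               x = ctr[1], y = ctr[2], z = ctr[3],
               monomer_index = p$monomer_index, stringsAsFactors = FALSE)
  }))
}

#' Write a pigment set as a minimal PDB file
#'
#' HETATM records only; used to round-trip synthetic complexes through the
#' same reader the real pipeline uses.
#'
#' @param pigments List of `pn_pigment` objects.
#' @param path Output path.
#' @param residue_names Named character vector mapping pigment_class to a
#'   residue name (defaults consistent with [default_residue_map()]).
#' @return `path`, invisibly.
#' @export
write_pigments_pdb <- function(pigments, path,
                               residue_names = c(CHL_A = "CLA", CHL_B = "CHL",
                                                 CHL_C1 = "KC1", CRT = "LUT")) {
  lines <- character()
  serial <- 0L
  for (p in pigments) {
    res <- residue_names[[p$pigment_class]]
    for (k in seq_len(nrow(p$atoms))) {
      serial <- serial + 1L
      a <- p$atoms[k, ]
      lines <- c(lines, sprintf(
        "HETATM%5d %-4s %3s %1s%4s    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial, substr(a$atom_name, 1, 4), res, p$chain_id,
        p$site_id, a$x, a$y, a$z, toupper(a$element)))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
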