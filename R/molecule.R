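# Domain types: molecules, conformers, conformer libraries.
# Atoms are stored as a data.frame (one row per atom); bonds as a 2-column
# integer matrix of 1-based atom indices; proton groups as a named list of
# integer vectors (CH = 1 member, CH2 = 2, CH3 = 3).

#' Standard atomic masses (amu) for the elements the package handles
#' @keywords internal
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  F = 18.998, P = 30.974, Cl = 35.45, Br = 79.904, I = 126.904
)

#' Bondi van der Waals radii (Angstrom)
#' @keywords internal
.bondi_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  F = 1.47, P = 1.80, Cl = 1.75, Br = 1.85, I = 1.98
)

#' Look up atomic masses by element symbol
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in amu.
#' @export
atomic_mass <- function(elements) {
  m <- .atomic_masses[elements]
  if (anyNA(m)) {
    stop("unknown element(s): ",
         paste(unique(elements[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Look up Bondi van der Waals radii by element symbol
#'
#' @param elements character vector of element symbols.
#' @param override optional named numeric vector of per-element replacements.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(elements, override = NULL) {
  tab <- .bondi_radii
  if (!is.null(override)) tab[names(override)] <- override
  r <- tab[elements]
  if (anyNA(r)) {
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

#' Build an atom table
#'
#' Constructs the per-atom data.frame used inside a [molecule()]. Masses and
#' van der Waals radii are filled from internal element tables when not given.
#'
#' @param element character vector of element symbols.
#' @param name atom labels; defaults to `element` + index.
#' @param mass masses in amu; defaults to standard atomic weights.
#' @param charge partial charges in units of e; defaults to 0.
#' @param vdw van der Waals radii in Angstrom; defaults to the Bondi set.
#' @param is_hb_donor_h logical, TRUE for hydrogens that act as H-bond
#'   donor hydrogens (must be bonded to N/O/S).
#' @param is_hb_acceptor logical, TRUE for H-bond acceptor atoms.
#' @return data.frame with one row per atom.
#' @export
atom_table <- function(element, name = NULL, mass = NULL, charge = 0,
                       vdw = NULL, is_hb_donor_h = FALSE,
                       is_hb_acceptor = FALSE) {
  n <- length(element)
  if (is.null(name)) name <- paste0(element, seq_len(n))
  if (is.null(mass)) mass <- atomic_mass(element)
  if (is.null(vdw)) vdw <- vdw_radius(element)
  data.frame(
    element = element, name = name,
    mass = rep_len(mass, n), charge = rep_len(charge, n),
    vdw = rep_len(vdw, n),
    is_hb_donor_h = rep_len(is_hb_donor_h, n),
    is_hb_acceptor = rep_len(is_hb_acceptor, n),
    stringsAsFactors = FALSE
  )
}

#' Create a molecule
#'
#' A molecule is a topology: atoms, bonds and (optionally) proton groups.
#' Proton groups are the NMR-visible pseudo-atoms: a CH group holds one
#' hydrogen, CH2 two and CH3 three; all members must be hydrogens.
#'
#' @param atoms data.frame from [atom_table()].
#' @param bonds two-column matrix of 1-based atom indices.
#' @param proton_groups named list of integer vectors of hydrogen indices.
#' @return object of class `molecule`.
#' @export
molecule <- function(atoms, bonds, proton_groups = list()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- nrow(atoms)
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  if (any(atoms$vdw <= 0)) stop("van der Waals radii must be positive")
  if (nrow(bonds) > 0 &&
      (any(bonds < 1) || any(bonds > n) || any(bonds[, 1] == bonds[, 2]))) {
    stop("bond indices out of range or self-bonds present")
  }
  # donor hydrogens must be H bonded to an electronegative heavy atom
  don <- which(atoms$is_hb_donor_h)
  for (i in don) {
    if (atoms$element[i] != "H") {
      stop("atom ", i, " flagged as donor-H but is not a hydrogen")
    }
    nb <- bonded_neighbors(bonds, i)
    if (!any(atoms$element[nb] %in% c("N", "O", "S"))) {
      stop("donor-H atom ", i, " is not bonded to N/O/S")
    }
  }
  for (g in names(proton_groups)) {
    idx <- proton_groups[[g]]
    if (length(idx) < 1 || length(idx) > 3) {
      stop("proton group '", g, "' must have 1-3 members")
    }
    if (any(atoms$element[idx] != "H")) {
      stop("proton group '", g, "' contains non-hydrogen atoms")
    }
  }
  structure(list(atoms = atoms, bonds = bonds,
                 proton_groups = proton_groups),
            class = "molecule")
}

#' @keywords internal
bonded_neighbors <- function(bonds, i) {
  c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
}

#' Number of atoms in a molecule
#' @param mol a [molecule()].
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Create a conformer
#'
#' @param coords N x 3 numeric matrix of Cartesian coordinates in Angstrom.
#' @param id conformer identifier.
#' @return object of class `conformer`.
#' @export
conformer <- function(coords, id = "conf") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  if (!all(is.finite(coords))) stop("conformer '", id,
                                    "' has non-finite coordinates")
  structure(list(coords = coords, id = as.character(id)),
            class = "conformer")
}

#' Create a conformer library
#'
#' The central container of the pipeline: one molecule's topology plus a
#' list of conformers sharing that topology.
#'
#' @param mol a [molecule()].
#' @param conformers list of [conformer()] objects.
#' @param source free-text provenance.
#' @return object of class `conformer_library`.
#' @export
conformer_library <- function(mol, conformers, source = "") {
  stopifnot(inherits(mol, "molecule"), length(conformers) >= 1)
  n <- n_atoms(mol)
  for (k in seq_along(conformers)) {
    cf <- conformers[[k]]
    if (!inherits(cf, "conformer")) stop("element ", k, " is not a conformer")
    if (nrow(cf$coords) != n) {
      stop("conformer ", k, " has ", nrow(cf$coords),
           " atoms; molecule has ", n)
    }
  }
  structure(list(molecule = mol, conformers = conformers, source = source),
            class = "conformer_library")
}

#' @export
print.conformer_library <- function(x, ...) {
  cat("conformer_library:", length(x$conformers), "conformers,",
      n_atoms(x$molecule), "atoms",
      if (nzchar(x$source)) paste0("(", x$source, ")") else "", "\n")
  invisible(x)
}

#' Number of conformers in a library
#' @param lib a [conformer_library()].
#' @return integer conformer count.
#' @export
n_conformers <- function(lib) length(lib$conformers)

#' Extract the coordinate matrix of one conformer
#' @param lib a [conformer_library()].
#' @param k conformer index.
#' @return N x 3 matrix, Angstrom.
#' @export
coords_of <- function(lib, k) lib$conformers[[k]]$coords

#' Conformer ids of a library
#' @param lib a [conformer_library()].
#' @return character vector.
#' @export
conformer_ids <- function(lib) {
  vapply(lib$conformers, function(cf) cf$id, character(1))
}
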