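# Per-conformer molecular descriptors: radius of gyration, solvent-
# accessible surface area (Shrake-Rupley numerical integration), solvent-
# accessible 3D polar surface area, and intramolecular hydrogen-bond counts.

#' Mass-weighted radius of gyration
#'
#' sqrt(sum(m_i * |r_i - r_com|^2) / sum(m_i)) about the center of mass.
#'
#' @param coords N x 3 coordinate matrix (Angstrom) or a [conformer()].
#' @param masses per-atom masses in amu (positive).
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(coords, masses) {
  if (inherits(coords, "conformer")) coords <- coords$coords
  if (any(masses <= 0)) stop("masses must be positive")
  if (length(masses) != nrow(coords)) stop("mass/atom count mismatch")
  com <- colSums(coords * masses) / sum(masses)
  dev <- sweep(coords, 2, com)
  sqrt(sum(masses * rowSums(dev^2)) / sum(masses))
}

#' @keywords internal
fibonacci_sphere <- function(n) {
  # deterministic quasi-uniform unit-sphere point set (golden-angle spiral)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (i - 1 + 0.5)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by sampling `n_points` quasi-uniform test points on each
#' atom's solvent-expanded sphere (radius vdW + probe) and counting the
#' points not buried inside any other atom's expanded sphere. The point set
#' is deterministic, so results are reproducible bit-for-bit at fixed
#' `n_points`.
#'
#' @param coords N x 3 coordinate matrix (Angstrom) or a [conformer()].
#' @param radii per-atom van der Waals radii in Angstrom (positive).
#' @param probe solvent probe radius in Angstrom (default 1.4, water).
#' @param n_points test points per atom (default 960).
#' @return numeric vector of per-atom accessible areas in Angstrom^2;
#'   the molecular SASA is their sum.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  if (inherits(coords, "conformer")) coords <- coords$coords
  if (any(radii <= 0)) stop("radii must be positive")
  n <- nrow(coords)
  if (length(radii) != n) stop("radius/atom count mismatch")
  sphere <- fibonacci_sphere(n_points)
  rs <- radii + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    # neighbors whose expanded spheres can overlap atom i's
    dij2 <- rowSums(sweep(coords, 2, coords[i, ])^2)
    nb <- which(dij2 < (rs[i] + rs)^2 & seq_len(n) != i)
    pts <- sweep(sphere * rs[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- rowSums(sweep(pts, 2, coords[j, ])^2)
      acc <- acc & d2 >= rs[j]^2
      if (!any(acc)) break
    }
    area[i] <- sum(acc) / n_points * 4 * pi * rs[i]^2
  }
  area
}

#' Identify polar atoms
#'
#' An atom is polar iff its absolute partial charge exceeds
#' `charge_threshold` (e), or -- when `element_fallback` is on or the
#' molecule carries no charges at all -- iff it is N, O or S, or a hydrogen
#' bonded to one of these.
#'
#' @param mol a [molecule()].
#' @param charge_threshold partial-charge magnitude above which an atom is
#'   polar, in e (default 0.1).
#' @param element_fallback also apply the element rule (default TRUE).
#' @return logical vector, one per atom.
#' @export
polar_atoms <- function(mol, charge_threshold = 0.1, element_fallback = TRUE) {
  atoms <- mol$atoms
  polar <- abs(atoms$charge) > charge_threshold
  no_charges <- all(atoms$charge == 0)
  if (element_fallback || no_charges) {
    heavy_polar <- atoms$element %in% c("N", "O", "S")
    h_polar <- vapply(seq_len(nrow(atoms)), function(i) {
      atoms$element[i] == "H" &&
        any(atoms$element[bonded_neighbors(mol$bonds, i)] %in% c("N", "O", "S"))
    }, logical(1))
    polar <- polar | heavy_polar | h_polar
  }
  polar
}

#' Solvent-accessible 3D polar surface area
#'
#' SASA summed over the polar atoms of a specific conformer: the
#' conformation-dependent polar surface a molecule actually exposes, the
#' key descriptor of chameleonic behavior (folded conformers bury polarity
#' that extended conformers expose).
#'
#' @param coords N x 3 coordinate matrix or [conformer()].
#' @param mol the [molecule()] supplying elements, charges and radii.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param charge_threshold see [polar_atoms()].
#' @param element_fallback see [polar_atoms()].
#' @param n_points SASA sampling density (default 960).
#' @return polar surface area in Angstrom^2.
#' @export
sa_3d_psa <- function(coords, mol, probe = 1.4, charge_threshold = 0.1,
                      element_fallback = TRUE, n_points = 960) {
  a <- sasa(coords, mol$atoms$vdw, probe, n_points)
  sum(a[polar_atoms(mol, charge_threshold, element_fallback)])
}

#' Hydrogen-bond detection criteria
#'
#' Geometric criteria for counting intramolecular hydrogen bonds:
#' donor-acceptor distance, donor-H-acceptor angle, and minimum separation
#' along the bonded graph (to exclude trivially close pairs such as an
#' amide NH and its own carbonyl oxygen).
#'
#' @param max_da_distance maximum D...A distance in Angstrom (default 3.5).
#' @param min_dha_angle minimum D-H...A angle in degrees (default 135).
#' @param min_bond_separation minimum number of bonds between donor heavy
#'   atom and acceptor (default 4).
#' @return list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 3.5, min_dha_angle = 135,
                           min_bond_separation = 4) {
  stopifnot(max_da_distance > 0, min_dha_angle > 0, min_dha_angle <= 180)
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle,
                 min_bond_separation = min_bond_separation),
            class = "hbond_criteria")
}

#' Count intramolecular hydrogen bonds
#'
#' Counts donor-H...acceptor triples satisfying all three criteria. Donor
#' hydrogens and acceptors are the atoms flagged in the molecule's atom
#' table; the donor heavy atom is the N/O/S bonded to the donor hydrogen.
#'
#' @param coords N x 3 coordinate matrix or [conformer()].
#' @param mol the [molecule()].
#' @param criteria an [hbond_criteria()] object.
#' @return integer count of intramolecular hydrogen bonds.
#' @export
count_imhb <- function(coords, mol, criteria = hbond_criteria()) {
  if (inherits(coords, "conformer")) coords <- coords$coords
  atoms <- mol$atoms
  hs <- which(atoms$is_hb_donor_h)
  acc <- which(atoms$is_hb_acceptor)
  if (length(hs) == 0 || length(acc) == 0) return(0L)
  g <- igraph::graph_from_edgelist(mol$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(atoms)) {
    g <- igraph::add_vertices(g, nrow(atoms) - igraph::vcount(g))
  }
  sep <- igraph::distances(g)
  count <- 0L
  for (h in hs) {
    nb <- bonded_neighbors(mol$bonds, h)
    d_heavy <- nb[atoms$element[nb] %in% c("N", "O", "S")][1]
    for (a in acc) {
      if (a == d_heavy || a == h) next
      if (sep[d_heavy, a] < criteria$min_bond_separation) next
      da <- sqrt(sum((coords[a, ] - coords[d_heavy, ])^2))
      if (da > criteria$max_da_distance) next
      v1 <- coords[d_heavy, ] - coords[h, ]
      v2 <- coords[a, ] - coords[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang >= criteria$min_dha_angle) count <- count + 1L
    }
  }
  count
}

#' Descriptor table for a conformer library
#'
#' Computes per-conformer radius of gyration, total SASA, solvent-accessible
#' 3D polar surface area and intramolecular hydrogen-bond count, plus the
#' population-weighted mean of each column.
#'
#' @param lib a [conformer_library()].
#' @param weights per-conformer populations (default uniform); must match
#'   the conformer count.
#' @param probe probe radius in Angstrom (default 1.4).
#' @param charge_threshold see [polar_atoms()].
#' @param element_fallback see [polar_atoms()].
#' @param criteria an [hbond_criteria()] object.
#' @param n_points SASA sampling density (default 960).
#' @return list of class `descriptor_table`: `table` (data.frame with
#'   columns conformer_id, r_gyr, sasa_total, sa_3d_psa, n_imhb, weight)
#'   and `means` (named numeric, population-weighted).
#' @export
ensemble_descriptors <- function(lib, weights = NULL, probe = 1.4,
                                 charge_threshold = 0.1,
                                 element_fallback = TRUE,
                                 criteria = hbond_criteria(),
                                 n_points = 960) {
  nc <- n_conformers(lib)
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  if (length(weights) != nc) {
    stop("weight count (", length(weights), ") does not match conformer count (",
         nc, ")")
  }
  mol <- lib$molecule
  polar <- polar_atoms(mol, charge_threshold, element_fallback)
  rows <- lapply(seq_len(nc), function(k) {
    xyz <- coords_of(lib, k)
    a <- sasa(xyz, mol$atoms$vdw, probe, n_points)
    data.frame(conformer_id = lib$conformers[[k]]$id,
               r_gyr = radius_of_gyration(xyz, mol$atoms$mass),
               sasa_total = sum(a),
               sa_3d_psa = sum(a[polar]),
               n_imhb = count_imhb(xyz, mol, criteria),
               weight = weights[k],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  means <- c(r_gyr = weighted_mean(tab$r_gyr, weights),
             sasa_total = weighted_mean(tab$sasa_total, weights),
             sa_3d_psa = weighted_mean(tab$sa_3d_psa, weights),
             n_imhb = weighted_mean(tab$n_imhb, weights))
  structure(list(table = tab, means = means), class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table:", nrow(x$table), "conformers\n")
  cat("population-weighted means: Rgyr", signif(x$means["r_gyr"], 4),
      "A; SASA", signif(x$means["sasa_total"], 4),
      "A2; SA 3D PSA", signif(x$means["sa_3d_psa"], 4),
      "A2; #IMHB", signif(x$means["n_imhb"], 3), "\n")
  invisible(x)
}
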