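# Rigid-body superposition (Kabsch) and derived RMSD utilities.

#' @keywords internal
kabsch_rotation <- function(ref_c, mob_c) {
  # rotation R (proper, det +1) maximizing overlap of row-vector coordinate
  # sets already centered at the origin: mob_c %*% R ~ ref_c
  a <- t(mob_c) %*% ref_c
  s <- svd(a)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose one conformer onto another
#'
#' Optimal least-squares rigid-body superposition (rotation plus translation,
#' proper rotations only -- no reflection) of `mobile` onto `reference`,
#' fitted on `atom_subset` and applied to all atoms.
#'
#' @param reference,mobile N x 3 coordinate matrices or [conformer()]s with
#'   the same atom count.
#' @param atom_subset indices of atoms used for the fit (default all).
#' @param rmsd_atoms indices over which the reported RMSD is computed
#'   (default: all atoms).
#' @return list with `coords` (transformed mobile, N x 3) and `rmsd`
#'   (Angstrom, over `rmsd_atoms`).
#' @export
superpose <- function(reference, mobile, atom_subset = NULL,
                      rmsd_atoms = NULL) {
  ref <- if (inherits(reference, "conformer")) reference$coords else as.matrix(reference)
  mob <- if (inherits(mobile, "conformer")) mobile$coords else as.matrix(mobile)
  if (nrow(ref) != nrow(mob)) stop("atom counts differ")
  if (is.null(atom_subset)) atom_subset <- seq_len(nrow(ref))
  if (length(atom_subset) < 3) stop("need at least 3 atoms to superpose")
  rs <- ref[atom_subset, , drop = FALSE]
  ms <- mob[atom_subset, , drop = FALSE]
  rc <- sweep(rs, 2, colMeans(rs))
  if (qr(rc)$rank < 2) stop("fit atoms are collinear or coincident")
  mc <- sweep(ms, 2, colMeans(ms))
  rot <- kabsch_rotation(rc, mc)
  moved <- sweep(sweep(mob, 2, colMeans(ms)) %*% rot, 2, colMeans(rs), "+")
  if (is.null(rmsd_atoms)) rmsd_atoms <- seq_len(nrow(ref))
  dev <- moved[rmsd_atoms, , drop = FALSE] - ref[rmsd_atoms, , drop = FALSE]
  list(coords = moved, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Best-fit RMSD between two coordinate sets
#'
#' @param a,b N x 3 coordinate matrices.
#' @param atom_subset indices used for both fit and RMSD (default all).
#' @return RMSD in Angstrom after optimal superposition.
#' @export
rmsd_fit <- function(a, b, atom_subset = NULL) {
  superpose(a, b, atom_subset, rmsd_atoms = atom_subset)$rmsd
}
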