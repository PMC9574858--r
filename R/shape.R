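# Shape and clustering analysis: principal-moment shape descriptors,
# Cartesian PCA of superposed conformers, K-means clustering, diverse-subset
# selection, fold classification, and per-atom fluctuations (RMSF).

#' Normalized principal-moment-of-inertia ratios
#'
#' Principal moments I1 <= I2 <= I3 of the mass-weighted inertia tensor
#' about the center of mass; NPR1 = I1/I3, NPR2 = I2/I3. Every conformation
#' maps into the triangle with vertices (0,1) rod, (0.5,0.5) disc and
#' (1,1) sphere.
#'
#' @param coords N x 3 coordinate matrix or [conformer()] (>= 2 atoms).
#' @param masses per-atom masses in amu.
#' @return named numeric: `npr1`, `npr2`.
#' @export
npr <- function(coords, masses) {
  if (inherits(coords, "conformer")) coords <- coords$coords
  if (nrow(coords) < 2) stop("need at least 2 atoms")
  com <- colSums(coords * masses) / sum(masses)
  x <- sweep(coords, 2, com)
  r2 <- rowSums(x^2)
  inertia <- diag(sum(masses * r2), 3) - t(x * masses) %*% x
  mom <- sort(eigen(inertia, symmetric = TRUE)$values)
  if (mom[3] <= 1e-12) stop("all atoms coincident: inertia tensor is zero")
  c(npr1 = mom[1] / mom[3], npr2 = mom[2] / mom[3])
}

#' @keywords internal
align_to_mean <- function(lib, atom_subset = NULL, tol = 1e-4,
                          max_iter = 100) {
  # iteratively superpose all conformers onto their mean structure until the
  # mean stops moving; returns list(aligned = list of N x 3, mean = N x 3)
  nc <- n_conformers(lib)
  if (is.null(atom_subset)) atom_subset <- seq_len(n_atoms(lib$molecule))
  aligned <- lapply(seq_len(nc), function(k) {
    superpose(coords_of(lib, 1), coords_of(lib, k), atom_subset)$coords
  })
  mean_xyz <- Reduce(`+`, aligned) / nc
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(x) {
      superpose(mean_xyz, x, atom_subset)$coords
    })
    new_mean <- Reduce(`+`, aligned) / nc
    shift <- sqrt(max(rowSums((new_mean - mean_xyz)^2)))
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  list(aligned = aligned, mean = mean_xyz)
}

#' Cartesian PCA of a conformer library
#'
#' All conformers are iteratively superposed onto their mean structure
#' (mean-shift tolerance 1e-4 Angstrom), then PCA is run on the flattened
#' Cartesian deviations of `atom_subset`.
#'
#' @param lib a [conformer_library()] with >= 2 conformers.
#' @param atom_subset atom indices entering the PCA (default all).
#' @param n_components number of score columns returned (default 2).
#' @return list with `scores` (conformers x components),
#'   `explained_variance` (fraction per component, all components) and
#'   `aligned` (list of superposed coordinate matrices).
#' @export
pca_conformers <- function(lib, atom_subset = NULL, n_components = 2) {
  nc <- n_conformers(lib)
  if (nc < 2) stop("need at least 2 conformers")
  if (is.null(atom_subset)) atom_subset <- seq_len(n_atoms(lib$molecule))
  al <- align_to_mean(lib, atom_subset)
  x <- t(vapply(al$aligned, function(m) {
    as.vector(t(m[atom_subset, , drop = FALSE]))
  }, numeric(3 * length(atom_subset))))
  x <- sweep(x, 2, colMeans(x))
  total_var <- sum(x^2)
  n_components <- min(n_components, ncol(x), nc - 1)
  if (total_var < 1e-20) {
    return(list(scores = matrix(0, nc, n_components),
                explained_variance = rep(0, n_components),
                aligned = al$aligned))
  }
  p <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x[, seq_len(n_components), drop = FALSE],
       explained_variance = ev,
       aligned = al$aligned)
}

#' K-means clustering of PC scores
#'
#' Best-of-`n_restarts` K-means (k = 5 by default) on the PCA scores,
#' deterministic given `seed`. Labels are renumbered by descending cluster
#' size so that cluster 1 is always the largest.
#'
#' @param scores conformers x components score matrix.
#' @param k number of clusters (default 5); must not exceed the number of
#'   points.
#' @param seed RNG seed.
#' @param n_restarts random restarts (default 10).
#' @return integer vector of cluster labels in 1..k.
#' @export
kmeans_cluster <- function(scores, k = 5, seed = 1, n_restarts = 10) {
  scores <- as.matrix(scores)
  if (k > nrow(scores)) {
    stop("k (", k, ") exceeds the number of points (", nrow(scores), ")")
  }
  set.seed(seed)
  km <- suppressWarnings(
    stats::kmeans(scores, centers = k, nstart = n_restarts, iter.max = 100))
  sizes <- tabulate(km$cluster, nbins = k)
  relabel <- integer(k)
  relabel[order(-sizes, seq_len(k))] <- seq_len(k)
  relabel[km$cluster]
}

#' Diverse subset selection within clusters
#'
#' Within each cluster, deterministic greedy max-min (farthest-point)
#' selection in PC space, seeded from the member nearest the cluster
#' centroid. Clusters no larger than `per_cluster` are returned whole.
#'
#' @param scores conformers x components score matrix.
#' @param labels cluster labels from [kmeans_cluster()].
#' @param per_cluster members selected per cluster (default 26).
#' @return named list, one integer vector of selected row indices per
#'   cluster label.
#' @export
diverse_subset <- function(scores, labels, per_cluster = 26) {
  stopifnot(per_cluster >= 1)
  scores <- as.matrix(scores)
  out <- list()
  for (cl in sort(unique(labels))) {
    members <- which(labels == cl)
    if (length(members) <= per_cluster) {
      out[[as.character(cl)]] <- members
      next
    }
    pts <- scores[members, , drop = FALSE]
    centroid <- colMeans(pts)
    d_centroid <- sqrt(rowSums(sweep(pts, 2, centroid)^2))
    sel <- which.min(d_centroid)
    dmin <- sqrt(rowSums(sweep(pts, 2, pts[sel, ])^2))
    while (length(sel) < per_cluster) {
      cand <- which.max(dmin)
      sel <- c(sel, cand)
      dmin <- pmin(dmin, sqrt(rowSums(sweep(pts, 2, pts[cand, ])^2)))
    }
    out[[as.character(cl)]] <- members[sel]
  }
  out
}

#' Classify a conformer as folded, semi-folded or linear
#'
#' Automated proxy for visual fold classification of a bifunctional
#' molecule: the distance between the two ligand-set centroids, d_AB, is
#' normalized by the contour length (sum of bond lengths) of the shortest
#' bonded path between the two ligand anchor atoms (the ligand atoms bonded
#' to the linker). The normalized extension e = d_AB / contour is compared
#' to two thresholds: folded if e < `t_folded`, linear if e > `t_linear`,
#' semi-folded otherwise. Rigid motions of the conformer leave e unchanged.
#'
#' @param coords N x 3 coordinate matrix or [conformer()].
#' @param mol the [molecule()] (bonds required).
#' @param ligand_a_atoms,ligand_b_atoms disjoint, non-empty atom index sets
#'   of the two terminal ligands.
#' @param t_folded upper extension bound for "folded" (default 0.35).
#' @param t_linear lower extension bound for "linear" (default 0.65).
#' @return list with `class` (one of `"folded"`, `"semi_folded"`,
#'   `"linear"`), `extension` (e), `d_ab` (Angstrom) and `contour`
#'   (Angstrom).
#' @export
classify_fold <- function(coords, mol, ligand_a_atoms, ligand_b_atoms,
                          t_folded = 0.35, t_linear = 0.65) {
  if (inherits(coords, "conformer")) coords <- coords$coords
  if (length(ligand_a_atoms) == 0 || length(ligand_b_atoms) == 0 ||
      length(intersect(ligand_a_atoms, ligand_b_atoms)) > 0) {
    stop("ligand atom sets must be disjoint and non-empty")
  }
  ca <- colMeans(coords[ligand_a_atoms, , drop = FALSE])
  cb <- colMeans(coords[ligand_b_atoms, , drop = FALSE])
  d_ab <- sqrt(sum((ca - cb)^2))
  anchor <- function(set) {
    for (i in set) {
      if (any(!bonded_neighbors(mol$bonds, i) %in% set)) return(i)
    }
    set[1]
  }
  aa <- anchor(ligand_a_atoms)
  ab <- anchor(ligand_b_atoms)
  blen <- sqrt(rowSums((coords[mol$bonds[, 1], , drop = FALSE] -
                        coords[mol$bonds[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(mol$bonds, directed = FALSE)
  if (igraph::vcount(g) < nrow(coords)) {
    g <- igraph::add_vertices(g, nrow(coords) - igraph::vcount(g))
  }
  igraph::E(g)$weight <- blen
  contour <- igraph::distances(g, v = aa, to = ab)[1, 1]
  if (!is.finite(contour)) stop("ligand anchors are not bonded-connected")
  e <- d_ab / contour
  cls <- if (e < t_folded) "folded" else if (e > t_linear) "linear"
         else "semi_folded"
  list(class = cls, extension = e, d_ab = d_ab, contour = contour)
}

#' Per-atom root mean square fluctuation
#'
#' Frames are iteratively superposed onto their mean structure (fit on
#' `atom_subset`); RMSF_i = sqrt(mean over frames |r_i - mean_i|^2).
#'
#' @param lib a [conformer_library()] treated as a trajectory (>= 2 frames).
#' @param atom_subset atoms used for the superposition fit (default all).
#' @return numeric vector of per-atom RMSF in Angstrom.
#' @export
rmsf <- function(lib, atom_subset = NULL) {
  if (n_conformers(lib) < 2) stop("need at least 2 frames")
  al <- align_to_mean(lib, atom_subset)
  dev2 <- lapply(al$aligned, function(x) rowSums((x - al$mean)^2))
  sqrt(Reduce(`+`, dev2) / length(dev2))
}
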