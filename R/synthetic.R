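# Synthetic-data generators with known ground truth: a model bifunctional
# molecule (two terminal rings joined by a linker), conformer ensembles
# built from three geometric fold templates, and NOE buildup curves
# simulated from a known-weight ensemble via sigma ~ r^-6.
#
# Templates are geometric, not physical: no force field is involved, so the
# fold labels and ensemble weights are exact by construction.

#' Specification for the synthetic generators
#'
#' @param n_linker_atoms linker chain length (>= 8).
#' @param ligand_size atoms per terminal ring (>= 5).
#' @param fold_fractions length-3 numeric (folded, semi_folded, linear)
#'   summing to 1.
#' @param n_conformers conformers to generate.
#' @param noise_sigma_xyz Gaussian coordinate noise, Angstrom per axis
#'   (default 0.1).
#' @param seed RNG seed.
#' @return list of class `generator_spec`.
#' @export
generator_spec <- function(n_linker_atoms = 12, ligand_size = 6,
                           fold_fractions = c(0.6, 0.3, 0.1),
                           n_conformers = 100, noise_sigma_xyz = 0.1,
                           seed = 1) {
  stopifnot(n_linker_atoms >= 8, ligand_size >= 5, n_conformers >= 1,
            noise_sigma_xyz >= 0, length(fold_fractions) == 3)
  if (any(fold_fractions < 0) || abs(sum(fold_fractions) - 1) > 1e-9) {
    stop("fold_fractions must be non-negative and sum to 1")
  }
  structure(list(n_linker_atoms = as.integer(n_linker_atoms),
                 ligand_size = as.integer(ligand_size),
                 fold_fractions = fold_fractions,
                 n_conformers = as.integer(n_conformers),
                 noise_sigma_xyz = noise_sigma_xyz,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Build the model bifunctional molecule
#'
#' Topology: a planar carbon ring A (one ring nitrogen carrying the only
#' NH donor hydrogen), a saturated linker chain with ether oxygens at two
#' fixed positions (partial charge -0.4 e), and a ring B with one
#' ring oxygen acting as hydrogen-bond acceptor. Every linker carbon
#' carries two geminal hydrogens 1.78 Angstrom apart (the internal NOE
#' distance reference). Proton groups: `"NH"`, one `"H<i>"` CH2 group per
#' linker carbon, and single-proton groups `"refa"`/`"refb"` on the middle
#' linker CH2.
#'
#' @param spec a [generator_spec()].
#' @return a [molecule()] with an extra `$layout` field describing ring,
#'   linker, donor/acceptor and hydrogen indices (used by the template
#'   builder).
#' @export
build_model_protac <- function(spec) {
  L <- spec$ligand_size
  n <- spec$n_linker_atoms
  k_n <- round(L / 3)       # ring A nitrogen (donor heavy atom)
  k_o <- round(L / 2)       # ring B oxygen (acceptor)
  ring_a <- seq_len(L)
  linker <- L + seq_len(n)
  ring_b <- L + n + seq_len(L)
  linker_is_o <- seq_len(n) %in% .linker_o_positions
  element <- c(
    ifelse(seq_len(L) - 1 == k_n, "N", "C"),
    ifelse(linker_is_o, "O", "C"),
    ifelse(seq_len(L) - 1 == k_o, "O", "C"))
  # geminal hydrogens for every linker carbon
  h_parent <- rep(linker[!linker_is_o], each = 2)
  element <- c(element, rep("H", length(h_parent)))
  donor_n <- ring_a[k_n + 1]
  donor_h <- length(element) + 1L
  element <- c(element, "H")
  charge <- numeric(length(element))
  charge[element %in% c("N", "O")] <- -0.4
  charge[donor_h] <- 0.4
  bonds <- rbind(
    cbind(ring_a, c(ring_a[-1], ring_a[1])),              # ring A cycle
    cbind(ring_b, c(ring_b[-1], ring_b[1])),              # ring B cycle
    c(ring_a[1], linker[1]), c(linker[n], ring_b[1]),     # ring-linker
    cbind(linker[-n], linker[-1]),                        # linker chain
    cbind(h_parent, 2 * L + n + seq_along(h_parent)),     # C-H
    c(donor_n, donor_h))                                  # N-H
  acceptor <- element == "O"
  donor_flag <- seq_along(element) == donor_h
  atoms <- atom_table(element, charge = charge,
                      is_hb_donor_h = donor_flag, is_hb_acceptor = acceptor)
  # proton groups: one CH2 group per linker carbon, NH, and the two single
  # protons of the middle CH2 as the geminal reference pair
  h_idx <- 2 * L + n + seq_along(h_parent)
  groups <- split(h_idx, h_parent)
  names(groups) <- paste0("H", match(as.integer(names(groups)), linker))
  carbons <- which(!linker_is_o)
  ref_c <- carbons[ceiling(length(carbons) / 2)]
  ref_pair <- groups[[paste0("H", ref_c)]]
  groups$refa <- ref_pair[1]
  groups$refb <- ref_pair[2]
  groups$NH <- donor_h
  mol <- molecule(atoms, bonds, groups)
  mol$layout <- list(ring_a = ring_a, ring_b = ring_b, linker = linker,
                     linker_is_o = linker_is_o, h_parent = h_parent,
                     h_idx = h_idx, donor_n = donor_n, donor_h = donor_h,
                     acceptor_o = ring_b[k_o + 1], k_n = k_n, k_o = k_o,
                     ref_carbon = ref_c)
  mol
}

# Linker ether positions are fixed (not proportional to length) so that
# model compounds of different linker lengths carry the same polar payload;
# the conformational mixture, not the atom count, then drives the polar
# surface area contrast.
#' @keywords internal
.linker_o_positions <- c(3L, 6L)

#' @keywords internal
.ring_bond <- 1.4
.ring_radius <- function(L) .ring_bond / (2 * sin(pi / L))

#' @keywords internal
backbone_path <- function(type, n_bb, bond = 1.5, strand_sep = 2.3) {
  # backbone = ring A anchor, linker atoms, ring B anchor; planar (z = 0)
  if (type == "linear") {
    # all-anti zig-zag with tetrahedral angles
    half <- 109.47 / 2 * pi / 180
    x <- (seq_len(n_bb) - 1) * bond * sin(half)
    y <- ifelse(seq_len(n_bb) %% 2 == 0, bond * cos(half), 0)
    return(cbind(x, y, 0))
  }
  if (type == "semi_folded") {
    # one turn: two straight arms meeting at a 45 degree apex angle; the
    # apex atom sits at a convex, fully exposed corner, so it must not be
    # one of the ether oxygens
    m <- ceiling(n_bb / 2)
    while ((m - 1) %in% .linker_o_positions) m <- m + 1
    u2 <- c(cos(3 * pi / 4), sin(3 * pi / 4))
    pts <- matrix(0, n_bb, 3)
    pts[seq_len(m), 1] <- (seq_len(m) - 1) * bond
    apex <- pts[m, 1:2]
    for (j in seq_len(n_bb - m)) {
      pts[m + j, 1:2] <- apex + j * bond * u2
    }
    return(pts)
  }
  # folded: two-turn serpentine bringing the termini back together; turn
  # corners are convex and exposed, so shift the split (n1 + n3 fixed,
  # which preserves the end-to-end geometry) until no ether sits on one
  n3 <- max(2, floor((n_bb - 2) / 4))
  n1 <- max(2, floor((n_bb - 2) / 2) - n3)
  n2 <- n_bb - n1 - n3
  corners <- function(n1) c(n1 - 1, n1, n1 + n2 - 1, n1 + n2)
  while (n1 > 2 && any(corners(n1) %in% .linker_o_positions)) {
    n1 <- n1 - 1
    n3 <- n3 + 1
  }
  s <- strand_sep
  x1 <- (seq_len(n1) - 1) * bond
  x2 <- x1[n1] - (seq_len(n2) - 1) * bond
  x3 <- x2[n2] + (seq_len(n3) - 1) * bond
  cbind(c(x1, x2, x3), c(rep(0, n1), rep(s, n2), rep(2 * s, n3)), 0)
}

#' @keywords internal
heavy_template_coordinates <- function(mol, type) {
  # heavy atoms only (rings and linker); hydrogens are rebuilt afterwards
  # so that rigid local geometry (the 1.78 Angstrom geminal reference)
  # survives coordinate noise
  lay <- mol$layout
  L <- length(lay$ring_a)
  n <- length(lay$linker)
  n_bb <- n + 2L
  bb <- backbone_path(type, n_bb)
  xyz <- matrix(0, n_atoms(mol), 3)
  rr <- .ring_radius(L)
  place_ring <- function(anchor_pos, inward) {
    # inward: unit vector from the anchor atom toward the chain
    center <- anchor_pos - rr * inward
    a0 <- atan2(inward[2], inward[1])
    ang <- a0 + (seq_len(L) - 1) * 2 * pi / L
    cbind(center[1] + rr * cos(ang), center[2] + rr * sin(ang), 0)
  }
  u1 <- (bb[2, ] - bb[1, ])[1:2]; u1 <- u1 / sqrt(sum(u1^2))
  v <- (bb[n_bb, ] - bb[n_bb - 1, ])[1:2]; v <- v / sqrt(sum(v^2))
  xyz[lay$ring_a, ] <- place_ring(bb[1, 1:2], u1)
  xyz[lay$ring_b, ] <- place_ring(bb[n_bb, 1:2], -v)
  xyz[lay$linker, ] <- bb[2:(n_bb - 1), ]
  xyz
}

#' @keywords internal
place_hydrogens <- function(mol, xyz, type) {
  # geminal CH2 hydrogens: perpendicular in-plane offset plus +/- 0.89
  # along the local normal, so every geminal pair is exactly 1.78 Angstrom
  # apart with C-H about 1.09 Angstrom, whatever the heavy-atom geometry
  lay <- mol$layout
  chain <- c(lay$ring_a[1], lay$linker, lay$ring_b[1])
  for (j in seq_along(lay$h_parent)) {
    if (j %% 2 == 0) next
    ci <- lay$h_parent[j]
    pos <- which(chain == ci)
    t <- xyz[chain[pos + 1], ] - xyz[chain[pos - 1], ]
    t <- t / sqrt(sum(t^2))
    # split the pair along the out-of-plane normal, offset along the
    # in-plane perpendicular (keeps the pair clear of adjacent strands)
    ref <- if (abs(t[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    z <- ref - sum(ref * t) * t
    z <- z / sqrt(sum(z^2))
    m <- c(t[2] * z[3] - t[3] * z[2],
           t[3] * z[1] - t[1] * z[3],
           t[1] * z[2] - t[2] * z[1])
    base <- xyz[ci, ]
    xyz[lay$h_idx[j], ] <- base + 0.63 * m + 0.89 * z
    xyz[lay$h_idx[j + 1], ] <- base + 0.63 * m - 0.89 * z
  }
  # donor hydrogen: points at the acceptor in the folded template (allowing
  # the intramolecular hydrogen bond), outward from ring A otherwise
  nd <- xyz[lay$donor_n, ]
  dir <- if (type == "folded") {
    w <- xyz[lay$acceptor_o, ] - nd
    w / sqrt(sum(w^2))
  } else {
    ca <- colMeans(xyz[lay$ring_a, , drop = FALSE])
    w <- nd - ca
    w / sqrt(sum(w^2))
  }
  xyz[lay$donor_h, ] <- nd + 1.01 * dir
  xyz
}

#' @keywords internal
template_coordinates <- function(mol, type) {
  place_hydrogens(mol, heavy_template_coordinates(mol, type), type)
}

#' @keywords internal
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a conformer ensemble with known fold labels
#'
#' Emits `spec$n_conformers` conformers by perturbing the three geometric
#' templates (two-turn hairpin, single-turn, extended all-anti) in the
#' proportions `spec$fold_fractions` (deterministic largest-remainder
#' allocation, block-ordered), adding isotropic Gaussian coordinate noise
#' and a random rigid rotation and translation per conformer. Seeded and
#' fully reproducible.
#'
#' @param mol molecule from [build_model_protac()].
#' @param spec the [generator_spec()].
#' @param true_weights optional per-conformer populations stored as ground
#'   truth for the NOE simulator (default uniform).
#' @return list of class `truth_bundle`: `library`, `fold_labels`,
#'   `true_weights`, `true_restraint_distances` (NULL until
#'   [simulate_noe_buildups()] fills it).
#' @export
generate_ensemble <- function(mol, spec, true_weights = NULL) {
  n <- spec$n_conformers
  counts <- floor(spec$fold_fractions * n)
  rem <- spec$fold_fractions * n - counts
  while (sum(counts) < n) {
    i <- which.max(rem)
    counts[i] <- counts[i] + 1L
    rem[i] <- -1
  }
  labels <- rep(c("folded", "semi_folded", "linear"), counts)
  set.seed(spec$seed)
  heavy <- which(mol$atoms$element != "H")
  confs <- vector("list", n)
  for (k in seq_len(n)) {
    xyz <- heavy_template_coordinates(mol, labels[k])
    # noise perturbs the heavy-atom skeleton; hydrogens are rebuilt from
    # the perturbed frame so rigid local geometry (the geminal reference
    # distance) is preserved exactly
    xyz[heavy, ] <- xyz[heavy, ] +
      matrix(stats::rnorm(3 * length(heavy), 0, spec$noise_sigma_xyz),
             ncol = 3)
    xyz <- place_hydrogens(mol, xyz, labels[k])
    xyz <- sweep(xyz %*% random_rotation(), 2, stats::runif(3, -10, 10), "+")
    confs[[k]] <- conformer(xyz, id = sprintf("%s_%03d", labels[k], k))
  }
  lib <- conformer_library(mol, confs, source = "synthetic templates")
  if (is.null(true_weights)) true_weights <- rep(1 / n, n)
  stopifnot(length(true_weights) == n)
  structure(list(library = lib, fold_labels = labels,
                 true_weights = true_weights / sum(true_weights),
                 true_restraint_distances = NULL),
            class = "truth_bundle")
}

#' Simulate NOE buildup curves from a known-weight ensemble
#'
#' Per restraint, the ensemble-averaged distance d_j is back-calculated
#' from the bundle's true weights (same averaging convention as the
#' population fit). Buildup rates follow sigma_j = sigma_ref *
#' (r_ref / d_j)^6, with sigma_ref set so the reference pair's normalized
#' intensity reaches 0.3 at `anchor_time` (default: the last mixing time).
#' Intensities follow sigma * t * (1 - sigma * t / 2) -- a mild saturation
#' that mimics the curvature of real buildups -- with multiplicative
#' uniform noise on each cross peak; diagonal peaks are synthesized so that
#' [normalize_noe()] recovers the intended normalized intensities. Passing
#' mixing times much shorter than `anchor_time` keeps all curves in the
#' strictly linear regime.
#'
#' @param bundle a [generate_ensemble()] result.
#' @param pairs data.frame with columns `pair_id`, `group_a`, `group_b`,
#'   `kind`; must contain the reference row `ref_pair_id`.
#' @param ref_pair_id `pair_id` of the internal reference (geminal) pair.
#' @param mixing_times seconds (default 0.1 to 0.7 in 0.1 steps).
#' @param noise_fraction multiplicative noise amplitude (default 0).
#' @param seed RNG seed.
#' @param averaging ensemble averaging convention, `"linear"` or `"r6"`.
#' @param anchor_time time at which the reference intensity reaches 0.3
#'   (default `max(mixing_times)`).
#' @param peak_scale arbitrary diagonal intensity (default 1000).
#' @return list with `curves` (list of [buildup_curve()]), `pairs`,
#'   `true_distances` (ensemble-averaged, Angstrom) and `sigma_ref` (1/s);
#'   also returned invisibly inside the updated bundle via
#'   `attr(, "bundle")`.
#' @export
simulate_noe_buildups <- function(bundle, pairs, ref_pair_id = "ref",
                                  mixing_times = seq(0.1, 0.7, by = 0.1),
                                  noise_fraction = 0, seed = 1,
                                  averaging = c("linear", "r6"),
                                  anchor_time = NULL, peak_scale = 1000) {
  averaging <- match.arg(averaging)
  stopifnot(inherits(bundle, "truth_bundle"),
            ref_pair_id %in% pairs$pair_id)
  mat <- back_calculate(bundle$library, pairs)
  w <- bundle$true_weights
  d_ens <- ensemble_distances(mat, w, averaging)
  names(d_ens) <- pairs$pair_id
  r_ref <- d_ens[[ref_pair_id]]
  if (is.null(anchor_time)) anchor_time <- max(mixing_times)
  x0 <- 1 - sqrt(1 - 2 * 0.3)  # solves x (1 - x/2) = 0.3
  sigma_ref <- x0 / anchor_time
  sigma <- sigma_ref * (r_ref / d_ens)^6
  set.seed(seed)
  curves <- lapply(seq_len(nrow(pairs)), function(j) {
    y <- sigma[j] * mixing_times * (1 - sigma[j] * mixing_times / 2)
    y <- pmax(y, 1e-12)
    u1 <- stats::runif(length(y), -noise_fraction, noise_fraction)
    u2 <- stats::runif(length(y), -noise_fraction, noise_fraction)
    buildup_curve(pairs$pair_id[j], mixing_times,
                  cross_1 = y * peak_scale * (1 + u1),
                  cross_2 = y * peak_scale * (1 + u2),
                  diagonal_1 = rep(peak_scale, length(y)),
                  diagonal_2 = rep(peak_scale, length(y)))
  })
  names(curves) <- pairs$pair_id
  list(curves = curves, pairs = pairs, true_distances = d_ens,
       sigma_ref = sigma_ref)
}

#' Default NOE restraint pairs for the model molecule
#'
#' A set of CH2-CH2 and NH-CH2 proton-group pairs spanning the linker
#' (group separations of 2-4 linker positions plus two long-range pairs),
#' preceded by the geminal reference pair `"ref"`. These pairs have
#' ensemble-averaged distances in the NOE-observable range and respond
#' strongly to the folded/extended contrast.
#'
#' @param mol molecule from [build_model_protac()].
#' @return data.frame with columns `pair_id`, `group_a`, `group_b`, `kind`.
#' @export
default_restraint_pairs <- function(mol) {
  lay <- mol$layout
  carbons <- which(!lay$linker_is_o)
  g <- paste0("H", carbons)
  pick <- function(i, j) c(g[i], g[j])
  m <- length(g)
  combos <- list()
  for (step in 2:3) {
    for (i in seq_len(m - step)) combos[[length(combos) + 1]] <- pick(i, i + step)
  }
  combos[[length(combos) + 1]] <- pick(1, m)
  combos[[length(combos) + 1]] <- pick(2, m - 1)
  ab <- do.call(rbind, combos)
  out <- data.frame(
    pair_id = c("ref", paste0(ab[, 1], "_", ab[, 2]), paste0("NH_", g[2])),
    group_a = c("refa", ab[, 1], "NH"),
    group_b = c("refb", ab[, 2], g[2]),
    kind = c("CH", rep("CH2", nrow(ab)), "CH2"),
    stringsAsFactors = FALSE)
  out[!duplicated(out$pair_id), ]
}

#' Preset synthetic compounds mirroring a permeability series
#'
#' Three model compounds differing only in linker length and fold mixture:
#' `protac1` (12-atom linker, mostly folded: 0.6/0.3/0.1), `protac2`
#' (8-atom linker, mixed: 0.3/0.4/0.3) and `protac3` (8-atom linker,
#' mostly extended: 0.1/0.2/0.7). The folded-shifted compound hides polar
#' surface and forms intramolecular hydrogen bonds; the extended-shifted
#' one exposes polarity -- the synthetic analog of a chameleonic
#' permeability series.
#'
#' @param name one of `"protac1"`, `"protac2"`, `"protac3"`.
#' @param n_conformers conformers to generate (default 100).
#' @param seed RNG seed (default 7).
#' @param noise_sigma_xyz coordinate noise in Angstrom (default 0.1).
#' @return list with `spec`, `molecule` and `bundle`.
#' @export
synthetic_preset <- function(name = c("protac1", "protac2", "protac3"),
                             n_conformers = 100, seed = 7,
                             noise_sigma_xyz = 0.1) {
  name <- match.arg(name)
  par <- switch(name,
    protac1 = list(n_linker = 12, fractions = c(0.6, 0.3, 0.1)),
    protac2 = list(n_linker = 8, fractions = c(0.3, 0.4, 0.3)),
    protac3 = list(n_linker = 8, fractions = c(0.1, 0.2, 0.7)))
  spec <- generator_spec(n_linker_atoms = par$n_linker,
                         fold_fractions = par$fractions,
                         n_conformers = n_conformers,
                         noise_sigma_xyz = noise_sigma_xyz,
                         seed = seed)
  mol <- build_model_protac(spec)
  list(spec = spec, molecule = mol, bundle = generate_ensemble(mol, spec))
}
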