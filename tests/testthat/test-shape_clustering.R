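# Superposition, PMI shape descriptors, PCA, K-means, subset selection,
# fold classification, RMSF.

test_that("superposition removes rigid motion and matches the closed form", {
  set.seed(2)
  x <- matrix(rnorm(24, sd = 3), 8, 3)
  expect_equal(superpose(x, x)$rmsd, 0, tolerance = 1e-12)
  th <- 1.1
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(x %*% rot, 2, c(4, -7, 2), "+")
  s <- superpose(x, moved)
  expect_lt(s$rmsd, 1e-6)
  expect_equal(s$coords, x, tolerance = 1e-6)
  # independent cross-check against bio3d's fitting
  y <- x + matrix(rnorm(24, sd = 0.5), 8, 3)
  ours <- superpose(x, y)$rmsd
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(x)), matrix(as.vector(t(y)), 1)))
  theirs <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - x)^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
  # one atom displaced 2 A, fit on the 3 fixed atoms -> overall RMSD 1
  ref <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(1, 1, 1))
  mob <- ref
  mob[4, ] <- mob[4, ] + c(0, 0, 2)
  expect_equal(superpose(ref, mob, atom_subset = 1:3)$rmsd, 1.0)
  expect_error(superpose(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("NPR ratios hit the rod, sphere and disc limits", {
  rod <- cbind(seq(-5, 5), 0, 0)
  s <- npr(rod, rep(1, nrow(rod)))
  expect_equal(unname(s["npr1"]), 0, tolerance = 1e-9)
  expect_equal(unname(s["npr2"]), 1, tolerance = 1e-9)
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_equal(unname(npr(tetra, rep(1, 4))), c(1, 1), tolerance = 1e-9)
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(unname(npr(sq, rep(1, 4))), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(npr(matrix(1, 3, 3), rep(1, 3)), "coincident")
  # all shapes live in the rod-disc-sphere triangle
  p <- default_test_preset(n = 10)
  masses <- p$molecule$atoms$mass
  for (k in 1:10) {
    v <- npr(coords_of(p$bundle$library, k), masses)
    expect_lte(v["npr1"], v["npr2"] + 1e-12)
    expect_gte(v["npr1"] + v["npr2"], 1 - 1e-12)
    expect_lte(v["npr2"], 1 + 1e-12)
  }
})

test_that("Cartesian PCA separates a one-degree-of-freedom ensemble", {
  # hinge: one arm rotates rigidly about the z axis; an off-axis anchor
  # atom keeps the fixed part non-collinear for the superposition fit
  base <- rbind(c(0, 2, 0), cbind(-(5:1), 0, 0), cbind(1:5, 0, 0))
  confs <- lapply(seq(-0.3, 0.3, length.out = 9), function(th) {
    rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    rbind(base[1:6, ], base[7:11, ] %*% rot)
  })
  pc <- pca_conformers(make_library(confs))
  expect_gt(pc$explained_variance[1], 0.95)
  expect_true(all(diff(pc$explained_variance) <= 1e-12))
  expect_lte(sum(pc$explained_variance), 1 + 1e-9)
  # identical conformers give all-zero scores
  pc0 <- pca_conformers(make_library(list(base, base, base)))
  expect_equal(max(abs(pc0$scores)), 0)
})

test_that("K-means recovers well-separated blobs and is size-canonical", {
  set.seed(14)
  blob <- function(cx, cy, n) cbind(rnorm(n, cx, 0.1), rnorm(n, cy, 0.1))
  scores <- rbind(blob(0, 0, 12), blob(10, 0, 8), blob(0, 10, 5))
  truth <- rep(1:3, c(12, 8, 5))
  lab <- kmeans_cluster(scores, k = 3, seed = 2)
  # exact recovery up to the size-ordered relabeling (sizes distinct here)
  expect_equal(lab, truth)
  expect_true(all(diff(tabulate(lab)) <= 0))
  expect_equal(kmeans_cluster(scores, k = 3, seed = 2), lab)  # deterministic
  expect_equal(unique(kmeans_cluster(scores, k = 1, seed = 1)), 1L)
  expect_error(kmeans_cluster(scores[1:3, ], k = 5, seed = 1), "exceeds")
})

test_that("diverse subset selection is max-min and keeps small clusters whole", {
  sc <- cbind(0:9, 0)
  lab <- rep(1L, 10)
  expect_equal(diverse_subset(sc, lab, per_cluster = 26)[["1"]], 1:10)
  sel <- diverse_subset(sc, lab, per_cluster = 3)[["1"]]
  expect_length(sel, 3)
  expect_true(all(c(1, 10) %in% sel))  # both extremes of the line
  expect_identical(diverse_subset(sc, lab, per_cluster = 3)[["1"]], sel)
  # brute-force oracle: first pick = nearest centroid, then greedy max-min
  set.seed(6)
  pts <- matrix(rnorm(40), 20, 2)
  sel2 <- diverse_subset(pts, rep(1L, 20), per_cluster = 5)[["1"]]
  d0 <- sqrt(rowSums(sweep(pts, 2, colMeans(pts))^2))
  oracle <- which.min(d0)
  dmin <- sqrt(rowSums(sweep(pts, 2, pts[oracle, ])^2))
  for (i in 2:5) {
    nxt <- which.max(dmin)
    oracle <- c(oracle, nxt)
    dmin <- pmin(dmin, sqrt(rowSums(sweep(pts, 2, pts[nxt, ])^2)))
  }
  expect_identical(sel2, oracle)
})

test_that("fold classification is threshold-driven and rigid-motion invariant", {
  spec <- generator_spec(n_conformers = 1, noise_sigma_xyz = 0)
  mol <- build_model_protac(spec)
  lay <- mol$layout
  cls <- vapply(c("folded", "semi_folded", "linear"), function(tp) {
    xyz <- protacfold:::template_coordinates(mol, tp)
    classify_fold(xyz, mol, lay$ring_a, lay$ring_b)$class
  }, character(1))
  expect_equal(unname(cls), c("folded", "semi_folded", "linear"))
  # rigid motion does not change the extension
  xyz <- protacfold:::template_coordinates(mol, "semi_folded")
  th <- 0.9
  rot <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  moved <- sweep(xyz %*% rot, 2, c(3, 3, 3), "+")
  expect_equal(classify_fold(moved, mol, lay$ring_a, lay$ring_b)$extension,
               classify_fold(xyz, mol, lay$ring_a, lay$ring_b)$extension,
               tolerance = 1e-9)
  expect_error(classify_fold(xyz, mol, lay$ring_a, lay$ring_a), "disjoint")
})

test_that("RMSF isolates the fluctuating atom and ranks linker flexibility", {
  base <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(3, 3, 0), c(1, 1, 2))
  frames <- lapply(c(-1, 1, -1, 1), function(dz) {
    f <- base
    f[5, 3] <- f[5, 3] + dz
    f
  })
  lib <- make_library(frames)
  r <- rmsf(lib, atom_subset = 1:4)
  expect_equal(r[1:4], rep(0, 4), tolerance = 1e-10)
  expect_equal(r[5], 1.0, tolerance = 1e-10)
  # static trajectory: all zero
  expect_equal(max(rmsf(make_library(list(base, base)))), 0, tolerance = 1e-10)
  # flexible ensemble fluctuates more than a rigid one
  spec_flex <- generator_spec(n_conformers = 10, noise_sigma_xyz = 0.3, seed = 4)
  spec_rig <- generator_spec(n_conformers = 10, noise_sigma_xyz = 0.05, seed = 4)
  mol <- build_model_protac(spec_flex)
  lk <- mol$layout$linker
  r_flex <- mean(rmsf(generate_ensemble(mol, spec_flex)$library)[lk])
  r_rig <- mean(rmsf(generate_ensemble(mol, spec_rig)$library)[lk])
  expect_gt(r_flex, r_rig)
})
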