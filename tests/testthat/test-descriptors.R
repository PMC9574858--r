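# Radius of gyration, SASA, 3D polar surface area, hydrogen-bond counting.

test_that("radius of gyration matches closed forms and is rigid-motion invariant", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1), 12), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two, c(1, 1)), 1.0)
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(radius_of_gyration(sq, rep(1, 4)), sqrt(2))
  # rigid rotation + translation leaves Rgyr unchanged
  set.seed(3)
  x <- matrix(rnorm(30), 10, 3)
  m <- runif(10, 1, 16)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(radius_of_gyration(sweep(x %*% rot, 2, c(5, -2, 1), "+"), m),
               radius_of_gyration(x, m), tolerance = 1e-10)
})

test_that("SASA reproduces the analytic sphere and buries enclosed atoms", {
  # isolated atom: 4 pi (r + probe)^2
  a <- sasa(matrix(0, 1, 3), radii = 1.5, probe = 1.4)
  expect_equal(a, 4 * pi * 2.9^2, tolerance = 0.01 * 4 * pi * 2.9^2)
  # small atom fully inside a large one is completely buried
  two <- rbind(c(0, 0, 0), c(0.5, 0, 0))
  a2 <- sasa(two, radii = c(3, 0.5), probe = 1.4)
  expect_equal(a2[2], 0)
  # default sampling within 2% of a 10x denser reference (self-convergence)
  pairc <- rbind(c(0, 0, 0), c(2.2, 0, 0))
  lo <- sasa(pairc, radii = c(1.7, 1.52), n_points = 960)
  hi <- sasa(pairc, radii = c(1.7, 1.52), n_points = 10000)
  expect_equal(lo, hi, tolerance = 0.02)
  # moving atoms closer never increases SASA (two-atom systems)
  seps <- seq(6, 1, by = -0.5)
  tot <- vapply(seps, function(s) {
    sum(sasa(rbind(c(0, 0, 0), c(s, 0, 0)), radii = c(1.7, 1.7)))
  }, numeric(1))
  expect_true(all(diff(tot) <= 1e-9))
})

test_that("polar surface area is the SASA of the polar atoms", {
  # 5-atom toy: polar atoms by charge; PSA = sum of their per-atom SASA
  atoms <- atom_table(c("C", "C", "C", "O", "N"),
                      charge = c(0, 0.05, 0, -0.5, -0.4))
  mol <- molecule(atoms, rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L)))
  set.seed(8)
  xyz <- matrix(rnorm(15, sd = 2), 5, 3)
  a <- sasa(xyz, mol$atoms$vdw)
  expect_equal(sa_3d_psa(xyz, mol, element_fallback = FALSE), sum(a[4:5]))
  # all charges below threshold, fallback off: zero polar area
  atoms0 <- atom_table(c("C", "C", "C"), charge = c(0.05, 0, -0.09))
  mol0 <- molecule(atoms0, rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(sa_3d_psa(matrix(rnorm(9), 3, 3), mol0,
                         element_fallback = FALSE), 0)
  # containment: PSA never exceeds total SASA on synthetic conformers
  p <- default_test_preset(n = 6)
  tab <- ensemble_descriptors(p$bundle$library, n_points = 480)$table
  expect_true(all(tab$sa_3d_psa <= tab$sasa_total + 1e-9))
})

test_that("hydrogen bonds are counted by distance, angle and bond separation", {
  # linear N-H...O=C geometry within criteria
  atoms <- atom_table(c("N", "H", "C", "C", "C", "O"),
                      is_hb_donor_h = c(FALSE, TRUE, rep(FALSE, 4)),
                      is_hb_acceptor = c(rep(FALSE, 5), TRUE))
  bonds <- rbind(c(1L, 2L), c(1L, 3L), c(3L, 4L), c(4L, 5L), c(5L, 6L))
  mol <- molecule(atoms, bonds)
  xyz <- rbind(c(0, 0, 0),      # N
               c(1.0, 0, 0),    # H along +x
               c(-1, 1, 0), c(-1, 2.5, 0), c(0.5, 3.2, 0),
               c(2.9, 0.05, 0)) # O nearly collinear, D...A 2.9
  expect_equal(count_imhb(xyz, mol), 1L)
  far <- xyz; far[6, ] <- c(6, 0, 0)
  expect_equal(count_imhb(far, mol), 0L)
  # same geometry but acceptor only 2 bonds from donor: excluded
  bonds2 <- rbind(c(1L, 2L), c(1L, 3L), c(3L, 6L), c(3L, 4L), c(4L, 5L))
  mol2 <- molecule(atoms, bonds2)
  expect_equal(count_imhb(xyz, mol2), 0L)
})

test_that("ensemble descriptor means are population-weighted", {
  p <- default_test_preset(n = 5)
  lib <- p$bundle$library
  w <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  d <- ensemble_descriptors(lib, weights = w, n_points = 480)
  expect_equal(unname(d$means["sa_3d_psa"]),
               sum(w * d$table$sa_3d_psa) / sum(w))
  expect_equal(unname(d$means["r_gyr"]), sum(w * d$table$r_gyr))
  expect_error(ensemble_descriptors(lib, weights = c(1, 1)), "weight count")
  # uniform weights over identical conformers reproduce the single values
  one <- coords_of(lib, 1)
  lib_id <- conformer_library(lib$molecule,
                              list(conformer(one, "a"), conformer(one, "b")))
  d_id <- ensemble_descriptors(lib_id, n_points = 480)
  expect_equal(unname(d_id$means["r_gyr"]), d_id$table$r_gyr[1])
})

test_that("fold classes order the descriptors as expected", {
  # pure-template libraries: folded < semi-folded < linear for Rgyr and
  # polar surface; folded has at least as many internal H-bonds
  stats <- lapply(list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)), function(ff) {
    s <- generator_spec(fold_fractions = ff, n_conformers = 8,
                        noise_sigma_xyz = 0.1, seed = 13)
    b <- generate_ensemble(build_model_protac(s), s)
    ensemble_descriptors(b$library, n_points = 480)$means
  })
  rg <- vapply(stats, `[[`, numeric(1), "r_gyr")
  psa <- vapply(stats, `[[`, numeric(1), "sa_3d_psa")
  hb <- vapply(stats, `[[`, numeric(1), "n_imhb")
  expect_true(all(diff(rg) > 0))
  expect_true(all(diff(psa) > 0))
  expect_gte(hb[1], hb[3])
})
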