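# Population deconvolution: back-calculation, simplex-constrained fitting,
# validation, AIC comparison.

test_that("back-calculation applies the r^-6 pseudo-atom averages", {
  # two single protons 3 A apart
  lib <- two_proton_library(list(rbind(c(0, 0, 0), c(0, 0, 0),
                                       c(0, 0, 3), c(0, 0, 3))))
  r <- data.frame(pair_id = "p", group_a = "a", group_b = "b")
  expect_equal(back_calculate(lib, r)[1, 1], 3.0)

  # CH2 group: equal member distances give the common value; mixed
  # distances give the two-term r^-6 mean
  atoms <- atom_table(c("C", "H", "H", "H"))
  mol <- molecule(atoms, rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L)),
                  proton_groups = list(ch2 = c(2L, 3L), x = 4L))
  eq <- conformer(rbind(c(0, 0, 0), c(0, 1, 0), c(0, -1, 0), c(2, 0, 0)))
  lib_eq <- conformer_library(mol, list(conformer(
    rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, -2), c(0, 0, 4)))))
  r2 <- data.frame(pair_id = "q", group_a = "ch2", group_b = "x")
  # member distances 2 and 6 -> ((2^-6 + 6^-6)/2)^(-1/6)
  expect_equal(back_calculate(lib_eq, r2)[1, 1],
               ((2^-6 + 6^-6) / 2)^(-1 / 6), tolerance = 1e-9)
  expect_error(back_calculate(lib_eq,
    data.frame(pair_id = "z", group_a = "nope", group_b = "x")),
    "unknown proton group")
})

test_that("population fitting recovers known weights and reports degeneracy", {
  set.seed(11)
  d <- matrix(runif(30, 2, 6), 10, 3)
  w_true <- c(0.6, 0.3, 0.1)
  fit <- fit_populations(d, as.vector(d %*% w_true))
  expect_equal(fit$weights, w_true, tolerance = 1e-4)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  expect_true(all(fit$weights >= 0))
  expect_lt(fit$fit_rmsd, 1e-6)

  # independent oracle: penalty-augmented NNLS through pracma
  dexp <- as.vector(d %*% w_true) * (1 + runif(10, -0.02, 0.02))
  fit2 <- fit_populations(d, dexp)
  w_or <- pracma::lsqnonneg(rbind(d, 1e4), c(dexp, 1e4))$x
  w_or <- w_or / sum(w_or)
  expect_equal(fit2$weights, w_or, tolerance = 1e-6)

  # single conformer: weight 1, rmsd equals plain distance RMSD
  f1 <- fit_populations(d[, 1, drop = FALSE], dexp)
  expect_equal(f1$weights, 1)
  expect_equal(f1$fit_rmsd, sqrt(mean((dexp - d[, 1])^2)))

  # duplicated column is flagged degenerate, not silently resolved
  fdup <- fit_populations(cbind(d, d[, 2]), dexp)
  expect_true(any(vapply(fdup$degenerate_pairs,
                         function(p) setequal(p, c(2, 4)), logical(1))))

  # mixture optimum never fits worse than any single conformer
  for (j in 1:3) {
    expect_lte(fit2$fit_rmsd,
               fit_populations(d[, j, drop = FALSE], dexp)$fit_rmsd + 1e-12)
  }
})

test_that("linear and r6 averaging agree for one conformer and both recover truth", {
  set.seed(12)
  d <- matrix(runif(36, 2, 6), 12, 3)
  w_true <- c(0.5, 0.3, 0.2)
  d_r6 <- as.vector(d^(-6) %*% w_true)^(-1 / 6)
  fr6 <- fit_populations(d, d_r6, averaging = "r6")
  expect_equal(fr6$weights, w_true, tolerance = 1e-3)
  one <- d[, 2, drop = FALSE]
  dexp <- runif(12, 2, 6)
  expect_equal(fit_populations(one, dexp, "linear")$fit_rmsd,
               fit_populations(one, dexp, "r6")$fit_rmsd)
})

test_that("noise and jackknife validation separate conditioned from degenerate fits", {
  set.seed(9)
  d <- matrix(runif(200, 2, 6), 40, 5)
  w_true <- c(0.4, 0.3, 0.2, 0.1, 0)
  dexp <- as.vector(d %*% w_true)
  fit <- fit_populations(d, dexp)
  # zero noise: no drift at all
  v0 <- validate_fit(d, dexp, fit, noise_fraction = 0, n_trials = 5, seed = 1)
  expect_equal(max(v0$noise_drift), 0, tolerance = 1e-8)
  # well-conditioned (8x more restraints than conformers): stable at 10%
  v <- validate_fit(d, dexp, fit, n_trials = 30, seed = 1)
  expect_true(v$stable)
  # one restraint, two distinct conformers: jackknife unconstrained
  d1 <- d[1, c(1, 5), drop = FALSE]
  f1 <- fit_populations(d1, dexp[1])
  v1 <- validate_fit(d1, dexp[1], f1, n_trials = 10, seed = 1)
  expect_false(v1$stable)
  expect_gte(max(v1$jackknife_drift), 0.5)
})

test_that("AIC comparison follows the least-squares closed form", {
  f <- fit_populations(matrix(runif(20, 2, 6), 20, 1), runif(20, 2, 6))
  expect_equal(compare_fits(f, f)$delta_aic, 0)
  expect_equal(compare_fits(f, f)$preference, "equivalent")
  # SSE_b = 2 * SSE_a at n = 20, equal k -> delta AIC = -20 ln 2
  col <- rep(3, 20)
  res_a <- rep(0.1, 20)
  fa <- fit_populations(matrix(col, 20, 1), col + res_a)
  fb <- fit_populations(matrix(col, 20, 1), col + sqrt(2) * res_a)
  expect_equal(compare_fits(fa, fb)$delta_aic, -20 * log(2), tolerance = 1e-9)
  expect_equal(compare_fits(fa, fb)$preference, "prefer_a")
  f15 <- fit_populations(matrix(runif(15, 2, 6), 15, 1), runif(15, 2, 6))
  expect_error(compare_fits(fa, f15), "different numbers")
})

test_that("weights stay on the simplex across random refits", {
  set.seed(21)
  for (i in 1:25) {
    nc <- sample(2:12, 1)
    nr <- sample(5:25, 1)
    d <- matrix(runif(nr * nc, 1.8, 6.5), nr, nc)
    f <- fit_populations(d, runif(nr, 1.8, 6.5))
    expect_true(all(f$weights >= 0))
    expect_equal(sum(f$weights), 1, tolerance = 1e-6)
  }
})
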