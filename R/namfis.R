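# NAMFIS-style deconvolution: fit population weights over a discrete
# conformer ensemble so that population-weighted back-calculated interproton
# distances reproduce the experimentally determined (time-averaged) ones.
#
# The fit is a constrained least-squares problem on the probability simplex:
#   min_w sum_j (d_exp[j] - d_ens[j](w))^2,  w_i >= 0, sum w_i = 1
# with d_ens either the linear population average of per-conformer distances
# (default) or the r^-6 ensemble average. The linear problem is convex and
# solved by non-negative least squares with an augmented sum-to-one row; the
# r^-6 problem is solved by quasi-Newton descent on a softmax
# parameterization, started from the linearized solution.

#' Back-calculate restraint distances for every conformer
#'
#' For each conformer and each restraint, all member-pair H-H distances
#' between the two proton groups are combined by the r^-6 mean:
#' d = (mean(d_pair^-6))^(-1/6). For a CH-CH pair this is the plain
#' distance; for CH2 and CH3 groups it reduces to the two- and three-term
#' pseudo-atom averages d = (((d1^-6)+(d2^-6))/2)^(-1/6) and
#' d = (((d1^-6)+(d2^-6)+(d3^-6))/3)^(-1/6).
#'
#' @param lib a [conformer_library()] whose molecule defines the proton
#'   groups named in `restraints`.
#' @param restraints data.frame with columns `group_a`, `group_b` (proton
#'   group labels); typically from [derive_restraints()].
#' @return matrix (restraints x conformers) of distances in Angstrom.
#' @export
back_calculate <- function(lib, restraints) {
  groups <- lib$molecule$proton_groups
  for (g in unique(c(restraints$group_a, restraints$group_b))) {
    if (!g %in% names(groups)) stop("unknown proton group '", g, "'")
  }
  m <- matrix(NA_real_, nrow = nrow(restraints), ncol = n_conformers(lib),
              dimnames = list(restraints$pair_id, conformer_ids(lib)))
  for (k in seq_len(n_conformers(lib))) {
    xyz <- coords_of(lib, k)
    for (j in seq_len(nrow(restraints))) {
      ia <- groups[[restraints$group_a[j]]]
      ib <- groups[[restraints$group_b[j]]]
      d6 <- outer(ia, ib, function(a, b) {
        rowSums((xyz[a, , drop = FALSE] - xyz[b, , drop = FALSE])^2)^(-3)
      })
      m[j, k] <- mean(d6)^(-1 / 6)
    }
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("back-calculated distances must be positive and finite")
  }
  m
}

#' @keywords internal
ensemble_distances <- function(mat, w, averaging) {
  if (averaging == "linear") as.vector(mat %*% w)
  else as.vector(mat^(-6) %*% w)^(-1 / 6)
}

#' @keywords internal
nnls_lh <- function(a, b, tol = 1e-10, dual_scale = NULL) {
  # Lawson-Hanson active-set non-negative least squares; dual_scale sets
  # the magnitude against which dual feasibility is judged (callers with a
  # large penalty row must pass the scale of the data part, or the huge
  # penalty gradient would mask genuine dual infeasibility)
  n <- ncol(a)
  x <- numeric(n)
  passive <- logical(n)
  if (is.null(dual_scale)) dual_scale <- max(abs(crossprod(a, b)))
  iter <- 0L
  max_iter <- 100L * n
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- as.vector(crossprod(a, b - a %*% x))
    w[passive] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol * max(1, dual_scale)) break
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.solve(a[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
  }
  x
}

#' @keywords internal
solve_simplex_nnls <- function(a, b, penalty = 1e4) {
  # min ||a w - b||^2 with w >= 0 and a soft sum(w) = 1 row, renormalized;
  # the penalty row makes the sum constraint dominate without changing the
  # optimum direction, and the final renormalization removes the residual
  scale <- max(abs(a), 1)
  aug_a <- rbind(a / scale, penalty)
  aug_b <- c(b / scale, penalty)
  w <- nnls_lh(aug_a, aug_b,
               dual_scale = max(abs(crossprod(a / scale, b / scale))))
  if (sum(w) <= 0) stop("population fit infeasible: all weights zero")
  w / sum(w)
}

#' Fit conformer populations to experimental distances
#'
#' Solves the constrained least-squares deconvolution described above.
#' Near-duplicate conformers (pairwise back-calculated distance profiles
#' with correlation > 0.999 or numerically identical) make the weight split
#' between them non-identifiable; such pairs are reported in
#' `degenerate_pairs`, not silently resolved.
#'
#' The Akaike information criterion uses the least-squares form
#' AIC = n * log(SSE/n) + 2k, with k the number of weights at or above
#' `report_threshold`.
#'
#' @param mat back-calculation matrix (restraints x conformers) from
#'   [back_calculate()].
#' @param experimental experimental distances, Angstrom, one per matrix row.
#' @param averaging `"linear"` (population average of distances, default)
#'   or `"r6"` (r^-6 ensemble average).
#' @param report_threshold populations at or above this value count as
#'   selected conformers (default 0.01).
#' @return object of class `ensemble_fit`: `weights` (sum to 1),
#'   `selected` (indices with weight >= threshold), `fit_rmsd` (Angstrom),
#'   `n_restraints`, `sse`, `aic`, `averaging`, `degenerate_pairs`.
#' @export
fit_populations <- function(mat, experimental,
                            averaging = c("linear", "r6"),
                            report_threshold = 0.01) {
  averaging <- match.arg(averaging)
  mat <- as.matrix(mat)
  if (ncol(mat) < 1) stop("need at least one conformer column")
  if (length(experimental) != nrow(mat)) {
    stop("experimental distance count (", length(experimental),
         ") does not match matrix rows (", nrow(mat), ")")
  }
  if (ncol(mat) == 1) {
    w <- 1
  } else if (averaging == "linear") {
    w <- solve_simplex_nnls(mat, experimental)
  } else {
    # start from the linearization sum(w * d^-6) = d_exp^-6, then refine the
    # distance-space objective on a softmax parameterization
    w0 <- solve_simplex_nnls(mat^(-6), experimental^(-6))
    obj <- function(z) {
      w <- exp(z - max(z))
      w <- w / sum(w)
      sum((experimental - ensemble_distances(mat, w, "r6"))^2)
    }
    best <- NULL
    for (z0 in list(log(pmax(w0, 1e-8)), rep(0, ncol(mat)))) {
      o <- stats::optim(z0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
      if (is.null(best) || o$value < best$value) best <- o
    }
    w <- exp(best$par - max(best$par))
    w <- w / sum(w)
  }
  resid <- experimental - ensemble_distances(mat, w, averaging)
  sse <- sum(resid^2)
  n <- nrow(mat)
  k <- sum(w >= report_threshold)
  deg <- degenerate_columns(mat)
  structure(list(weights = w,
                 selected = which(w >= report_threshold),
                 fit_rmsd = sqrt(sse / n),
                 n_restraints = n,
                 sse = sse,
                 aic = n * log(max(sse, 1e-12) / n) + 2 * k,
                 averaging = averaging,
                 report_threshold = report_threshold,
                 degenerate_pairs = deg),
            class = "ensemble_fit")
}

#' @keywords internal
degenerate_columns <- function(mat, cor_threshold = 0.999) {
  nc <- ncol(mat)
  pairs <- list()
  if (nc < 2 || nrow(mat) == 0) return(pairs)
  for (i in seq_len(nc - 1)) {
    for (j in (i + 1):nc) {
      identical_cols <- max(abs(mat[, i] - mat[, j])) < 1e-9
      r <- if (nrow(mat) >= 3 &&
               stats::sd(mat[, i]) > 0 && stats::sd(mat[, j]) > 0) {
        stats::cor(mat[, i], mat[, j])
      } else NA_real_
      if (identical_cols || (!is.na(r) && r > cor_threshold)) {
        pairs[[length(pairs) + 1]] <- c(i, j)
      }
    }
  }
  pairs
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat("ensemble_fit (", x$averaging, " averaging): ",
      length(x$selected), " of ", length(x$weights),
      " conformers selected; fit RMSD ", signif(x$fit_rmsd, 3),
      " A; AIC ", signif(x$aic, 4), "\n", sep = "")
  if (length(x$degenerate_pairs) > 0) {
    cat("  note:", length(x$degenerate_pairs),
        "near-duplicate conformer pair(s); weight splits between them are",
        "not identifiable\n")
  }
  invisible(x)
}

#' Validate an ensemble fit by noise and jackknife perturbation
#'
#' Two stability checks: (a) `n_trials` refits with every experimental
#' distance multiplied by (1 + u), u uniform on
#' \[-noise_fraction, +noise_fraction\]; (b) leave-one-out refits dropping
#' each restraint in turn. Each refit's drift is the maximum absolute
#' change of any population weight. The ensemble is declared stable iff
#' the mean drift over noise trials and the largest jackknife drift both
#' stay below `tolerance`. (The mean, not the maximum, summarizes the
#' stochastic scheme: the maximum over trials is an extreme-value
#' statistic that grows without bound as trials are added and would brand
#' every ensemble unstable eventually.)
#'
#' @param mat back-calculation matrix used for the fit.
#' @param experimental experimental distances used for the fit.
#' @param fit the [fit_populations()] result to perturb.
#' @param noise_fraction relative noise amplitude (default 0.10).
#' @param n_trials number of noise refits (default 50).
#' @param seed RNG seed for the noise draws.
#' @param tolerance maximum tolerated absolute weight drift (default 0.10).
#' @return object of class `validation_report`: `baseline_rmsd`,
#'   `noise_drift` (per trial), `jackknife_drift` (per restraint), `stable`.
#' @export
validate_fit <- function(mat, experimental, fit, noise_fraction = 0.10,
                         n_trials = 50, seed = 1, tolerance = 0.10) {
  stopifnot(inherits(fit, "ensemble_fit"))
  mat <- as.matrix(mat)
  w0 <- fit$weights
  set.seed(seed)
  noise_drift <- vapply(seq_len(n_trials), function(i) {
    u <- stats::runif(length(experimental), -noise_fraction, noise_fraction)
    f <- fit_populations(mat, experimental * (1 + u), fit$averaging,
                         fit$report_threshold)
    max(abs(f$weights - w0))
  }, numeric(1))
  jack_drift <- vapply(seq_len(nrow(mat)), function(j) {
    if (nrow(mat) == 1) return(1)  # no restraints left: weights unconstrained
    f <- fit_populations(mat[-j, , drop = FALSE], experimental[-j],
                         fit$averaging, fit$report_threshold)
    max(abs(f$weights - w0))
  }, numeric(1))
  structure(list(baseline_rmsd = fit$fit_rmsd,
                 noise_drift = noise_drift,
                 jackknife_drift = jack_drift,
                 tolerance = tolerance,
                 stable = mean(noise_drift) < tolerance &&
                          max(jack_drift) < tolerance),
            class = "validation_report")
}

#' Compare two ensemble fits by AIC
#'
#' Delta AIC = AIC_a - AIC_b; fits within `equivalence_margin` of each other
#' are reported as equivalent, otherwise the lower-AIC fit is preferred.
#'
#' @param fit_a,fit_b [fit_populations()] results on the same restraint set.
#' @param equivalence_margin |Delta AIC| below which the fits are called
#'   equivalent (default 2).
#' @return list with `delta_aic` and `preference`
#'   (`"equivalent"`, `"prefer_a"` or `"prefer_b"`).
#' @export
compare_fits <- function(fit_a, fit_b, equivalence_margin = 2) {
  if (fit_a$n_restraints != fit_b$n_restraints) {
    stop("fits use different numbers of restraints (",
         fit_a$n_restraints, " vs ", fit_b$n_restraints, ")")
  }
  d <- fit_a$aic - fit_b$aic
  list(delta_aic = d,
       preference = if (abs(d) < equivalence_margin) "equivalent"
                    else if (d < 0) "prefer_a" else "prefer_b")
}
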