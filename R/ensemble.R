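# Ensemble bookkeeping: redundancy elimination, conformational-search
# completeness, and population-weighted statistics.

#' Remove redundant conformers by an RMSD cut-off
#'
#' Greedy pass in input order: a conformer is kept iff its best-fit
#' superposed heavy-atom RMSD to every previously kept conformer exceeds
#' `rmsd_cutoff`. The order of survivors is preserved and the operation is
#' idempotent. The default 3 Angstrom cut-off is the conventional redundancy
#' filter applied to pooled conformational-search output before ensemble
#' fitting.
#'
#' @param lib a [conformer_library()].
#' @param rmsd_cutoff Angstrom, must be positive.
#' @param heavy_only use only non-hydrogen atoms for the RMSD (default TRUE).
#' @return a [conformer_library()] of survivors; kept indices in
#'   `attr(, "kept")`.
#' @export
deduplicate_conformers <- function(lib, rmsd_cutoff = 3, heavy_only = TRUE) {
  stopifnot(inherits(lib, "conformer_library"), rmsd_cutoff > 0)
  sub <- if (heavy_only && sum(lib$molecule$atoms$element != "H") >= 3) {
    which(lib$molecule$atoms$element != "H")
  } else {
    seq_len(n_atoms(lib$molecule))
  }
  kept <- integer(0)
  for (k in seq_len(n_conformers(lib))) {
    xk <- coords_of(lib, k)
    dup <- FALSE
    for (j in kept) {
      if (rmsd_fit(coords_of(lib, j), xk, sub) <= rmsd_cutoff) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- c(kept, k)
  }
  out <- conformer_library(lib$molecule, lib$conformers[kept],
                           source = lib$source)
  attr(out, "kept") <- kept
  out
}

#' Completeness estimate of a conformational search
#'
#' Probability that a stochastic search with `n_steps` steps over a space of
#' `n_conformers` distinct conformers has visited any given conformer at
#' least once: 1 - (1 - 1/N)^M.
#'
#' @param n_conformers N, total number of conformers found (>= 1).
#' @param n_steps M, number of search steps (>= 1).
#' @return probability in \[0, 1\].
#' @export
search_completeness <- function(n_conformers, n_steps) {
  if (any(n_conformers < 1) || any(n_steps < 1)) {
    stop("n_conformers and n_steps must be >= 1")
  }
  1 - (1 - 1 / n_conformers)^n_steps
}

#' Population-weighted mean
#'
#' @param values numeric vector.
#' @param weights non-negative weights of the same length, summing to > 0.
#' @return sum(w * v) / sum(w).
#' @export
weighted_mean <- function(values, weights) {
  if (length(values) != length(weights)) stop("length mismatch")
  if (any(weights < 0)) stop("weights must be non-negative")
  sw <- sum(weights)
  if (sw <= 0) stop("weights must not all be zero")
  sum(weights * values) / sw
}
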