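# Permeability surrogates from assay potencies and the descriptor-vs-
# permeability ranking that ties solution ensembles to cell permeability.
#
# For a degrader that must reach an intracellular target, the ratio of the
# cellular to the biochemical (cell-free) potency is a surrogate for passive
# cell permeability: a highly permeable compound has a low cell/bio ratio.

#' Cell/biochemical potency ratio
#'
#' @param ic50_cell cellular IC50 in micromolar (> 0).
#' @param ic50_bio biochemical (cell-free) IC50 in micromolar (> 0).
#' @return list with `ratio` (ic50_cell / ic50_bio) and `display`
#'   (nearest integer, ties away from zero), vectorized.
#' @export
cell_bio_ratio <- function(ic50_cell, ic50_bio) {
  if (any(ic50_cell <= 0) || any(ic50_bio <= 0)) {
    stop("IC50 values must be positive")
  }
  ratio <- ic50_cell / ic50_bio
  list(ratio = ratio, display = floor(ratio + 0.5))
}

#' Passive permeability from bidirectional transport
#'
#' Geometric mean of the apical-to-basolateral and basolateral-to-apical
#' apparent permeabilities across a cell monolayer:
#' P_passive = (Papp_AB * Papp_BA)^0.5.
#'
#' @param papp_ab,papp_ba apparent permeabilities in nm/s (> 0).
#' @return passive permeability in nm/s, vectorized.
#' @export
passive_permeability <- function(papp_ab, papp_ba) {
  if (any(papp_ab <= 0) || any(papp_ba <= 0)) {
    stop("apparent permeabilities must be positive")
  }
  sqrt(papp_ab * papp_ba)
}

#' Rank ensemble descriptors against permeability
#'
#' Joins per-compound population-weighted ensemble descriptors to
#' permeability surrogates and reports the Spearman rank concordance
#' between low ensemble polarity (-SA 3D PSA) and high permeability:
#' concordance 1 means the compound exposing the least polar surface is
#' also the most permeable. With exactly two compounds the concordance is
#' the sign of the single pair. Discordant pairs are listed.
#'
#' @param records data.frame with columns `compound_id` and `permeability`
#'   (any permeability surrogate where larger = more permeable, e.g.
#'   P_passive, or the negated cell/bio ratio).
#' @param descriptor_tables named list (by compound_id) of
#'   [ensemble_descriptors()] results.
#' @return list of class `rank_report`: `table` (per-compound descriptors
#'   and surrogates), `concordance` (Spearman rho), `discordant_pairs`.
#' @export
rank_report <- function(records, descriptor_tables) {
  stopifnot(nrow(records) >= 2)
  miss <- setdiff(records$compound_id, names(descriptor_tables))
  if (length(miss) > 0) {
    stop("missing descriptor table(s) for compound(s): ",
         paste(miss, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    id <- records$compound_id[i]
    m <- descriptor_tables[[id]]$means
    data.frame(compound_id = id,
               permeability = records$permeability[i],
               sa_3d_psa = unname(m["sa_3d_psa"]),
               r_gyr = unname(m["r_gyr"]),
               n_imhb = unname(m["n_imhb"]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (nrow(tab) == 2) {
    rho <- sign((tab$permeability[1] - tab$permeability[2]) *
                (tab$sa_3d_psa[2] - tab$sa_3d_psa[1]))
  } else {
    rho <- stats::cor(-tab$sa_3d_psa, tab$permeability, method = "spearman")
  }
  disc <- list()
  for (i in seq_len(nrow(tab) - 1)) {
    for (j in (i + 1):nrow(tab)) {
      if ((tab$sa_3d_psa[i] - tab$sa_3d_psa[j]) *
          (tab$permeability[i] - tab$permeability[j]) > 0) {
        disc[[length(disc) + 1]] <- c(tab$compound_id[i], tab$compound_id[j])
      }
    }
  }
  structure(list(table = tab, concordance = rho, discordant_pairs = disc),
            class = "rank_report")
}

#' @export
print.rank_report <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("Spearman concordance of low SA 3D PSA with high permeability:",
      signif(x$concordance, 3), "\n")
  if (length(x$discordant_pairs) > 0) {
    cat("discordant pair(s):",
        paste(vapply(x$discordant_pairs, paste, character(1),
                     collapse = " vs "), collapse = "; "), "\n")
  }
  invisible(x)
}
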