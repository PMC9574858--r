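# Shared fixtures, built in code.

# a bare n-atom carbon "molecule" with no bonds, for coordinate-level ops
bare_molecule <- function(n, element = "C") {
  molecule(atom_table(rep(element, n)), bonds = matrix(integer(0), ncol = 2))
}

make_library <- function(coord_list, element = "C", ids = NULL) {
  n <- nrow(coord_list[[1]])
  if (is.null(ids)) ids <- paste0("c", seq_along(coord_list))
  conformer_library(
    bare_molecule(n, element),
    Map(conformer, coord_list, ids))
}

# exactly linear buildup curve with unit diagonals
linear_curve <- function(sigma, times = seq(0.1, 0.7, by = 0.1),
                         pair_id = "p") {
  y <- sigma * times
  buildup_curve(pair_id, times, y, y, rep(1, length(y)), rep(1, length(y)))
}

# a small molecule with two single-proton groups at controllable positions
two_proton_library <- function(coord_list) {
  atoms <- atom_table(c("C", "H", "C", "H"))
  bonds <- rbind(c(1L, 2L), c(3L, 4L))
  mol <- molecule(atoms, bonds,
                  proton_groups = list(a = 2L, b = 4L))
  conformer_library(mol, Map(conformer, coord_list,
                             paste0("c", seq_along(coord_list))))
}

default_test_preset <- function(name = "protac1", n = 30, seed = 7) {
  synthetic_preset(name, n_conformers = n, seed = seed)
}
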