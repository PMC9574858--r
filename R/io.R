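# Structure file I/O: multi-model PDB, SDF V2000, multi-frame XYZ.
# PDB parsing goes through bio3d; SDF parsing through ChemmineR. Writers are
# plain formatted text. None of these formats carries partial charges except
# our SDF convention (a ">  <PARTIAL_CHARGES>" data field written by
# write_conformer_library and read back if present).

#' Read a conformer library from a structure file
#'
#' Supported formats: multi-model PDB (`MODEL`/`ENDMDL`), SDF V2000 (one
#' record per conformer), and multi-frame XYZ. Atom masses and van der Waals
#' radii are filled from internal element tables. Partial charges are read
#' only when the file carries them (SDF `PARTIAL_CHARGES` data field);
#' otherwise they default to zero with a warning, so polarity-dependent
#' descriptors need either charges in the file or the element fallback.
#'
#' @param path file path.
#' @param format one of `"pdb"`, `"sdf"`, `"xyz"`; default guessed from the
#'   file extension.
#' @return a [conformer_library()].
#' @export
read_conformer_library <- function(path, format = c("auto", "pdb", "sdf", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", sdf = "sdf", mol = "sdf",
                     xyz = "xyz",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  switch(format,
         pdb = read_pdb_library(path),
         sdf = read_sdf_library(path),
         xyz = read_xyz_library(path))
}

#' @keywords internal
read_pdb_library <- function(path) {
  lines <- readLines(path)
  model_starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(model_starts) > 1) {
    # pre-scan: every model must carry the same number of atom records
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(m) {
      sum(is_atom[bounds[m]:(bounds[m + 1] - 1L)])
    }, integer(1))
    if (length(unique(counts)) > 1) {
      bad <- which(counts != counts[1])[1]
      stop("inconsistent atom counts across PDB models: model ", bad,
           " has ", counts[bad], " atoms, model 1 has ", counts[1])
    }
  }
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- nrow(p$atom)
  elements <- trimws(p$atom$elesy)
  if (any(!nzchar(elements))) {
    # fall back to the first letter of the atom name
    nm <- trimws(p$atom$elety)
    elements[!nzchar(elements)] <- substr(nm[!nzchar(elements)], 1, 1)
  }
  atoms <- atom_table(elements, name = trimws(p$atom$elety))
  warning("PDB carries no partial charges; defaulting all charges to 0")
  mol <- molecule(atoms, bonds = matrix(integer(0), ncol = 2))
  confs <- lapply(seq_len(nrow(xyz)), function(m) {
    conformer(matrix(xyz[m, ], ncol = 3, byrow = TRUE),
              id = paste0("model_", m))
  })
  conformer_library(mol, confs, source = path)
}

#' @keywords internal
read_sdf_library <- function(path) {
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfs) < 1) stop("no SDF records in ", path)
  first_ab <- ChemmineR::atomblock(sdfs[[1]])
  n <- nrow(first_ab)
  elements <- sub("_.*$", "", rownames(first_ab))
  bb <- ChemmineR::bondblock(sdfs[[1]])
  bonds <- if (nrow(bb) > 0) {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  } else matrix(integer(0), ncol = 2)
  charges <- rep(0, n)
  db <- ChemmineR::datablock(sdfs[[1]])
  if ("PARTIAL_CHARGES" %in% names(db)) {
    charges <- as.numeric(strsplit(trimws(db[["PARTIAL_CHARGES"]]),
                                   "\\s+")[[1]])
    if (length(charges) != n) stop("PARTIAL_CHARGES field length mismatch")
  } else {
    warning("SDF carries no partial charges; defaulting all charges to 0")
  }
  atoms <- atom_table(elements, charge = charges)
  mol <- molecule(atoms, bonds)
  confs <- lapply(seq_along(sdfs@SDF), function(k) {
    ab <- ChemmineR::atomblock(sdfs[[k]])
    if (nrow(ab) != n) {
      stop("inconsistent atom counts across SDF records: record ", k,
           " has ", nrow(ab), " atoms, record 1 has ", n)
    }
    conformer(unname(ab[, 1:3, drop = FALSE]), id = paste0("conf_", k))
  })
  conformer_library(mol, confs, source = path)
}

#' @keywords internal
read_xyz_library <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  confs <- list()
  elements <- NULL
  pos <- 1L
  frame <- 0L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1) stop("malformed XYZ atom count at line ", pos)
    frame <- frame + 1L
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (is.null(elements)) {
      elements <- el
    } else if (length(el) != length(elements)) {
      stop("inconsistent atom counts across XYZ frames: frame ", frame)
    }
    confs[[frame]] <- conformer(xyz, id = paste0("frame_", frame))
    pos <- pos + 2L + n
  }
  warning("XYZ carries no partial charges; defaulting all charges to 0")
  atoms <- atom_table(elements)
  mol <- molecule(atoms, bonds = matrix(integer(0), ncol = 2))
  conformer_library(mol, confs, source = path)
}

#' Write a conformer library to a structure file
#'
#' Coordinates are written with 3 (PDB) or 4-6 (SDF, XYZ) decimals, so
#' round-tripping preserves them to at least 1e-3 Angstrom. The SDF writer
#' adds a `PARTIAL_CHARGES` data field when any atom carries a nonzero
#' charge, which [read_conformer_library()] reads back.
#'
#' @param lib a [conformer_library()].
#' @param path output path.
#' @param format one of `"pdb"`, `"sdf"`, `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_conformer_library <- function(lib, path,
                                    format = c("pdb", "sdf", "xyz")) {
  format <- match.arg(format)
  atoms <- lib$molecule$atoms
  out <- switch(format,
    pdb = {
      lines <- character(0)
      for (m in seq_along(lib$conformers)) {
        xyz <- lib$conformers[[m]]$coords
        lines <- c(lines, sprintf("MODEL     %4d", m),
          sprintf("HETATM%5d %-4s LIG A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                  seq_len(nrow(xyz)), substr(atoms$name, 1, 4),
                  xyz[, 1], xyz[, 2], xyz[, 3], atoms$element),
          "ENDMDL")
      }
      c(lines, "END")
    },
    sdf = {
      bonds <- lib$molecule$bonds
      has_chg <- any(atoms$charge != 0)
      unlist(lapply(seq_along(lib$conformers), function(m) {
        xyz <- lib$conformers[[m]]$coords
        rec <- c(lib$conformers[[m]]$id, "  protacfold", "",
                 sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(xyz), nrow(bonds)),
                 sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[, 1], xyz[, 2], xyz[, 3], atoms$element))
        if (nrow(bonds) > 0) {
          rec <- c(rec, sprintf("%3d%3d  1  0  0  0  0",
                                bonds[, 1], bonds[, 2]))
        }
        rec <- c(rec, "M  END")
        if (has_chg) {
          rec <- c(rec, ">  <PARTIAL_CHARGES>",
                   paste(format(atoms$charge, trim = TRUE), collapse = " "),
                   "")
        }
        c(rec, "$$$$")
      }))
    },
    xyz = {
      unlist(lapply(seq_along(lib$conformers), function(m) {
        xyz <- lib$conformers[[m]]$coords
        c(sprintf("%d", nrow(xyz)), lib$conformers[[m]]$id,
          sprintf("%-3s %14.6f %14.6f %14.6f",
                  atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]))
      }))
    })
  writeLines(out, path)
  invisible(path)
}
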