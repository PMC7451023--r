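# Conformational-ensemble container and structure/boost-table I/O.
#
# A StructureEnsemble holds T frames of the same N atoms: an atom table
# (identity metadata) plus a T x N x 3 coordinate array in Angstrom. All
# analyses in the package consume this object; bio3d does the PDB-format
# heavy lifting behind read/write.

stop_surfplast <- function(message, class) {
  abort(message, class = c(paste0("surfplast_", class), "surfplast_error"))
}

#' Construct a conformational ensemble
#'
#' @param atoms Data frame with one row per atom and columns `serial`,
#'   `name`, `resname`, `chain`, `resseq`, `icode`, `element`. Missing
#'   columns are filled with sensible defaults.
#' @param coords Numeric array `T x N x 3` (frames x atoms x xyz, Angstrom),
#'   or an `N x 3` matrix for a single frame.
#' @param frame_ids Optional integer frame labels (default `1:T`).
#' @return A `structure_ensemble` object.
#' @export
structure_ensemble <- function(atoms, coords, frame_ids = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1L, dim(coords)))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L) {
    stop_surfplast("`coords` must be a T x N x 3 array", "dimension_error")
  }
  atoms <- as_tibble(atoms)
  defaults <- list(serial = seq_len(nrow(atoms)), name = "CA",
                   resname = "ALA", chain = "A",
                   resseq = seq_len(nrow(atoms)), icode = "", element = "C")
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  }
  if (nrow(atoms) != dim(coords)[2]) {
    stop_surfplast(sprintf(
      "atom table has %d rows but coords has %d atoms",
      nrow(atoms), dim(coords)[2]), "dimension_error")
  }
  if (!all(is.finite(coords))) {
    stop_surfplast("coordinates must be finite", "domain_error")
  }
  if (any(atoms$element == "" | is.na(atoms$element))) {
    stop_surfplast("atom elements must be non-empty", "domain_error")
  }
  if (is.null(frame_ids)) frame_ids <- seq_len(dim(coords)[1])
  structure(
    list(atoms = atoms, coords = coords, frame_ids = as.integer(frame_ids)),
    class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d frame(s) x %d atom(s)\n",
              n_frames(x), n_atoms(x)))
  cat(sprintf("  residues: %d   chains: %s\n",
              nrow(dplyr::distinct(x$atoms, .data$chain, .data$resseq,
                                   .data$icode)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param ensemble A `structure_ensemble`.
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

# Residue identity key: chain + resseq + insertion code.
residue_key <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resseq,
         ifelse(atoms$icode == "", "", atoms$icode))
}

#' Logical atom mask from a selection
#'
#' A selection is `"all"`, a character vector of atom names (e.g. `"CA"`),
#' a logical vector of length N, or an integer index vector.
#' @param ensemble A `structure_ensemble`.
#' @param selection Selection specifier.
#' @return Logical vector of length `n_atoms(ensemble)`.
#' @export
atom_mask <- function(ensemble, selection = "all") {
  n <- n_atoms(ensemble)
  if (is.logical(selection)) {
    if (length(selection) != n)
      stop_surfplast("logical selection has wrong length", "dimension_error")
    mask <- selection
  } else if (is.numeric(selection)) {
    mask <- rep(FALSE, n)
    mask[as.integer(selection)] <- TRUE
  } else if (identical(selection, "all")) {
    mask <- rep(TRUE, n)
  } else {
    mask <- ensemble$atoms$name %in% selection
  }
  if (!any(mask)) {
    stop_surfplast("selection matches no atoms", "selection_error")
  }
  mask
}

#' Subset an ensemble by atom selection
#' @inheritParams atom_mask
#' @return A `structure_ensemble` restricted to the selected atoms.
#' @export
select_atoms <- function(ensemble, selection) {
  mask <- atom_mask(ensemble, selection)
  structure_ensemble(ensemble$atoms[mask, , drop = FALSE],
                     ensemble$coords[, mask, , drop = FALSE],
                     ensemble$frame_ids)
}

#' Coordinates of one frame
#' @param ensemble A `structure_ensemble`.
#' @param frame Frame index (1-based).
#' @return `N x 3` matrix.
#' @export
frame_coords <- function(ensemble, frame) {
  matrix(ensemble$coords[frame, , ], ncol = 3L,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Time-averaged atomic coordinates
#' @param ensemble A `structure_ensemble`.
#' @return `N x 3` matrix of per-atom mean positions.
#' @export
mean_coords <- function(ensemble) {
  apply(ensemble$coords, c(2, 3), mean)
}

# ---- PDB I/O ---------------------------------------------------------------

# Pre-scan a PDB file: validate parsable ATOM/HETATM coordinates and
# consistent atom counts across MODEL blocks (bio3d only warns on both).
prescan_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    stop_surfplast(sprintf("no ATOM/HETATM records in '%s'", path),
                   "parse_error")
  }
  atom_idx <- which(is_atom)
  for (i in atom_idx) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals))) {
      stop_surfplast(sprintf(
        "unparseable coordinates on line %d of '%s'", i, path),
        "parse_error")
    }
  }
  model_idx <- grep("^MODEL", lines)
  if (length(model_idx) > 1L) {
    block <- findInterval(atom_idx, model_idx)
    counts <- tabulate(block[block > 0], nbins = length(model_idx))
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop_surfplast(sprintf(
        "MODEL %d has %d atoms; expected %d (as in MODEL 1)",
        bad, counts[bad], counts[1]), "structure_error")
    }
  }
  invisible(length(model_idx))
}

#' Read a multi-model PDB file as a conformational ensemble
#'
#' Each MODEL becomes one frame; a file without MODEL records yields a
#' single-frame ensemble. Atom order is preserved as in the file.
#'
#' @param path Path to a PDB file.
#' @param selection Atom selection applied after reading (see [atom_mask()]);
#'   default `"all"`.
#' @return A `structure_ensemble`.
#' @export
read_multimodel_pdb <- function(path, selection = "all") {
  if (!file.exists(path)) {
    stop_surfplast(sprintf("file '%s' does not exist", path), "io_error")
  }
  prescan_pdb(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_at <- nrow(pdb$atom)
  nt <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, n_at, nt)), c(3L, 2L, 1L))
  elesy <- pdb$atom$elesy
  elesy[is.na(elesy) | elesy == ""] <-
    substr(trimws(pdb$atom$elety[is.na(elesy) | elesy == ""]), 1, 1)
  atoms <- tibble(
    serial = pdb$atom$eleno,
    name = trimws(pdb$atom$elety),
    resname = trimws(pdb$atom$resid),
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resseq = pdb$atom$resno,
    icode = ifelse(is.na(pdb$atom$insert), "", pdb$atom$insert),
    element = trimws(elesy))
  ens <- structure_ensemble(atoms, coords)
  if (identical(selection, "all")) ens else select_atoms(ens, selection)
}

#' Write an ensemble to a multi-model PDB file
#'
#' @param ensemble A `structure_ensemble`.
#' @param path Output path.
#' @param b Optional length-N B-factor column (default 0).
#' @return Invisibly, `path`.
#' @export
write_ensemble_pdb <- function(ensemble, path, b = NULL) {
  nt <- n_frames(ensemble)
  n <- n_atoms(ensemble)
  xyz <- matrix(0, nrow = nt, ncol = 3L * n)
  for (d in 1:3) xyz[, seq(d, 3L * n, by = 3L)] <- ensemble$coords[, , d]
  if (nt == 1L) xyz <- xyz[1L, ]
  if (is.null(b)) b <- rep(0, n)
  at <- ensemble$atoms
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resseq,
                   resid = at$resname, eleno = at$serial, elety = at$name,
                   chain = at$chain, insert = ifelse(at$icode == "", NA,
                                                     at$icode),
                   elesy = at$element, b = b)
  invisible(path)
}

#' Write a structure with per-atom values in the B-factor column
#'
#' Writes the first frame of `ensemble` with `values` (clamped to
#' `[0, 999.99]`, formatted `%6.2f` in PDB columns 61-66), the standard
#' vehicle for projecting RMSF or plasticity onto a structure.
#'
#' @param ensemble A `structure_ensemble`; frame 1 provides the geometry.
#' @param values Numeric vector, one value per atom.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bfactor_pdb <- function(ensemble, values, path) {
  if (length(values) != n_atoms(ensemble)) {
    stop_surfplast(sprintf(
      "expected %d per-atom values, got %d", n_atoms(ensemble),
      length(values)), "dimension_error")
  }
  b <- pmin(pmax(values, 0), 999.99)
  one <- structure_ensemble(ensemble$atoms,
                            ensemble$coords[1L, , , drop = FALSE])
  write_ensemble_pdb(one, path, b = b)
}

# ---- boost-energy tables ---------------------------------------------------

#' Per-frame gaMD boost-potential series
#'
#' @param delta_v Non-negative numeric vector, kcal/mol: the harmonic boost
#'   energy added to each frame by gaMD.
#' @param temperature Simulation temperature in Kelvin.
#' @return A `boost_series` object.
#' @export
boost_series <- function(delta_v, temperature) {
  if (length(delta_v) == 0L) {
    stop_surfplast("boost series is empty", "empty_error")
  }
  if (any(!is.finite(delta_v))) {
    stop_surfplast("boost energies must be finite", "domain_error")
  }
  if (any(delta_v < 0)) {
    stop_surfplast("boost energies must be non-negative (harmonic boost)",
                   "domain_error")
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop_surfplast("temperature must be positive (Kelvin)", "domain_error")
  }
  structure(list(delta_v = as.numeric(delta_v),
                 temperature = as.numeric(temperature)),
            class = "boost_series")
}

#' @export
print.boost_series <- function(x, ...) {
  cat(sprintf(
    "<boost_series> %d frames at %g K; mean dV = %.4g kcal/mol\n",
    length(x$delta_v), x$temperature, mean(x$delta_v)))
  invisible(x)
}

#' Read a plain-text boost-energy table
#'
#' One Delta-V value (kcal/mol) per line; `#` starts a comment; blank lines
#' are ignored.
#'
#' @param path Path to the table.
#' @param temperature Simulation temperature in Kelvin.
#' @return A `boost_series`.
#' @export
read_boost_series <- function(path, temperature) {
  if (!file.exists(path)) {
    stop_surfplast(sprintf("file '%s' does not exist", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  stripped <- trimws(sub("#.*$", "", lines))
  keep <- which(stripped != "")
  if (length(keep) == 0L) {
    stop_surfplast(sprintf("no boost values in '%s'", path), "empty_error")
  }
  vals <- suppressWarnings(as.numeric(stripped[keep]))
  if (any(is.na(vals))) {
    bad <- keep[which(is.na(vals))[1]]
    stop_surfplast(sprintf("non-numeric boost value on line %d of '%s'",
                           bad, path), "parse_error")
  }
  boost_series(vals, temperature)
}

#' Write a boost series to a plain-text table
#' @param boost A `boost_series`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_boost_series <- function(boost, path) {
  writeLines(c(sprintf("# boost potential dV (kcal/mol), T = %g K",
                       boost$temperature),
               sprintf("%.10g", boost$delta_v)), path)
  invisible(path)
}

# Boost/ensemble pairing is validated where the two meet, not at read time.
check_boost_pairing <- function(ensemble, boost) {
  if (length(boost$delta_v) != n_frames(ensemble)) {
    stop_surfplast(sprintf(
      "boost series has %d frames but ensemble has %d",
      length(boost$delta_v), n_frames(ensemble)), "dimension_error")
  }
  invisible(TRUE)
}
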