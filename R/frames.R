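#' Construct a structure frame
#'
#' A frame is one conformation of a molecule: per-atom 3D coordinates in
#' Angstroms plus atom/residue/chain annotations and a binary class label.
#'
#' @param coords numeric matrix, n_atoms x 3, finite coordinates in Angstroms.
#' @param atom_names character vector of atom identifiers (e.g. "CA").
#' @param residue_ids integer residue numbers, non-decreasing within a chain.
#' @param residue_names character vector of 3-letter residue codes.
#' @param chain_ids character vector of chain labels.
#' @param class_label 0 or 1; which of the two ensembles the frame belongs to.
#' @param frame_time optional time stamp in ns.
#' @return An object of class `dect_frame`.
#' @export
structure_frame <- function(coords, atom_names = NULL, residue_ids = NULL,
                            residue_names = NULL, chain_ids = NULL,
                            class_label = 0L, frame_time = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  if (ncol(coords) != 3L) stop_("coords must have 3 columns")
  if (n < 4L) stop_("a frame needs at least 4 atoms, got %d", n)
  if (!all(is.finite(coords))) stop_("coords must be finite")
  if (!class_label %in% c(0L, 1L)) stop_("class_label must be 0 or 1")
  atom_names    <- as.character(atom_names    %||% rep("CA", n))
  residue_ids   <- as.integer(  residue_ids   %||% seq_len(n))
  residue_names <- as.character(residue_names %||% rep("GLY", n))
  chain_ids     <- as.character(chain_ids     %||% rep("A", n))
  for (v in list(atom_names, residue_ids, residue_names, chain_ids))
    if (length(v) != n) stop_("annotation length does not match %d atoms", n)
  structure(list(coords = coords, atom_names = atom_names,
                 residue_ids = residue_ids, residue_names = residue_names,
                 chain_ids = chain_ids, class_label = as.integer(class_label),
                 frame_time = frame_time),
            class = "dect_frame")
}

#' @method print dect_frame
#' @export
print.dect_frame <- function(x, ...) {
  cat(sprintf("<dect_frame> %d atoms, %d residues, chains %s, class %d\n",
              nrow(x$coords), length(unique(x$residue_ids)),
              paste(unique(x$chain_ids), collapse = ","), x$class_label))
  invisible(x)
}

n_atoms <- function(frame) nrow(frame$coords)

## indices of backbone alpha-carbons
ca_indices <- function(frame) {
  idx <- which(frame$atom_names == "CA")
  if (length(idx) == 0L) idx <- seq_len(n_atoms(frame))
  idx
}

#' Atom selection
#'
#' @param chain optional chain label(s) to keep.
#' @param residues optional integer vector of residue ids to keep (use
#'   `a:b` for a range).
#' @param heavy_only drop hydrogens (atom names starting with H after any
#'   leading digits)?
#' @return A `dect_selection` list.
#' @export
frame_selection <- function(chain = NULL, residues = NULL, heavy_only = FALSE) {
  structure(list(chain = chain, residues = residues,
                 heavy_only = isTRUE(heavy_only)),
            class = "dect_selection")
}

apply_selection <- function(frame, selection) {
  if (is.null(selection)) return(frame)
  keep <- rep(TRUE, n_atoms(frame))
  if (!is.null(selection$chain))
    keep <- keep & frame$chain_ids %in% selection$chain
  if (!is.null(selection$residues))
    keep <- keep & frame$residue_ids %in% selection$residues
  if (isTRUE(selection$heavy_only))
    keep <- keep & !grepl("^[0-9]*H", frame$atom_names)
  if (!any(keep)) stop_("selection removes every atom")
  subset_frame(frame, which(keep))
}

subset_frame <- function(frame, idx) {
  structure_frame(frame$coords[idx, , drop = FALSE], frame$atom_names[idx],
                  frame$residue_ids[idx], frame$residue_names[idx],
                  frame$chain_ids[idx], frame$class_label, frame$frame_time)
}

#' Read structure frames from PDB or XYZ files
#'
#' PDB files are parsed with \pkg{bio3d}; a multi-model file (MODEL/ENDMDL
#' records) contributes one frame per model.  Plain-text XYZ tables must have
#' columns `name x y z` (one atom per line, whitespace separated).  For atoms
#' with alternate locations, altLoc "" or "A" is kept.
#'
#' @param paths character vector of file paths, read in order.
#' @param selection optional [frame_selection()] applied to every frame.
#' @param class_label label (0/1) assigned to all frames read.
#' @return An ensemble: list with `frames` (list of `dect_frame`) and the
#'   applied `selection`, class `dect_ensemble`.
#' @export
read_frames <- function(paths, selection = NULL, class_label = 0L) {
  frames <- list()
  for (p in paths) {
    if (!file.exists(p)) stop_("file not found: %s", p)
    new <- if (grepl("\\.xyz$|\\.txt$", p, ignore.case = TRUE))
      list(read_xyz_frame(p, class_label)) else read_pdb_frames(p, class_label)
    frames <- c(frames, new)
  }
  if (length(frames) == 0L) stop_("no frames read")
  frames <- lapply(frames, apply_selection, selection = selection)
  structure(list(frames = frames, selection = selection),
            class = "dect_ensemble")
}

read_pdb_frames <- function(path, class_label) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop_("cannot parse PDB %s: %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  lapply(seq_len(nrow(xyz)), function(i) {
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    structure_frame(m, at$elety[keep], at$resno[keep], at$resid[keep],
                    at$chain[keep], class_label)
  })
}

read_xyz_frame <- function(path, class_label) {
  tb <- tryCatch(utils::read.table(path, stringsAsFactors = FALSE),
                 error = function(e) stop_("cannot parse XYZ %s: %s",
                                           path, conditionMessage(e)))
  if (ncol(tb) < 4L) stop_("XYZ table %s needs columns: name x y z", path)
  structure_frame(as.matrix(tb[, 2:4]), atom_names = tb[, 1],
                  class_label = class_label)
}

#' Write frames to a PDB file
#'
#' Writes one MODEL per frame.  Optional per-atom scores go into the
#' B-factor column, clamped to `[0, 99.99]` at 2 decimals.
#'
#' @param frames list of `dect_frame` (or a `dect_ensemble`).
#' @param path output file.
#' @param b_factors optional numeric vector (one value per atom) recycled
#'   across frames.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, b_factors = NULL) {
  if (inherits(frames, "dect_ensemble")) frames <- frames$frames
  if (inherits(frames, "dect_frame")) frames <- list(frames)
  n <- n_atoms(frames[[1L]])
  b <- if (is.null(b_factors)) rep(0, n) else pmin(pmax(b_factors, 0), 99.99)
  if (length(b) != n) stop_("b_factors length %d != %d atoms", length(b), n)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (n_atoms(fr) != n) stop_("all frames must share one atom count")
    writeLines(sprintf("MODEL     %4d", i), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      seq_len(n) %% 100000L,
      substr(fr$atom_names, 1, 4),
      substr(fr$residue_names, 1, 3), substr(fr$chain_ids, 1, 1),
      fr$residue_ids %% 10000L,
      fr$coords[, 1], fr$coords[, 2], fr$coords[, 3], 1, round(b, 2))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
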