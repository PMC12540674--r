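#' Construct a molecular structure
#'
#' A `Structure` is an atom table plus one coordinate set in Angstrom,
#' optionally carrying per-atom van der Waals radii (needed by [sasa()] and
#' [pore_radius_profile()]).
#'
#' @param atoms data frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resno`, `element`. Residue numbers within a chain must be non-decreasing.
#' @param coords numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param vdw optional numeric vector of per-atom van der Waals radii
#'   (Angstrom, all positive), or `NULL`.
#' @return An object of class `Structure`.
#' @export
structure_new <- function(atoms, coords, vdw = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("serial", "name", "resname", "chain", "resno", "element")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L)
    stop("coords must have 3 columns (x, y, z in Angstrom)", call. = FALSE)
  if (nrow(coords) != nrow(atoms))
    stop("coords rows (", nrow(coords), ") != atom count (", nrow(atoms), ")",
         call. = FALSE)
  for (ch in unique(atoms$chain)) {
    rn <- atoms$resno[atoms$chain == ch]
    if (is.unsorted(rn))
      stop("residue numbers in chain '", ch, "' are not non-decreasing",
           call. = FALSE)
  }
  if (!is.null(vdw)) {
    vdw <- as.numeric(vdw)
    if (length(vdw) != nrow(atoms))
      stop("vdw length != atom count", call. = FALSE)
    if (any(!is.finite(vdw)) || any(vdw <= 0))
      stop("all vdW radii must be finite and > 0", call. = FALSE)
  }
  out <- list(atoms = atoms, coords = coords, vdw = vdw)
  class(out) <- "Structure"
  out
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)",
      if (!is.null(x$vdw)) "(vdW radii set)" else "", "\n")
  invisible(x)
}

#' Number of atoms in a structure or trajectory frame
#' @param x a `Structure` or `Trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Structure")) return(nrow(x$atoms))
  if (inherits(x, "Trajectory")) return(nrow(x$atoms))
  stop("n_atoms: not a Structure or Trajectory", call. = FALSE)
}

# small built-in element table, Bondi-style radii (Angstrom)
.vdw_table <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, CA = 2.31, NA. = 2.27,
  MG = 1.73, ZN = 1.39, FE = 1.40, K = 2.75
)

#' Look up van der Waals radii by element symbol
#'
#' A small built-in table (Bondi-style radii) covering the elements common in
#' protein/ligand structures; unknown elements receive `default`.
#'
#' @param elements character vector of element symbols (case-insensitive).
#' @param default radius (Angstrom) assigned to unknown elements.
#' @return numeric vector of radii, same length as `elements`.
#' @export
element_vdw <- function(elements, default = 1.70) {
  key <- toupper(trimws(as.character(elements)))
  key[key == "NA"] <- "NA."
  r <- .vdw_table[key]
  r[is.na(r)] <- default
  unname(r)
}

#' Construct a trajectory
#'
#' A `Trajectory` is an ordered set of coordinate frames sharing a single
#' atom table. The analysis selection defaults to C-alpha atoms when the
#' atom table names any (`name == "CA"`), otherwise to all atoms.
#'
#' @param atoms shared atom table (see [structure_new()]).
#' @param frames list of coordinate matrices (n_atoms x 3, Angstrom), or a
#'   3-d array `(n_atoms, 3, n_frames)`.
#' @param times optional per-frame times in ps.
#' @param selection optional integer vector of atom indices used by RMSD /
#'   RMSF / PCA; default C-alpha subset.
#' @return An object of class `Trajectory`.
#' @export
trajectory_new <- function(atoms, frames, times = NULL, selection = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (!is.list(frames) || !length(frames))
    stop("frames must be a non-empty list of coordinate matrices", call. = FALSE)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f); storage.mode(f) <- "double"; f
  })
  na <- nrow(atoms)
  for (i in seq_along(frames)) {
    if (ncol(frames[[i]]) != 3L || nrow(frames[[i]]) != na)
      stop("frame ", i, " has wrong shape (expected ", na, " x 3)",
           call. = FALSE)
  }
  if (!is.null(times) && length(times) != length(frames))
    stop("times length != frame count", call. = FALSE)
  if (is.null(selection)) {
    ca <- which(toupper(trimws(atoms$name)) == "CA")
    selection <- if (length(ca)) ca else seq_len(na)
  }
  selection <- as.integer(selection)
  if (!length(selection) || any(selection < 1L) || any(selection > na))
    stop("selection indices out of range", call. = FALSE)
  out <- list(atoms = atoms, frames = frames, times = times,
              selection = selection)
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,", nrow(x$atoms), "atoms,",
      length(x$selection), "selected\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "Trajectory"))
  length(traj$frames)
}

#' Extract one frame of a trajectory as a Structure
#' @param traj a `Trajectory`.
#' @param i frame index.
#' @param vdw optional per-atom radii to attach.
#' @return a `Structure`.
#' @export
frame_structure <- function(traj, i, vdw = NULL) {
  stopifnot(inherits(traj, "Trajectory"))
  i <- as.integer(i)
  if (i < 1L || i > length(traj$frames))
    stop("frame index out of range", call. = FALSE)
  structure_new(traj$atoms, traj$frames[[i]], vdw = vdw)
}
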