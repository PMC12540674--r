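#' Read a structure from file
#'
#' Two dialects are supported: fixed-width PDB (`ATOM`/`HETATM`, via bio3d)
#' and a plain CSV xyz-table with columns `atom,x,y,z` (optionally
#' `name,element`). Coordinates are Angstrom in both dialects. Atoms are
#' kept exactly in file order.
#'
#' @param path file path.
#' @param dialect `"auto"` (by extension), `"pdb"` or `"xyz"`.
#' @param default_vdw radius assigned to elements missing from the built-in
#'   table (Angstrom).
#' @return a `Structure` with `vdw` filled from [element_vdw()].
#' @export
read_structure <- function(path, dialect = c("auto", "pdb", "xyz"),
                           default_vdw = 1.70) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (dialect == "auto") dialect <- .guess_dialect(path)
  if (dialect == "pdb") {
    pdb <- .read_pdb_checked(path)
    atoms <- .atoms_from_bio3d(pdb)
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[1L, ] else as.numeric(pdb$xyz)
    coords <- matrix(xyz, ncol = 3L, byrow = TRUE)
  } else {
    tab <- .read_xyz_table(path, need_frame = FALSE)
    atoms <- tab$atoms
    coords <- tab$frames[[1L]]
  }
  structure_new(atoms, coords,
                vdw = element_vdw(atoms$element, default = default_vdw))
}

#' Write a structure to file
#'
#' Inverse of [read_structure()]. PDB output uses fixed-width ATOM records
#' (coordinates to 3 decimals, so round-trips are exact to 5e-4 Angstrom);
#' the xyz dialect writes coordinates at full precision.
#'
#' @param s a `Structure`.
#' @param path output path.
#' @param dialect `"pdb"` or `"xyz"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, dialect = c("pdb", "xyz")) {
  stopifnot(inherits(s, "Structure"))
  dialect <- match.arg(dialect)
  if (nrow(s$atoms) == 0L) stop("refusing to write an empty structure",
                                call. = FALSE)
  if (dialect == "pdb") {
    .write_pdb_frames(s$atoms, list(s$coords), path)
  } else {
    .write_xyz_table(s$atoms, list(s$coords), path, with_frame = FALSE)
  }
  invisible(path)
}

#' Read a trajectory from file
#'
#' Multi-model PDB (one `MODEL`/`ENDMDL` block per frame) is the canonical
#' interchange format; the CSV xyz-table dialect (`frame,atom,x,y,z`) is
#' accepted for synthetic data. All frames share one atom table.
#'
#' @inheritParams read_structure
#' @param selection optional atom-index selection (default C-alpha atoms,
#'   falling back to all atoms when none are named `CA`).
#' @return a `Trajectory`.
#' @export
read_trajectory <- function(path, dialect = c("auto", "pdb", "xyz"),
                            selection = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read '", path, "'", call. = FALSE)
  if (dialect == "auto") dialect <- .guess_dialect(path)
  if (dialect == "pdb") {
    pdb <- .read_pdb_checked(path, multi = TRUE)
    atoms <- .atoms_from_bio3d(pdb)
    xyz <- pdb$xyz
    if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
    frames <- lapply(seq_len(nrow(xyz)), function(i)
      matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  } else {
    tab <- .read_xyz_table(path, need_frame = TRUE)
    atoms <- tab$atoms
    frames <- tab$frames
  }
  trajectory_new(atoms, frames, selection = selection)
}

#' Write a trajectory to file
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @param dialect `"pdb"` (multi-model) or `"xyz"` (CSV table).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("pdb", "xyz")) {
  stopifnot(inherits(traj, "Trajectory"))
  dialect <- match.arg(dialect)
  if (dialect == "pdb") {
    .write_pdb_frames(traj$atoms, traj$frames, path)
  } else {
    .write_xyz_table(traj$atoms, traj$frames, path, with_frame = TRUE)
  }
  invisible(path)
}

.guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("pdb", "ent")) return("pdb")
  if (ext %in% c("csv", "xyz", "tsv", "txt")) return("xyz")
  # peek: PDB record names at line starts
  head1 <- readLines(path, n = 5L, warn = FALSE)
  if (any(grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER)", head1))) "pdb" else "xyz"
}

.read_pdb_checked <- function(path, multi = FALSE) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0L)
    stop("no ATOM/HETATM records in '", path, "'", call. = FALSE)
  pdb
}

.atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elesy <- a$elesy
  if (is.null(elesy)) elesy <- rep(NA_character_, nrow(a))
  # fall back on the first letter of the atom name when the element column
  # is blank (common in minimal hand-written files)
  blank <- is.na(elesy) | trimws(elesy) == ""
  elesy[blank] <- substr(gsub("[0-9]", "", trimws(a$elety[blank])), 1L, 1L)
  data.frame(serial = a$eleno, name = trimws(a$elety), resname = trimws(a$resid),
             chain = chain, resno = a$resno, element = toupper(trimws(elesy)),
             stringsAsFactors = FALSE)
}

.write_pdb_frames <- function(atoms, frames, path) {
  xyz <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  ok <- tryCatch({
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = atoms$resno, resid = atoms$resname,
                     eleno = atoms$serial, elety = atoms$name,
                     chain = atoms$chain, elesy = atoms$element)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("cannot write PDB file '", path, "'", call. = FALSE)
  invisible(path)
}

# CSV xyz-table dialect ------------------------------------------------------

.read_xyz_table <- function(path, need_frame = FALSE) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("failed to parse xyz-table '", path,
                                          "': ", conditionMessage(e),
                                          call. = FALSE))
  need <- c("atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("xyz-table '", path, "' lacks column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  if (!"frame" %in% names(df)) {
    if (need_frame && anyDuplicated(df$atom))
      stop("xyz-table '", path, "' has duplicate atom ids but no frame column",
           call. = FALSE)
    df$frame <- 1L
  }
  for (cn in c("frame", "atom", "x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("xyz-table '", path, "': non-numeric '", cn, "' at line ",
           bad[1L] + 1L, call. = FALSE)  # +1 for the header line
    df[[cn]] <- v
  }
  frames_id <- sort(unique(df$frame))
  first <- df[df$frame == frames_id[1L], ]
  ord <- order(first$atom)
  atom_ids <- first$atom[ord]
  name <- if ("name" %in% names(df)) as.character(first$name[ord])
          else rep("CA", length(atom_ids))
  element <- if ("element" %in% names(df)) as.character(first$element[ord])
             else rep("C", length(atom_ids))
  atoms <- data.frame(serial = as.integer(atom_ids), name = name,
                      resname = "GLY", chain = "A",
                      resno = seq_along(atom_ids), element = toupper(element),
                      stringsAsFactors = FALSE)
  frames <- lapply(frames_id, function(fr) {
    sub <- df[df$frame == fr, ]
    if (nrow(sub) != length(atom_ids))
      stop("xyz-table '", path, "': frame ", fr, " has ", nrow(sub),
           " atoms, expected ", length(atom_ids), call. = FALSE)
    sub <- sub[order(sub$atom), ]
    unname(as.matrix(sub[, c("x", "y", "z")]))
  })
  list(atoms = atoms, frames = frames)
}

.write_xyz_table <- function(atoms, frames, path, with_frame = TRUE) {
  rows <- lapply(seq_along(frames), function(i) {
    data.frame(frame = i, atom = atoms$serial, x = frames[[i]][, 1L],
               y = frames[[i]][, 2L], z = frames[[i]][, 3L],
               name = atoms$name, element = atoms$element,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!with_frame) out$frame <- NULL
  ok <- tryCatch({ utils::write.csv(out, path, row.names = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("cannot write xyz-table '", path, "'", call. = FALSE)
  invisible(path)
}
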