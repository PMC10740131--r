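## Containers and readers for multi-frame coordinate data. Coordinates are
## stored in nm throughout (PDB/XYZ files are Angstrom; converted on ingest).

#' Van der Waals radii (nm) used by default
#'
#' Small element-to-radius map; unknown elements fall back to 0.17 nm.
#' @param elements Character vector of element symbols.
#' @return Numeric vector of radii in nm.
#' @export
vdw_radii <- function(elements) {
  tab <- c(C = 0.17, N = 0.155, O = 0.152, S = 0.18, H = 0.12)
  r <- tab[toupper(elements)]
  r[is.na(r)] <- 0.17
  unname(r)
}

## Guess the element from a PDB-style atom name ("CA" -> C, "1HB" -> H ...)
guess_element <- function(atom_names) {
  vapply(atom_names, function(nm) {
    nm <- gsub("[0-9' ]", "", nm)
    first <- toupper(substr(nm, 1, 1))
    if (first %in% c("C", "N", "O", "S", "H")) first else first
  }, character(1), USE.NAMES = FALSE)
}

#' Single coordinate frame
#'
#' One snapshot of a structure: parallel per-atom arrays of names, residue
#' ids, coordinates (nm), interaction-class flags and van der Waals radii.
#' Flags default from the element: N/O are potential hydrogen-bond donors
#' and acceptors (donor capability is confirmed geometrically, by an attached
#' hydrogen, in [count_hbonds()]); C/S/H count as hydrophobic, the rest as
#' hydrophilic.
#'
#' @param coords n x 3 numeric matrix of positions in nm.
#' @param atom_names Character vector (default "X1".."Xn").
#' @param residue_ids Integer vector (default all 1).
#' @param elements Element symbols; guessed from `atom_names` when missing.
#' @param radii Per-atom vdW radii in nm (default [vdw_radii()] lookup).
#' @param is_donor,is_acceptor,is_hydrophobic Logical per-atom flags
#'   (defaults derived from `elements`).
#' @return An object of class `traj_frame`.
#' @export
traj_frame <- function(coords, atom_names = NULL, residue_ids = NULL,
                       elements = NULL, radii = NULL, is_donor = NULL,
                       is_acceptor = NULL, is_hydrophobic = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L || any(!is.finite(coords)))
    stop_invalid("coords must be a finite n x 3 matrix")
  n <- nrow(coords)
  if (is.null(atom_names)) atom_names <- paste0("X", seq_len(n))
  if (is.null(residue_ids)) residue_ids <- rep(1L, n)
  if (is.null(elements)) elements <- guess_element(atom_names)
  if (is.null(radii)) radii <- vdw_radii(elements)
  if (is.null(is_acceptor)) is_acceptor <- elements %in% c("N", "O")
  if (is.null(is_donor)) is_donor <- elements %in% c("N", "O")
  if (is.null(is_hydrophobic)) is_hydrophobic <- elements %in% c("C", "S", "H")
  lens <- c(length(atom_names), length(residue_ids), length(elements),
            length(radii), length(is_donor), length(is_acceptor),
            length(is_hydrophobic))
  if (any(lens != n))
    stop_invalid("per-atom arrays must all have length nrow(coords)")
  structure(list(coords = unname(coords), atom_names = atom_names,
                 residue_ids = residue_ids, elements = elements,
                 radii = as.numeric(radii), is_donor = is_donor,
                 is_acceptor = is_acceptor, is_hydrophobic = is_hydrophobic),
            class = "traj_frame")
}

#' @export
print.traj_frame <- function(x, ...) {
  cat(sprintf("<traj_frame> %d atoms\n", nrow(x$coords)))
  invisible(x)
}

#' Multi-frame trajectory
#'
#' @param frames List of [traj_frame()] objects sharing the same atom roster.
#' @param times Frame times in ps, strictly increasing (default 0, 1, 2, ...).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, times = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1L,
            all(vapply(frames, inherits, logical(1), "traj_frame")))
  n <- nrow(frames[[1]]$coords)
  if (!all(vapply(frames, function(f) nrow(f$coords), integer(1)) == n))
    stop_invalid("all frames must have the same atom count")
  roster <- frames[[1]]$atom_names
  if (!all(vapply(frames, function(f) identical(f$atom_names, roster),
                  logical(1))))
    stop_invalid("all frames must share the same atom roster")
  if (is.null(times)) times <- seq_along(frames) - 1
  if (length(times) != length(frames) || any(diff(times) <= 0))
    stop_invalid("times must be strictly increasing, one per frame")
  structure(list(frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g-%g ps\n",
              length(x$frames), nrow(x$frames[[1]]$coords),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Read a (multi-model) PDB file as a trajectory
#'
#' Parses ATOM/HETATM records (MODEL/ENDMDL delimited frames) and converts
#' coordinates from Angstrom to nm. Atom classification defaults to the
#' element-based rules of [traj_frame()].
#'
#' @param file Path to a PDB file.
#' @param times Optional frame times in ps.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(file, times = NULL) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  an <- pdb$atom$elety
  rid <- pdb$atom$resno
  el <- pdb$atom$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- guess_element(an)
  xyz <- pdb$xyz  # nframes x 3n, Angstrom
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i) {
    co <- matrix(xyz[i, ], ncol = 3, byrow = TRUE) / 10
    traj_frame(co, atom_names = an, residue_ids = rid, elements = el)
  })
  trajectory(frames, times = times)
}

#' Read a multi-frame XYZ file as a trajectory
#'
#' Standard XYZ blocks (atom count, comment, `element x y z` lines in
#' Angstrom), converted to nm.
#'
#' @inheritParams read_trajectory_pdb
#' @return A [trajectory()].
#' @export
read_trajectory_xyz <- function(file, times = NULL) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop_invalid("malformed XYZ: expected atom count at line %d", i)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, character(1), 1L)
    co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3))) / 10
    frames[[length(frames) + 1L]] <- traj_frame(co, atom_names = el,
                                                elements = toupper(el))
    i <- i + 2L + n
  }
  if (!length(frames)) stop_invalid("no frames found in XYZ file")
  trajectory(frames, times = times)
}
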