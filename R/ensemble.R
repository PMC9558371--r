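#' Ordered coordinate frames with PDB-style atom metadata
#'
#' An `ensemble` pairs an atom table (shared by every frame) with a frame x
#' coordinate matrix.  Coordinates are stored in nanometres; residue numbers
#' are author (PDB) numbers, so KIT residues such as D810, R791 or K623 are
#' addressed by their crystallographic numbers without renumbering.
#'
#' @param atoms Data frame with columns `elety` (atom name, PDB convention:
#'   N, CA, C, O, NZ, OE1, ...), `resid` (3-letter residue name), `resno`
#'   (author residue number) and optionally `chain` and `eleno`.
#' @param xyz Numeric matrix of dimension `n_frames x (3 * n_atoms)`, frame
#'   coordinates in nm laid out `x1, y1, z1, x2, ...` (bio3d convention), or
#'   a numeric vector for a single frame.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "resid", "resno")
  if (!all(need %in% names(atoms)))
    stop("atom table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$eleno)) atoms$eleno <- seq_len(nrow(atoms))
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop("xyz has ", ncol(xyz), " columns but the atom table implies ",
         3L * nrow(atoms), call. = FALSE)
  if (nrow(xyz) < 1L) stop("an ensemble needs at least one frame", call. = FALSE)
  structure(list(atoms = atoms, xyz = xyz), class = "ensemble")
}

#' @rdname ensemble
#' @param ens An `ensemble`.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' @rdname ensemble
#' @export
n_atoms <- function(ens) nrow(ens$atoms)

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frame(s), %d atoms, residues %d-%d\n",
              n_frames(x), n_atoms(x), min(x$atoms$resno), max(x$atoms$resno)))
  invisible(x)
}

#' Select atom indices by residue number and atom name
#'
#' @param ens An [ensemble()].
#' @param resno Residue numbers to keep (`NULL` = all).
#' @param elety Atom names to keep (`NULL` = all); the backbone is
#'   `c("N", "CA", "C", "O")`.
#' @return Integer vector of atom indices (rows of `ens$atoms`).
#' @export
select_atoms <- function(ens, resno = NULL, elety = NULL) {
  stopifnot(inherits(ens, "ensemble"))
  keep <- rep(TRUE, n_atoms(ens))
  if (!is.null(resno)) {
    missing <- setdiff(resno, unique(ens$atoms$resno))
    if (length(missing))
      stop("residue(s) absent from ensemble: ",
           paste(missing, collapse = ", "), call. = FALSE)
    keep <- keep & ens$atoms$resno %in% resno
  }
  if (!is.null(elety)) keep <- keep & ens$atoms$elety %in% elety
  idx <- which(keep)
  if (length(idx) == 0L) stop("atom selection is empty", call. = FALSE)
  idx
}

# columns of the xyz matrix covered by atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

#' Evenly spaced frame subsample
#'
#' Picks `n` frames at indices `round(k * (F - 1) / (n - 1)) + 1` for
#' `k = 0 ... n-1` (half-up rounding), so the first and last frames are
#' always included.  The default of 750 frames matches the snapshot count
#' conventionally used for per-frame metric distributions.
#'
#' @param ens An [ensemble()] with `F` frames.
#' @param n Number of frames to keep, `1 <= n <= F`.
#' @return An [ensemble()] with `n` frames.
#' @export
subsample_evenly <- function(ens, n = 750L) {
  stopifnot(inherits(ens, "ensemble"))
  n <- as.integer(n)
  nf <- n_frames(ens)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n > nf)
    stop("requested ", n, " frames from an ensemble of ", nf, call. = FALSE)
  idx <- if (n == 1L) 1L else
    as.integer(floor((0:(n - 1L)) * (nf - 1) / (n - 1) + 0.5)) + 1L
  ensemble(ens$atoms, ens$xyz[idx, , drop = FALSE])
}

#' Read a (multi-model) PDB file into an ensemble
#'
#' Uses bio3d to parse the file; every MODEL becomes one frame.  PDB
#' coordinates (angstrom) are converted to nanometres.
#'
#' @param path Path to a PDB file.
#' @return An [ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  if (!file.exists(path)) stop("no such PDB file: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  atoms <- data.frame(elety = pdb$atom$elety, resid = pdb$atom$resid,
                      resno = pdb$atom$resno,
                      chain = ifelse(is.na(pdb$atom$chain), "A",
                                     pdb$atom$chain),
                      eleno = pdb$atom$eleno, stringsAsFactors = FALSE)
  ensemble(atoms, xyz / 10)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Frames become MODEL/ENDMDL blocks with standard atom naming; coordinates
#' are converted from nm to angstrom.
#'
#' @param ens An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "ensemble"))
  bio3d::write.pdb(file = path, xyz = ens$xyz * 10,
                   resno = ens$atoms$resno, resid = ens$atoms$resid,
                   elety = ens$atoms$elety, chain = ens$atoms$chain,
                   eleno = ens$atoms$eleno)
  invisible(path)
}
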