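#' Signed dihedral (torsion) angle of four points
#'
#' Standard right-handed torsion: looking down the p2-p3 bond, the angle is
#' positive when p4 must be rotated clockwise to eclipse p1.  Accepts single
#' points (length-3 vectors) or per-frame point matrices (`n x 3`), in any
#' consistent length unit.
#'
#' @param p1,p2,p3,p4 Length-3 vectors or `n x 3` matrices.
#' @return Angle(s) in degrees, in (-180, 180].  A planar cis (eclipsed)
#'   arrangement gives 0, trans gives 180.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L)
  p1 <- as_mat(p1); p2 <- as_mat(p2); p3 <- as_mat(p3); p4 <- as_mat(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  rowcross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- rowcross(b1, b2)
  n2 <- rowcross(b2, b3)
  if (any(rowSums(n1^2) < 1e-20) || any(rowSums(n2^2) < 1e-20))
    stop("collinear atom triple: dihedral plane undefined", call. = FALSE)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- rowcross(n1, b2n)
  x <- rowSums(n1 * n2)
  y <- -rowSums(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# per-frame coordinates (n_frames x 3) of one uniquely identified atom
atom_coords <- function(ens, resno, elety) {
  i <- which(ens$atoms$resno == resno & ens$atoms$elety == elety)
  if (length(i) == 0L)
    stop("atom ", elety, " of residue ", resno, " not found", call. = FALSE)
  if (length(i) > 1L)
    stop("atom ", elety, " of residue ", resno, " is not unique",
         call. = FALSE)
  ens$xyz[, xyz_cols(i), drop = FALSE]
}

metric_series <- function(name, values, unit) {
  structure(list(name = name, values = as.numeric(values), unit = unit),
            class = "metric_series")
}

#' @export
print.metric_series <- function(x, ...) {
  cat(sprintf("%s (%s): %d frame(s), mean %.4g\n", x$name, x$unit,
              length(x$values), mean(x$values)))
  invisible(x)
}

#' Backbone Phi and Psi series of one residue
#'
#' `residue_phi` measures the torsion over atoms C(i-1)-N(i)-CA(i)-C(i);
#' residue `resno - 1` must be present, so the first residue of a chain has
#' no Phi.  `residue_psi` defaults to the carbonyl torsion
#' N(i)-CA(i)-C(i)-O(i) — the definition used for the kinase DFG/HDR
#' descriptors here — rather than the conventional N(i)-CA(i)-C(i)-N(i+1);
#' set `convention = "next_n"` for the conventional angle.
#'
#' @param ens An [ensemble()].
#' @param resno Author residue number.
#' @param convention For `residue_psi`: `"carbonyl"` (default, atom O) or
#'   `"next_n"` (amide nitrogen of residue `resno + 1`).
#' @return A `metric_series` of per-frame angles in degrees.
#' @export
residue_phi <- function(ens, resno) {
  stopifnot(inherits(ens, "ensemble"))
  if (!any(ens$atoms$resno == resno - 1L))
    stop("Phi of residue ", resno, " needs residue ", resno - 1L,
         ", which is absent (first residue has no Phi)", call. = FALSE)
  ang <- dihedral_angle(atom_coords(ens, resno - 1L, "C"),
                        atom_coords(ens, resno, "N"),
                        atom_coords(ens, resno, "CA"),
                        atom_coords(ens, resno, "C"))
  metric_series(paste0("phi_", resno), ang, "degrees")
}

#' @rdname residue_phi
#' @export
residue_psi <- function(ens, resno, convention = c("carbonyl", "next_n")) {
  stopifnot(inherits(ens, "ensemble"))
  convention <- match.arg(convention)
  last <- if (convention == "carbonyl") atom_coords(ens, resno, "O") else
    atom_coords(ens, resno + 1L, "N")
  ang <- dihedral_angle(atom_coords(ens, resno, "N"),
                        atom_coords(ens, resno, "CA"),
                        atom_coords(ens, resno, "C"),
                        last)
  metric_series(paste0("psi_", resno), ang, "degrees")
}

#' DFG-motif backbone descriptor
#'
#' Phi and Psi series of the DFG aspartate and phenylalanine (KIT numbering
#' D810 and F811 by default).  Raw angle series are returned; no in/out
#' binary call is made — in/out boundaries are study-specific and can be
#' applied by the caller.
#'
#' @param ens An [ensemble()].
#' @param asp_resno,phe_resno Author residue numbers of the DFG Asp and Phe.
#' @param ... Passed to [residue_psi()] (e.g. `convention`).
#' @return Named list of four `metric_series`: `phi_asp`, `psi_asp`,
#'   `phi_phe`, `psi_phe`.
#' @export
dfg_descriptor <- function(ens, asp_resno = 810L, phe_resno = 811L, ...) {
  list(phi_asp = residue_phi(ens, asp_resno),
       psi_asp = residue_psi(ens, asp_resno, ...),
       phi_phe = residue_phi(ens, phe_resno),
       psi_phe = residue_psi(ens, phe_resno, ...))
}

#' HDR-motif orientation descriptor
#'
#' Phi series of the HDR arginine (KIT numbering R791 by default).
#'
#' @param ens An [ensemble()].
#' @param arg_resno Author residue number of the HDR Arg.
#' @return A `metric_series`.
#' @export
hdr_descriptor <- function(ens, arg_resno = 791L) {
  residue_phi(ens, arg_resno)
}

#' Minimum salt-bridge distance between a lysine and an acidic side chain
#'
#' Per frame, the minimum distance over all pairs of lysine amine nitrogens
#' (NZ) and carboxylate oxygens (OE1/OE2 for Glu, OD1/OD2 for Asp) of the
#' acidic residue — the standard measure of the catalytic K623-E640 and
#' K623-D810 contacts.
#'
#' @param ens An [ensemble()].
#' @param lys_resnum,acidic_resnum Author residue numbers.
#' @return A `metric_series` of per-frame distances in nm.
#' @export
salt_bridge_distance <- function(ens, lys_resnum, acidic_resnum) {
  stopifnot(inherits(ens, "ensemble"))
  n_idx <- which(ens$atoms$resno == lys_resnum & ens$atoms$elety == "NZ")
  o_idx <- which(ens$atoms$resno == acidic_resnum &
                   ens$atoms$elety %in% c("OE1", "OE2", "OD1", "OD2"))
  if (length(n_idx) == 0L)
    stop("no NZ amine nitrogen on residue ", lys_resnum, call. = FALSE)
  if (length(o_idx) == 0L)
    stop("no carboxylate oxygens (OE1/OE2/OD1/OD2) on residue ",
         acidic_resnum, call. = FALSE)
  d <- vapply(seq_len(n_frames(ens)), function(f) {
    dm <- outer(n_idx, o_idx, Vectorize(function(i, j) {
      sqrt(sum((ens$xyz[f, xyz_cols(i)] - ens$xyz[f, xyz_cols(j)])^2))
    }))
    min(dm)
  }, numeric(1))
  metric_series(sprintf("saltbridge_%d_%d", lys_resnum, acidic_resnum),
                d, "nm")
}
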