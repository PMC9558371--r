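#' Synthetic work samples satisfying the Crooks fluctuation theorem
#'
#' Draws forward and reverse work values from the unique pair of Gaussian
#' distributions that satisfies the Crooks fluctuation theorem exactly for a
#' chosen free-energy difference and dissipated work: with
#' \eqn{\sigma^2 = 2 W_{diss} / \beta} (the fluctuation-dissipation
#' relation),
#' \deqn{W_f \sim N(\Delta G + W_{diss}, \sigma^2), \quad
#'       W_r \sim N(-\Delta G + W_{diss}, \sigma^2),}
#' so that \eqn{\ln[P_f(W) / P_r(-W)] = \beta (W - \Delta G)} holds
#' analytically.  Zero dissipation gives degenerate (delta) distributions at
#' \eqn{\pm\Delta G}.  The ground truth is recorded in the returned work set
#' (`dg_true`) for test oracles only.
#'
#' @param dg_true True free-energy difference, kJ/mol.
#' @param dissipation Mean dissipated work \eqn{W_{diss}}, kJ/mol, >= 0.
#' @param n_forward,n_reverse Number of transitions per direction (the
#'   default of 450 mirrors typical nonequilibrium switching campaigns).
#' @param temperature Temperature in kelvin.
#' @param seed Integer seed; identical specs and seeds give bitwise
#'   identical samples.  The caller's RNG state is preserved.
#' @param transformation_id Label for the generated transformation.
#' @return A [work_set()].
#' @export
generate_cft_work_samples <- function(dg_true, dissipation,
                                      n_forward = 450L, n_reverse = 450L,
                                      temperature = 310, seed = 1L,
                                      transformation_id = "synthetic") {
  stopifnot(is.numeric(dg_true), length(dg_true) == 1L)
  if (!is.numeric(dissipation) || dissipation < 0)
    stop("dissipation must be >= 0 kJ/mol", call. = FALSE)
  n_forward <- as.integer(n_forward); n_reverse <- as.integer(n_reverse)
  if (n_forward < 1L || n_reverse < 1L)
    stop("need at least one transition per direction", call. = FALSE)
  beta <- beta_from_temperature(temperature)
  sigma <- sqrt(2 * dissipation / beta)
  with_seed(seed, {
    fw <- stats::rnorm(n_forward, mean = dg_true + dissipation, sd = sigma)
    rv <- stats::rnorm(n_reverse, mean = -dg_true + dissipation, sd = sigma)
    work_set(fw, rv, temperature = temperature,
             transformation_id = transformation_id, dg_true = dg_true)
  })
}

## ---- idealized peptide geometry ------------------------------------------

# standard backbone internal coordinates (angstrom / degrees)
.pep_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.0, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  omega = 180.0)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place atom D from A, B, C with bond length |C-D|, angle B-C-D and torsion
# A-B-C-D (natural extension reference frame; angles in degrees)
nerf_place <- function(a, b, c_, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  bc <- c_ - b
  bc <- bc / sqrt(sum(bc^2))
  n <- cross3(b - a, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("degenerate geometry: collinear reference atoms",
                       call. = FALSE)
  n <- n / nn
  m <- cross3(n, bc)
  d2 <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  c_ + d2[1] * bc + d2[2] * m + d2[3] * n
}

# wrap angle(s) in degrees into (-180, 180]
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x == -180] <- 180
  x
}

# expand a scalar / per-residue vector / frame x residue matrix of angle
# targets to a full n_frames x n_res matrix
expand_targets <- function(x, n_frames, n_res, what) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(n_frames, n_res)))
      stop(what, " matrix must be n_frames x n_res", call. = FALSE)
    m <- x
  } else if (length(x) == 1L) {
    m <- matrix(x, n_frames, n_res)
  } else if (length(x) == n_res) {
    m <- matrix(x, n_frames, n_res, byrow = TRUE)
  } else {
    stop(what, " must be a scalar, a length-n_res vector, or an ",
         "n_frames x n_res matrix", call. = FALSE)
  }
  if (any(m <= -180 | m > 180))
    stop(what, " targets must lie in (-180, 180] degrees", call. = FALSE)
  m
}

#' Idealized peptide frames with prescribed backbone dihedrals
#'
#' Builds an all-backbone (N, CA, C, O) polypeptide by internal-coordinate
#' chain construction with standard bond lengths and angles, so that
#' measuring the backbone dihedrals on the output reproduces the prescribed
#' targets: `phi` is the torsion C(i-1)-N(i)-CA(i)-C(i) and `psi` the
#' carbonyl torsion N(i)-CA(i)-C(i)-O(i) (the same definitions used by
#' [residue_phi()] and [residue_psi()]).  The amide nitrogen of residue
#' i+1 is placed anti to the carbonyl oxygen, so the conventional
#' \eqn{\psi} (N-CA-C-N') equals `psi + 180` (wrapped).
#'
#' @param n_res Chain length in residues, >= 2.
#' @param n_frames Number of frames, >= 1.
#' @param phi,psi Dihedral targets in degrees, each in (-180, 180]: a
#'   scalar, a per-residue vector of length `n_res`, or an
#'   `n_frames x n_res` matrix.  `phi` is undefined for residue 1 and that
#'   column is ignored.
#' @param noise_sd Gaussian noise (degrees, >= 0) added independently to
#'   every dihedral target in every frame.
#' @param seed Integer seed for the noise; ignored when `noise_sd = 0`.
#' @param resno_start First author residue number (use e.g. 810 to emulate
#'   KIT numbering on a toy chain).
#' @param resid Residue name applied to all residues.
#' @return An [ensemble()] with 4 backbone atoms per residue, coordinates
#'   in nm.
#' @export
generate_peptide_frames <- function(n_res, n_frames = 1L, phi = -60,
                                    psi = 120, noise_sd = 0, seed = 1L,
                                    resno_start = 1L, resid = "ALA") {
  n_res <- as.integer(n_res); n_frames <- as.integer(n_frames)
  if (n_res < 2L) stop("chain needs >= 2 residues", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("noise_sd must be >= 0 degrees", call. = FALSE)
  phi_m <- expand_targets(phi, n_frames, n_res, "phi")
  psi_m <- expand_targets(psi, n_frames, n_res, "psi")
  if (noise_sd > 0) {
    noisy <- with_seed(seed, list(
      phi = matrix(stats::rnorm(length(phi_m), 0, noise_sd), nrow(phi_m)),
      psi = matrix(stats::rnorm(length(psi_m), 0, noise_sd), nrow(psi_m))))
    phi_m <- wrap_angle(phi_m + noisy$phi)
    psi_m <- wrap_angle(psi_m + noisy$psi)
  }
  g <- .pep_geom
  n_atoms <- 4L * n_res
  xyz <- matrix(NA_real_, n_frames, 3L * n_atoms)
  for (f in seq_len(n_frames)) {
    coords <- matrix(NA_real_, n_atoms, 3L)  # angstrom
    at <- function(i) coords[i, ]
    # residue r occupies rows 4r-3..4r as N, CA, C, O
    iN <- function(r) 4L * r - 3L
    iCA <- function(r) 4L * r - 2L
    iC <- function(r) 4L * r - 1L
    iO <- function(r) 4L * r
    coords[iN(1), ] <- c(0, 0, 0)
    coords[iCA(1), ] <- c(g$b_n_ca, 0, 0)
    th <- g$a_n_ca_c * pi / 180
    coords[iC(1), ] <- coords[iCA(1), ] +
      g$b_ca_c * c(-cos(th), sin(th), 0)
    coords[iO(1), ] <- nerf_place(at(iN(1)), at(iCA(1)), at(iC(1)),
                                  g$b_c_o, g$a_ca_c_o, psi_m[f, 1])
    for (r in 2:n_res) {
      p <- r - 1L
      # N(r): torsion N-CA-C-N' = conventional psi = carbonyl psi + 180
      coords[iN(r), ] <- nerf_place(at(iN(p)), at(iCA(p)), at(iC(p)),
                                    g$b_c_n, g$a_ca_c_n,
                                    wrap_angle(psi_m[f, p] + 180))
      coords[iCA(r), ] <- nerf_place(at(iCA(p)), at(iC(p)), at(iN(r)),
                                     g$b_n_ca, g$a_c_n_ca, g$omega)
      coords[iC(r), ] <- nerf_place(at(iC(p)), at(iN(r)), at(iCA(r)),
                                    g$b_ca_c, g$a_n_ca_c, phi_m[f, r])
      coords[iO(r), ] <- nerf_place(at(iN(r)), at(iCA(r)), at(iC(r)),
                                    g$b_c_o, g$a_ca_c_o, psi_m[f, r])
    }
    xyz[f, ] <- as.vector(t(coords)) / 10  # angstrom -> nm
  }
  atoms <- data.frame(
    elety = rep(c("N", "CA", "C", "O"), n_res),
    resid = resid,
    resno = rep(seq.int(resno_start, length.out = n_res), each = 4L),
    chain = "A", eleno = seq_len(n_atoms), stringsAsFactors = FALSE)
  ensemble(atoms, xyz)
}

#' Random-displacement ensemble with prescribed covariance modes
#'
#' Generates frames `mean + sum_m z_m * mode_m` with
#' `z_m ~ N(0, variance_m)`, i.e. an ensemble whose population covariance is
#' exactly the prescribed low-rank structure.  Used to test PCA recovery.
#'
#' @param mean Mean coordinates: an `n_atoms x 3` matrix or a length-`3N`
#'   vector, in nm.
#' @param modes `3N x k` matrix of mutually orthogonal mode vectors
#'   (normalized internally).
#' @param variances Length-`k` vector of per-mode variances, nm^2, >= 0.
#' @param n_frames Number of frames to draw.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param atoms Optional atom table (see [ensemble()]); by default a
#'   CA-only chain of alanines numbered 1..N.
#' @param orth_tol Orthogonality tolerance for the mode check.
#' @return An [ensemble()].
#' @export
generate_gaussian_ensemble <- function(mean, modes, variances,
                                       n_frames = 100L, seed = 1L,
                                       atoms = NULL, orth_tol = 1e-8) {
  if (is.matrix(mean)) mean <- as.vector(t(mean))
  mean <- as.numeric(mean)
  if (length(mean) %% 3L != 0L)
    stop("mean coordinates must have length 3N", call. = FALSE)
  modes <- as.matrix(modes)
  if (nrow(modes) != length(mean))
    stop("mode vectors must have 3N rows", call. = FALSE)
  variances <- as.numeric(variances)
  if (length(variances) != ncol(modes))
    stop("one variance per mode required", call. = FALSE)
  if (any(variances < 0)) stop("variances must be >= 0", call. = FALSE)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  norms <- sqrt(colSums(modes^2))
  if (any(norms == 0)) stop("zero-length mode vector", call. = FALSE)
  modes <- sweep(modes, 2L, norms, "/")
  gram <- crossprod(modes)
  if (max(abs(gram - diag(ncol(modes)))) > orth_tol)
    stop("mode vectors are not mutually orthogonal (tolerance ", orth_tol,
         ")", call. = FALSE)
  n_at <- length(mean) / 3L
  if (is.null(atoms))
    atoms <- data.frame(elety = "CA", resid = "ALA", resno = seq_len(n_at),
                        chain = "A", eleno = seq_len(n_at),
                        stringsAsFactors = FALSE)
  xyz <- with_seed(seed, {
    z <- matrix(stats::rnorm(n_frames * ncol(modes)), n_frames) %*%
      diag(sqrt(variances), ncol(modes))
    sweep(z %*% t(modes), 2L, mean, "+")
  })
  ensemble(atoms, xyz)
}

#' Minimal lysine/acidic-residue fixture with prescribed salt-bridge distances
#'
#' Builds a two-residue ensemble (LYS with an NZ amine nitrogen, plus GLU or
#' ASP with its two carboxylate oxygens) in which the minimum
#' amine-carboxylate distance in frame k equals `distances[k]` exactly; the
#' second oxygen is placed farther away by `second_offset`.
#'
#' @param distances Per-frame NZ-to-nearest-oxygen distances, nm.
#' @param acidic `"GLU"` (oxygens OE1/OE2) or `"ASP"` (OD1/OD2).
#' @param lys_resno,acidic_resno Author residue numbers (KIT defaults:
#'   K623 and E640).
#' @param second_offset Extra distance (nm) of the far oxygen.
#' @return An [ensemble()] with 3 atoms.
#' @export
salt_bridge_fixture <- function(distances, acidic = c("GLU", "ASP"),
                                lys_resno = 623L, acidic_resno = 640L,
                                second_offset = 0.2) {
  acidic <- match.arg(acidic)
  distances <- as.numeric(distances)
  if (length(distances) < 1L || any(distances < 0))
    stop("distances must be non-negative, with >= 1 frame", call. = FALSE)
  ox <- if (acidic == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
  atoms <- data.frame(
    elety = c("NZ", ox), resid = c("LYS", acidic, acidic),
    resno = c(lys_resno, acidic_resno, acidic_resno),
    chain = "A", eleno = 1:3, stringsAsFactors = FALSE)
  xyz <- t(vapply(distances, function(d)
    c(0, 0, 0, d, 0, 0, d + second_offset, 0, 0), numeric(9)))
  ensemble(atoms, xyz)
}
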