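#' Principal component analysis of a coordinate ensemble
#'
#' Builds the covariance model of atomic fluctuations used to map kinase
#' conformational ensembles onto a low-dimensional reference space.  Each
#' frame is first least-squares superposed onto the mean structure of the
#' selected atoms (iterated until the mean converges), then the
#' eigendecomposition of the 3N x 3N covariance of the selection is
#' computed.  Modes are orthonormal and sorted by non-increasing variance;
#' no mass weighting is applied.
#'
#' @param ens An [ensemble()] with at least 2 frames.
#' @param resno,elety Atom selection (see [select_atoms()]); the default
#'   takes the backbone atoms N, CA, C, O of all residues.  The global KIT
#'   reference uses `resno = c(571:688, 763:930)`.
#' @param atom_idx Explicit atom indices, overriding `resno`/`elety`.
#' @param superpose Superpose frames onto the selection mean before the
#'   covariance (default `TRUE`; disable for toy ensembles generated
#'   without global motion).  Superposition needs >= 3 selected atoms.
#' @return An object of class `pca_model`: `mean` (3n vector, nm), `modes`
#'   (3n x k orthonormal matrix), `variances` (nm^2, non-increasing),
#'   `explained` (fractions summing to 1), `selection` (atom table of the
#'   fitted selection) and `superpose`.
#' @export
fit_pca <- function(ens, resno = NULL, elety = c("N", "CA", "C", "O"),
                    atom_idx = NULL, superpose = TRUE) {
  stopifnot(inherits(ens, "ensemble"))
  if (n_frames(ens) < 2L)
    stop("PCA needs at least 2 frames", call. = FALSE)
  if (is.null(atom_idx)) atom_idx <- select_atoms(ens, resno, elety)
  x <- ens$xyz[, xyz_cols(atom_idx), drop = FALSE]
  if (superpose) {
    if (length(atom_idx) < 3L)
      stop("superposition needs >= 3 selected atoms", call. = FALSE)
    x <- superpose_to_mean(x)
  }
  mu <- colMeans(x)
  if (max(abs(sweep(x, 2L, mu))) < 1e-12)
    stop("all frames identical after superposition: zero covariance",
         call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  variances <- pc$sdev^2
  structure(
    list(mean = mu, modes = pc$rotation, variances = variances,
         explained = variances / sum(variances),
         selection = ens$atoms[atom_idx, c("elety", "resid", "resno",
                                           "chain")],
         superpose = superpose),
    class = "pca_model")
}

# iteratively superpose frames (rows of an F x 3n matrix) onto their mean
superpose_to_mean <- function(x, max_iter = 10L, tol = 1e-10) {
  ref <- x[1L, ]
  inds <- seq_len(ncol(x))
  for (i in seq_len(max_iter)) {
    x <- bio3d::fit.xyz(fixed = ref, mobile = x,
                        fixed.inds = inds, mobile.inds = inds)
    mu <- colMeans(x)
    if (sqrt(mean((mu - ref)^2)) < tol) break
    ref <- mu
  }
  x
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(3L, length(x$explained))
  cat(sprintf("pca_model: %d atoms, %d modes; explained PC1..PC%d: %s\n",
              nrow(x$selection), length(x$variances), k,
              paste(sprintf("%.3f", x$explained[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Project frames onto a fitted PCA model
#'
#' Selects the model's atoms from the target ensemble (matched by residue
#' number and atom name), superposes each frame onto the model mean (when
#' the model was fitted with superposition), subtracts the mean and takes
#' inner products with the modes.  Both simulation frames and external
#' (e.g. crystallographic) structures read from PDB can be projected.
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param ens An [ensemble()] containing the model's atoms.
#' @param n_modes Number of leading components to report (default 2,
#'   the usual PC1/PC2 map).
#' @return Matrix `n_frames x n_modes` of PC coordinates (nm), columns
#'   named `PC1`, `PC2`, ...
#' @export
project <- function(model, ens, n_modes = 2L) {
  stopifnot(inherits(model, "pca_model"), inherits(ens, "ensemble"))
  n_modes <- min(as.integer(n_modes), ncol(model$modes))
  sel <- model$selection
  idx <- vapply(seq_len(nrow(sel)), function(i) {
    j <- which(ens$atoms$resno == sel$resno[i] &
                 ens$atoms$elety == sel$elety[i])
    if (length(j) != 1L)
      stop("atom ", sel$elety[i], " of residue ", sel$resno[i],
           if (length(j) == 0L) " missing from" else " ambiguous in",
           " the ensemble being projected", call. = FALSE)
    j
  }, integer(1))
  x <- ens$xyz[, xyz_cols(idx), drop = FALSE]
  if (model$superpose) {
    inds <- seq_along(model$mean)
    x <- bio3d::fit.xyz(fixed = model$mean, mobile = x,
                        fixed.inds = inds, mobile.inds = inds)
  }
  z <- sweep(x, 2L, model$mean) %*% model$modes[, seq_len(n_modes),
                                                drop = FALSE]
  colnames(z) <- paste0("PC", seq_len(n_modes))
  z
}

#' Catalytic/regulatory spine PCA
#'
#' PCA restricted to the atoms of the catalytic-spine residues (KIT
#' numbering A621, V603, L678, L798, L799, L800) and regulatory-spine
#' residues (L656, L644, F811, H790), the stacked hydrophobic columns whose
#' alignment signals the active kinase conformation.  Raw PC series are
#' produced; no aligned/broken call is made.
#'
#' @param ens An [ensemble()] containing the spine residues.
#' @param catalytic,regulatory Author residue numbers of the two spines.
#' @param elety Atom-name filter within those residues (`NULL` = all
#'   atoms).
#' @param ... Passed to [fit_pca()].
#' @return A `pca_model`.
#' @export
spine_pca <- function(ens,
                      catalytic = c(621L, 603L, 678L, 798L, 799L, 800L),
                      regulatory = c(656L, 644L, 811L, 790L),
                      elety = NULL, ...) {
  resno <- c(catalytic, regulatory)
  missing <- setdiff(resno, unique(ens$atoms$resno))
  if (length(missing))
    stop("spine residue(s) absent: ", paste(missing, collapse = ", "),
         call. = FALSE)
  fit_pca(ens, resno = resno, elety = elety, ...)
}

#' Serialize a PCA model to JSON
#'
#' @param model A `pca_model`.
#' @param path Output path.
#' @param n_modes Number of modes to persist (default: all).
#' @return `path`, invisibly.
#' @export
write_pca_json <- function(model, path, n_modes = length(model$variances)) {
  stopifnot(inherits(model, "pca_model"))
  k <- min(n_modes, ncol(model$modes))
  obj <- list(mean = model$mean,
              modes = unname(model$modes[, seq_len(k), drop = FALSE]),
              variances = model$variances[seq_len(k)],
              explained = model$explained[seq_len(k)],
              selection = model$selection,
              superpose = model$superpose)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
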