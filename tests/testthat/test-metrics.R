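test_that("dihedral angle follows the right-handed convention", {
  # planar eclipsed (cis) and anti (trans) arrangements
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 1, 0)), 0)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, -1, 0)), 180)
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                              c(1, 0, 1)), 90)
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("dihedral agrees with the independent bio3d formulation", {
  set.seed(41)
  for (i in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ])
    ref <- bio3d::torsion.xyz(as.vector(t(p)))
    expect_equal(mine, wrap_ref <- ((ref + 180) %% 360) - 180,
                 tolerance = 1e-8)
  }
})

test_that("dihedrals are invariant under rigid transforms", {
  set.seed(43)
  pe <- generate_peptide_frames(5, n_frames = 3, phi = -75, psi = 100)
  for (i in 1:10) {
    tr <- transform_ensemble(pe)
    expect_equal(residue_phi(tr, 3)$values, residue_phi(pe, 3)$values,
                 tolerance = 1e-8)
    expect_equal(residue_psi(tr, 3)$values, residue_psi(pe, 3)$values,
                 tolerance = 1e-8)
  }
})

test_that("phi/psi series round-trip and respect chain boundaries", {
  pe <- generate_peptide_frames(4, phi = -60, psi = 120)
  expect_equal(residue_phi(pe, 2)$values, -60, tolerance = 1e-6)
  expect_equal(residue_psi(pe, 3)$values, 120, tolerance = 1e-6)
  # conventional psi differs from the carbonyl psi by 180 degrees here
  conv <- residue_psi(pe, 2, convention = "next_n")$values
  expect_equal(((conv - (120 + 180)) + 180) %% 360 - 180, 0,
               tolerance = 1e-6)
  expect_error(residue_phi(pe, 1), "no Phi")
  expect_error(residue_phi(pe, 99), "not found|absent|needs residue")
})

test_that("a prescribed psi ramp yields a monotone measured series", {
  n <- 20
  psi_m <- matrix(120, n, 4)
  psi_m[, 2] <- seq(-150, 150, length.out = n)
  pe <- generate_peptide_frames(4, n_frames = n, phi = -60, psi = psi_m)
  vals <- residue_psi(pe, 2)$values
  expect_equal(vals, psi_m[, 2], tolerance = 1e-6)
  expect_true(all(diff(vals) > 0))
})

test_that("DFG and HDR descriptors address KIT-numbered residues", {
  pe <- generate_peptide_frames(6, n_frames = 2, phi = -65, psi = 140,
                                resno_start = 808L)
  d <- dfg_descriptor(pe)  # needs 809 (phi of 810), 810, 811
  expect_named(d, c("phi_asp", "psi_asp", "phi_phe", "psi_phe"))
  expect_equal(d$phi_asp$values, c(-65, -65), tolerance = 1e-6)
  expect_equal(d$psi_phe$values, c(140, 140), tolerance = 1e-6)
  h <- generate_peptide_frames(4, resno_start = 790L)
  expect_equal(length(hdr_descriptor(h)$values), 1)
  expect_error(dfg_descriptor(h), "not found|needs residue")
  expect_error(hdr_descriptor(pe), "not found|needs residue")
})

test_that("salt-bridge distance is the pair minimum, symmetric in labels", {
  sb <- salt_bridge_fixture(0.30, second_offset = 0.20)
  expect_equal(salt_bridge_distance(sb, 623, 640)$values, 0.30)
  # swapping the oxygen labels changes nothing
  sw <- sb
  sw$atoms$elety[sw$atoms$elety == "OE1"] <- "tmp"
  sw$atoms$elety[sw$atoms$elety == "OE2"] <- "OE1"
  sw$atoms$elety[sw$atoms$elety == "tmp"] <- "OE2"
  expect_equal(salt_bridge_distance(sw, 623, 640)$values, 0.30)
  # prescribed per-frame series recovered exactly; zero iff coincident
  ser <- c(0.28, 0.31, 0.55, 0)
  sbs <- salt_bridge_fixture(ser)
  expect_identical(salt_bridge_distance(sbs, 623, 640)$values, ser)
  expect_true(all(salt_bridge_distance(sbs, 623, 640)$values >= 0))
  # aspartate naming also supported; missing side chains are named
  sd_ <- salt_bridge_fixture(0.4, acidic = "ASP", acidic_resno = 810L)
  expect_equal(salt_bridge_distance(sd_, 623, 810)$values, 0.4)
  expect_error(salt_bridge_distance(sb, 640, 623), "NZ")
  expect_error(salt_bridge_distance(sb, 623, 999), "carboxylate")
})

test_that("PCA model satisfies its structural invariants", {
  set.seed(51)
  mu <- matrix(rnorm(36), 12)
  ens <- generate_gaussian_ensemble(mu, ortho_modes(12), c(3, 1),
                                    n_frames = 400, seed = 2)
  pm <- fit_pca(ens, elety = NULL, superpose = FALSE)
  expect_equal(sum(pm$explained), 1, tolerance = 1e-8)
  expect_true(all(diff(pm$variances) <= 1e-12))
  gram <- crossprod(pm$modes)
  expect_equal(gram, diag(ncol(pm$modes)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # degenerate input is flagged
  still <- generate_gaussian_ensemble(mu, ortho_modes(12), c(0, 0),
                                      n_frames = 5, seed = 1)
  expect_error(fit_pca(still, elety = NULL, superpose = FALSE),
               "zero covariance")
})

test_that("projection maps the mean to the origin and modes to axes", {
  set.seed(53)
  mu <- matrix(rnorm(30), 10)
  modes <- ortho_modes(10)
  ens <- generate_gaussian_ensemble(mu, modes, c(2, 0.5), n_frames = 500,
                                    seed = 3)
  pm <- fit_pca(ens, elety = NULL, superpose = FALSE)
  mean_ens <- ensemble(ens$atoms, matrix(pm$mean, 1))
  expect_equal(as.vector(project(pm, mean_ens)), c(0, 0), tolerance = 1e-9)
  # frame displaced along mode 1 projects to (c, 0)
  c1 <- 0.7
  fr <- ensemble(ens$atoms, matrix(pm$mean + c1 * pm$modes[, 1], 1))
  expect_equal(as.vector(project(pm, fr)), c(c1, 0), tolerance = 1e-9)
  # projecting the fitting ensemble reproduces the model variances
  z <- project(pm, ens, n_modes = 4)
  expect_equal(apply(z, 2, var), pm$variances[1:4], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA variances are invariant under rigid transforms", {
  pe <- generate_peptide_frames(8, n_frames = 60, phi = -60, psi = 120,
                                noise_sd = 8, seed = 9)
  pm <- fit_pca(pe)
  set.seed(61)
  tr <- transform_ensemble(pe)
  pm2 <- fit_pca(tr)
  expect_equal(pm2$variances[1:5], pm$variances[1:5], tolerance = 1e-6)
})

test_that("spine PCA uses the listed spine residues and reports absences", {
  spine <- c(621L, 603L, 678L, 798L, 799L, 800L, 656L, 644L, 811L, 790L)
  set.seed(63)
  atoms <- data.frame(elety = "CA", resid = "ALA", resno = spine,
                      chain = "A", eleno = seq_along(spine))
  ens <- generate_gaussian_ensemble(matrix(rnorm(30), 10),
                                    ortho_modes(10), c(2, 1),
                                    n_frames = 300, seed = 4, atoms = atoms)
  pm <- spine_pca(ens, superpose = FALSE)
  expect_equal(nrow(pm$selection), 10)
  expect_error(spine_pca(generate_peptide_frames(4)), "spine residue")
})

test_that("even subsampling hits the prescribed indices", {
  ens <- ensemble(data.frame(elety = "CA", resid = "ALA", resno = 1),
                  matrix(seq_len(30), 10, 3))
  expect_equal(subsample_evenly(ens, 10)$xyz, ens$xyz)
  e9 <- ensemble(ens$atoms, matrix(seq_len(27), 9, 3))
  expect_equal(subsample_evenly(e9, 3)$xyz[, 1], c(1, 5, 9))
  expect_equal(subsample_evenly(e9, 1)$xyz[, 1], 1)
  expect_error(subsample_evenly(e9, 10), "requested")
  expect_error(subsample_evenly(e9, 0), ">= 1")
})
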