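test_that("zero dissipation gives degenerate work distributions at +/- dG", {
  ws <- generate_cft_work_samples(5, 0, n_forward = 20, n_reverse = 20,
                                  seed = 1)
  expect_equal(ws$forward, rep(5, 20))
  expect_equal(ws$reverse, rep(-5, 20))
})

test_that("generated work samples match the stated Gaussian moments", {
  beta <- beta_from_temperature(310)
  sigma <- sqrt(2 * 2 / beta)
  ws <- generate_cft_work_samples(5, 2, 5000, 5000, temperature = 310,
                                  seed = 11)
  tol <- 3 * sigma / sqrt(5000)
  expect_lt(abs(mean(ws$forward) - 7), tol)
  expect_lt(abs(mean(ws$reverse) - (-3)), tol)
  # variance consistent with the fluctuation-dissipation relation
  expect_lt(abs(sd(ws$forward) - sigma) / sigma, 0.05)
  expect_lt(abs(sd(ws$reverse) - sigma) / sigma, 0.05)
})

test_that("the generating densities satisfy the Crooks identity exactly", {
  dg <- 3.2; diss <- 1.7; temp <- 310
  beta <- beta_from_temperature(temp)
  sigma <- sqrt(2 * diss / beta)
  w <- seq(-10, 15, length.out = 101)
  lhs <- dnorm(w, dg + diss, sigma, log = TRUE) -
    dnorm(-w, -dg + diss, sigma, log = TRUE)
  expect_equal(lhs, beta * (w - dg), tolerance = 1e-12)
})

test_that("work generation is reproducible from the seed", {
  a <- generate_cft_work_samples(5, 2, 100, 120, seed = 42)
  b <- generate_cft_work_samples(5, 2, 100, 120, seed = 42)
  expect_identical(a$forward, b$forward)
  expect_identical(a$reverse, b$reverse)
  c <- generate_cft_work_samples(5, 2, 100, 120, seed = 43)
  expect_false(identical(a$forward, c$forward))
})

test_that("work generator rejects invalid specifications", {
  expect_error(generate_cft_work_samples(5, -1), "dissipation")
  expect_error(generate_cft_work_samples(5, 1, n_forward = 0), "transition")
  expect_error(generate_cft_work_samples(5, 1, temperature = 0),
               "temperature")
  expect_error(generate_cft_work_samples(5, 1, temperature = -300),
               "temperature")
})

test_that("peptide frames reproduce prescribed dihedrals exactly", {
  pe <- generate_peptide_frames(3, n_frames = 1, phi = -60, psi = 180)
  expect_equal(residue_psi(pe, 2)$values, 180, tolerance = 1e-6)
  expect_equal(residue_phi(pe, 2)$values, -60, tolerance = 1e-6)

  # property: build-then-measure round-trips for random targets
  set.seed(7)
  for (i in 1:100) {
    phi <- runif(1, -179.9, 180)
    psi <- runif(1, -179.9, 180)
    pe <- generate_peptide_frames(3, phi = phi, psi = psi)
    expect_lt(abs(residue_phi(pe, 2)$values - phi), 1e-6)
    expect_lt(abs(residue_psi(pe, 2)$values - psi), 1e-6)
  }
})

test_that("dihedral noise perturbs targets at the requested scale", {
  pe <- generate_peptide_frames(3, n_frames = 400, phi = -60, psi = 120,
                                noise_sd = 5, seed = 3)
  err <- residue_phi(pe, 2)$values - (-60)
  expect_lt(abs(mean(err)), 1)          # unbiased
  expect_lt(abs(sd(err) - 5) / 5, 0.2)  # spread ~ noise_sd
  # reproducible from the seed
  pe2 <- generate_peptide_frames(3, n_frames = 400, phi = -60, psi = 120,
                                 noise_sd = 5, seed = 3)
  expect_identical(pe$xyz, pe2$xyz)
})

test_that("peptide generator rejects degenerate requests", {
  expect_error(generate_peptide_frames(1), ">= 2 residues")
  expect_error(generate_peptide_frames(3, n_frames = 0), "n_frames")
  expect_error(generate_peptide_frames(3, phi = 200), "\\(-180, 180\\]")
  expect_error(generate_peptide_frames(3, psi = -180), "\\(-180, 180\\]")
})

test_that("gaussian ensemble with zero variances repeats the mean", {
  mu <- matrix(rnorm(12), 4)
  ens <- generate_gaussian_ensemble(mu, ortho_modes(4), c(0, 0),
                                    n_frames = 5, seed = 1)
  for (f in 1:5)
    expect_equal(ens$xyz[f, ], as.vector(t(mu)))
})

test_that("gaussian ensemble realizes the planted covariance structure", {
  set.seed(21)
  mu <- matrix(rnorm(60), 20)
  modes <- ortho_modes(20)
  # single mode: PC1 takes essentially all variance
  e1 <- generate_gaussian_ensemble(mu, modes[, 1, drop = FALSE], 2.0,
                                   n_frames = 2000, seed = 5)
  p1 <- fit_pca(e1, elety = NULL, superpose = FALSE)
  expect_gte(p1$explained[1], 0.99)
  # two modes at 4:1 variance: recovered ratio within sampling error
  e2 <- generate_gaussian_ensemble(mu, modes, c(4, 1), n_frames = 5000,
                                   seed = 6)
  p2 <- fit_pca(e2, elety = NULL, superpose = FALSE)
  expect_equal(p2$variances[1] / p2$variances[2], 4, tolerance = 0.15)
  # reproducibility
  e2b <- generate_gaussian_ensemble(mu, modes, c(4, 1), n_frames = 5000,
                                    seed = 6)
  expect_identical(e2$xyz, e2b$xyz)
})

test_that("gaussian ensemble validates its specification", {
  mu <- matrix(0, 4, 3)
  bad <- cbind(rnorm(12), rnorm(12))
  bad[, 2] <- bad[, 1] + 1e-3 * bad[, 2]  # nearly parallel
  expect_error(generate_gaussian_ensemble(mu, bad, c(1, 1)),
               "orthogonal")
  expect_error(generate_gaussian_ensemble(mu, ortho_modes(4), c(1, -1)),
               "variances")
})

test_that("work tables round-trip through the TSV dialect", {
  ws <- list(generate_cft_work_samples(5, 2, 30, 40, seed = 1,
                                       transformation_id = "m1"),
             generate_cft_work_samples(-3, 1, 25, 25, seed = 2,
                                       transformation_id = "m2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_work_tsv(ws, path)
  back <- read_work_tsv(path, temperature = 310)
  expect_named(back, c("m1", "m2"))
  expect_equal(back$m1$forward, ws[[1]]$forward)
  expect_equal(back$m2$reverse, ws[[2]]$reverse)
})

test_that("ensembles round-trip through multi-model PDB", {
  pe <- generate_peptide_frames(4, n_frames = 3, phi = -60, psi = 120,
                                resno_start = 808)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(pe, path)
  back <- read_ensemble_pdb(path)
  expect_equal(n_frames(back), 3)
  expect_equal(back$atoms$elety, pe$atoms$elety)
  expect_equal(back$atoms$resno, pe$atoms$resno)
  # PDB stores 3 decimals in angstrom = 1e-4 nm resolution
  expect_equal(back$xyz, pe$xyz, tolerance = 1e-3)
})
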