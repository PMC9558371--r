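# Independent oracles used by the unit and acceptance tests.  These are
# written against the defining equations directly (different formulation and
# different solver than the package) so they can vouch for the
# implementation rather than mirror it.

# BAR maximum-likelihood dG via the literal count-ratio form of the
# self-consistency equation, solved with stats::uniroot.
oracle_bar_dg <- function(fw, rv, temperature = 310) {
  beta <- 1 / (0.008314463 * temperature)
  nf <- length(fw); nr <- length(rv)
  obj <- function(dg) {
    sum(1 / (1 + (nf / nr) * exp(beta * (fw - dg)))) -
      sum(1 / (1 + (nr / nf) * exp(beta * (rv + dg))))
  }
  rng <- range(c(fw, -rv))
  stats::uniroot(obj, lower = rng[1] - 10, upper = rng[2] + 10,
                 tol = 1e-12)$root
}

# crossing point of the two moment-fitted normal densities, located by
# dense numeric evaluation + uniroot between the means
oracle_crossing_dg <- function(fw, neg_rv) {
  m1 <- mean(fw); s1 <- sd(fw)
  m2 <- mean(neg_rv); s2 <- sd(neg_rv)
  dif <- function(x) dnorm(x, m1, s1) - dnorm(x, m2, s2)
  stats::uniroot(dif, lower = min(m1, m2), upper = max(m1, m2),
                 tol = 1e-12)$root
}

# closed-form overlap coefficient of two equal-variance normals
oracle_gaussian_overlap_equal_sd <- function(mu1, mu2, sigma) {
  2 * pnorm(-abs(mu1 - mu2) / (2 * sigma))
}

# uniform random rotation matrix (QR of a normal matrix, det fixed to +1)
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# apply a rigid transform (rotation + translation) to every frame
transform_ensemble <- function(ens, rot = rand_rotation(),
                               trans = rnorm(3)) {
  xyz <- t(apply(ens$xyz, 1, function(fr) {
    m <- matrix(fr, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% rot, 2, trans, "+")))
  }))
  ensemble(ens$atoms, xyz)
}

# two orthogonal random displacement modes for an N-atom toy system
ortho_modes <- function(n_atoms) {
  m1 <- rnorm(3 * n_atoms)
  m2 <- rnorm(3 * n_atoms)
  m2 <- m2 - sum(m2 * m1) / sum(m1^2) * m1
  cbind(m1, m2)
}
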