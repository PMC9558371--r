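#' @rdname bar_estimate
#' @export
free_energy_estimate <- function(dg, uncertainty = NA_real_, method = "BAR",
                                 n_bootstrap = 0L, n_f = NA_integer_,
                                 n_r = NA_integer_, transformation_id = "") {
  if (!is.na(uncertainty) && uncertainty < 0)
    stop("uncertainty must be >= 0", call. = FALSE)
  structure(
    list(dg = as.numeric(dg), uncertainty = as.numeric(uncertainty),
         method = match.arg(method, c("BAR", "crooks_crossing")),
         n_bootstrap = as.integer(n_bootstrap),
         n_f = as.integer(n_f), n_r = as.integer(n_r),
         transformation_id = as.character(transformation_id)[1L]),
    class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("dG = %.4f %s kJ/mol  [%s%s]%s\n", x$dg,
              if (is.na(x$uncertainty)) "" else sprintf("+/- %.4f", x$uncertainty),
              x$method,
              if (x$n_bootstrap > 0) sprintf(", %d bootstrap", x$n_bootstrap) else "",
              if (nzchar(x$transformation_id)) paste0("  ", x$transformation_id) else ""))
  invisible(x)
}

# BAR self-consistency objective.  With M = (1/beta) ln(n_f/n_r), the
# maximum-likelihood dG is the root of
#   sum_i 1/(1 + exp(beta (M + W_f,i - dG)))
#     - sum_j 1/(1 + exp(beta (-M + W_r,j + dG))) = 0,
# which is monotone increasing in dG.  1/(1+exp(x)) = plogis(-x).
bar_objective <- function(dg, forward, reverse, beta, log_nf_nr) {
  sum(stats::plogis(-(log_nf_nr + beta * (forward - dg)))) -
    sum(stats::plogis(-(-log_nf_nr + beta * (reverse + dg))))
}

#' Bennett acceptance ratio (BAR) free-energy estimate
#'
#' Solves the BAR maximum-likelihood self-consistency equation for the
#' free-energy difference \eqn{\Delta G} of an alchemical transformation from
#' its forward and reverse work samples.  With \eqn{n_f} forward and
#' \eqn{n_r} reverse transitions and \eqn{M = \beta^{-1}\ln(n_f/n_r)},
#' \eqn{\Delta G} is the root of
#' \deqn{\sum_i \frac{1}{1 + e^{\beta(M + W_{f,i} - \Delta G)}}
#'     = \sum_j \frac{1}{1 + e^{\beta(W_{r,j} + \Delta G - M)}}.}
#' When forward and reverse counts are equal, \eqn{M = 0}.  The objective is
#' monotone in \eqn{\Delta G}, so the root is found by bisection on the
#' interval spanned by the pooled work values (forward and negated reverse)
#' expanded by 10 kJ/mol, to an objective tolerance of 1e-10.
#'
#' @param ws A [work_set()].
#' @return A `fe_estimate` with `method = "BAR"` and no uncertainty attached
#'   (see [bootstrap_uncertainty()] or [estimate_work_set()]).
#' @references Bennett, C. H. (1976) J. Comput. Phys. 22, 245-268.
#'   Shirts, M. R. et al. (2003) Phys. Rev. Lett. 91, 140601.
#' @export
bar_estimate <- function(ws) {
  stopifnot(inherits(ws, "work_set"))
  fw <- ws$forward; rv <- ws$reverse
  beta <- ws$beta
  log_nf_nr <- log(length(fw) / length(rv))
  pooled <- c(fw, -rv)
  lo <- min(pooled) - 10
  hi <- max(pooled) + 10
  flo <- bar_objective(lo, fw, rv, beta, log_nf_nr)
  fhi <- bar_objective(hi, fw, rv, beta, log_nf_nr)
  if (flo > 0 || fhi < 0) {
    ov <- overlap_diagnostic(ws)
    stop(sprintf(paste0("BAR objective has no sign change in [%.3f, %.3f]; ",
                        "forward/reverse work distributions do not overlap ",
                        "(overlap coefficient %.3f)"), lo, hi, ov),
         call. = FALSE)
  }
  # bisection: deterministic and robust; the objective is monotone
  for (i in seq_len(200L)) {
    mid <- 0.5 * (lo + hi)
    fmid <- bar_objective(mid, fw, rv, beta, log_nf_nr)
    if (abs(fmid) < 1e-10 || (hi - lo) < 1e-13 * max(1, abs(mid))) break
    if (fmid < 0) lo <- mid else hi <- mid
  }
  free_energy_estimate(mid, method = "BAR", n_f = length(fw),
                       n_r = length(rv),
                       transformation_id = ws$transformation_id)
}

#' Crooks crossing free-energy estimate
#'
#' The Crooks fluctuation theorem implies that the forward work density
#' \eqn{P_f(W)} and the negated-reverse density \eqn{P_r(-W)} cross at
#' \eqn{W = \Delta G}.  This estimator fits a normal density to each sample
#' (moment fits: mean and standard deviation) and returns the crossing point
#' of the two fitted densities that lies between their means.  For equal
#' fitted variances the crossing is the midpoint of the two means.
#'
#' @param ws A [work_set()] with at least two samples per direction.
#' @return A `fe_estimate` with `method = "crooks_crossing"`.
#' @export
crooks_crossing_estimate <- function(ws) {
  stopifnot(inherits(ws, "work_set"))
  fw <- ws$forward
  nrv <- -ws$reverse
  if (length(fw) < 2L || length(nrv) < 2L)
    stop("crooks_crossing_estimate needs >= 2 samples per direction ",
         "to fit a variance", call. = FALSE)
  m1 <- mean(fw);  s1 <- stats::sd(fw)
  m2 <- mean(nrv); s2 <- stats::sd(nrv)
  if (s1 == 0 || s2 == 0)
    stop("zero variance in fitted work distribution; crossing undefined",
         call. = FALSE)
  a <- 1 / s1^2 - 1 / s2^2
  if (abs(a) < 1e-12 * max(1 / s1^2, 1 / s2^2)) {
    dg <- 0.5 * (m1 + m2)
  } else {
    # equate log-densities: quadratic a x^2 - 2 b x + c = 0
    b <- m1 / s1^2 - m2 / s2^2
    cc <- m1^2 / s1^2 - m2^2 / s2^2 - 2 * log(s2 / s1)
    disc <- b^2 - a * cc
    if (disc < 0)
      stop("fitted densities have no real crossing", call. = FALSE)
    roots <- (b + c(-1, 1) * sqrt(disc)) / a
    lo <- min(m1, m2); hi <- max(m1, m2)
    tol <- 1e-9 * max(1, abs(lo), abs(hi))
    inside <- roots >= lo - tol & roots <= hi + tol
    if (!any(inside))
      stop("no density crossing between the fitted means ",
           sprintf("(means %.4f and %.4f, roots %.4f and %.4f)",
                   m1, m2, roots[1], roots[2]), call. = FALSE)
    dg <- roots[inside][1L]
  }
  free_energy_estimate(dg, method = "crooks_crossing", n_f = length(fw),
                       n_r = length(nrv),
                       transformation_id = ws$transformation_id)
}

#' Bootstrap standard error of a free-energy estimate
#'
#' Resamples the forward and reverse work lists independently, with
#' replacement at their original sizes, re-estimates \eqn{\Delta G} for each
#' replicate and returns the standard deviation of the replicate estimates.
#' The default of 100 replicates matches the common practice of solving the
#' estimating equation 100 times on resampled data sets.
#'
#' @param ws A [work_set()].
#' @param estimator `"BAR"` or `"crooks_crossing"`.
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Standard error in kJ/mol.
#' @export
bootstrap_uncertainty <- function(ws, estimator = c("BAR", "crooks_crossing"),
                                  n_boot = 100L, seed = NULL) {
  stopifnot(inherits(ws, "work_set"))
  estimator <- match.arg(estimator)
  n_boot <- as.integer(n_boot)
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  est_fun <- switch(estimator, BAR = bar_estimate,
                    crooks_crossing = crooks_crossing_estimate)
  nf <- length(ws$forward); nr <- length(ws$reverse)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bws <- work_set(ws$forward[sample.int(nf, nf, replace = TRUE)],
                      ws$reverse[sample.int(nr, nr, replace = TRUE)],
                      temperature = ws$temperature,
                      transformation_id = ws$transformation_id)
      tryCatch(est_fun(bws)$dg, error = function(e) NA_real_)
    }, numeric(1))
  })
  n_fail <- sum(is.na(reps))
  if (n_fail > n_boot / 2)
    stop(sprintf("estimator failed on %d of %d bootstrap replicates",
                 n_fail, n_boot), call. = FALSE)
  stats::sd(reps[!is.na(reps)])
}

#' Estimate dG with bootstrap uncertainty in one call
#'
#' Convenience wrapper combining [bar_estimate()] or
#' [crooks_crossing_estimate()] with [bootstrap_uncertainty()].
#'
#' @inheritParams bootstrap_uncertainty
#' @return A `fe_estimate` with the bootstrap standard error attached.
#' @export
estimate_work_set <- function(ws, estimator = c("BAR", "crooks_crossing"),
                              n_boot = 100L, seed = NULL) {
  estimator <- match.arg(estimator)
  est <- switch(estimator, BAR = bar_estimate(ws),
                crooks_crossing = crooks_crossing_estimate(ws))
  est$uncertainty <- bootstrap_uncertainty(ws, estimator, n_boot, seed)
  est$n_bootstrap <- as.integer(n_boot)
  est
}

#' Forward/reverse work-distribution overlap coefficient
#'
#' Histogram overlap between the forward work sample and the negated reverse
#' work sample on a shared binning: 1 for identical distributions, 0 for
#' disjoint ones.  BAR is only reliable when the two distributions overlap,
#' so this value is attached to estimator output as a diagnostic.
#'
#' @param ws A [work_set()].
#' @param n_bins Number of shared bins; the default scales with sample size.
#' @return Overlap coefficient in \[0, 1\].
#' @export
overlap_diagnostic <- function(ws, n_bins = NULL) {
  stopifnot(inherits(ws, "work_set"))
  a <- ws$forward
  b <- -ws$reverse
  rng <- range(c(a, b))
  if (diff(rng) == 0) {
    # all values coincide: point masses at the same location
    return(1.0)
  }
  if (is.null(n_bins))
    n_bins <- max(10L, ceiling(sqrt(min(length(a), length(b)))))
  # widen slightly so extreme values fall inside the outer bins
  eps <- 1e-9 * diff(rng)
  breaks <- seq(rng[1] - eps, rng[2] + eps, length.out = n_bins + 1L)
  pa <- tabulate(findInterval(a, breaks, all.inside = TRUE), n_bins) / length(a)
  pb <- tabulate(findInterval(b, breaks, all.inside = TRUE), n_bins) / length(b)
  sum(pmin(pa, pb))
}
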