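#' A free-energy difference with a standard error
#'
#' Lightweight value type for \eqn{\Delta\Delta G} arithmetic: a value in
#' kJ/mol plus a standard error propagated in quadrature.
#'
#' @param value Energy in kJ/mol.
#' @param se Standard error in kJ/mol, >= 0.
#' @return An object of class `ddg`.
#' @export
ddg <- function(value, se = 0) {
  value <- as.numeric(value); se <- as.numeric(se)
  stopifnot(length(value) == 1L, length(se) == 1L)
  if (is.na(se)) se <- NA_real_ else if (se < 0)
    stop("standard error must be >= 0", call. = FALSE)
  structure(list(value = value, se = se), class = "ddg")
}

#' @export
print.ddg <- function(x, ...) {
  cat(sprintf("%.4g +/- %.2g kJ/mol\n", x$value, x$se))
  invisible(x)
}

#' Combine independent standard errors in quadrature
#'
#' @param ses Numeric vector of standard errors, all >= 0.
#' @return sqrt(sum(ses^2)).
#' @export
propagate_quadrature <- function(ses) {
  ses <- as.numeric(ses)
  if (any(!is.na(ses) & ses < 0))
    stop("standard errors must be >= 0", call. = FALSE)
  sqrt(sum(ses^2))
}

#' One leg of the mutation thermodynamic cycle
#'
#' A leg is an alchemical wild-type-to-mutant transformation carried out in
#' one environment: the unfolded reference peptide, the folded inactive
#' (autoinhibited) kinase, or the folded active kinase.  The physical folding
#' and activation legs of the cycle are never computed directly; they are
#' obtained by cycle closure from these three alchemical legs.
#'
#' @param mutation Mutation label, e.g. `"D816V"`.
#' @param leg One of `"unfolded"`, `"folded_inactive"`, `"folded_active"`.
#' @param dg Leg free-energy difference in kJ/mol, or a `fe_estimate`.
#' @param se Standard error, kJ/mol (ignored when `dg` is a `fe_estimate`).
#' @return An object of class `leg_result`.
#' @export
leg_result <- function(mutation, leg, dg, se = 0) {
  leg <- match.arg(leg, c("unfolded", "folded_inactive", "folded_active"))
  if (inherits(dg, "fe_estimate")) {
    se <- if (is.na(dg$uncertainty)) 0 else dg$uncertainty
    dg <- dg$dg
  }
  structure(list(mutation = as.character(mutation)[1L], leg = leg,
                 dg = as.numeric(dg), se = as.numeric(se)),
            class = "leg_result")
}

#' Per-state relative stability of a mutant from two cycle legs
#'
#' Closes the folding thermodynamic cycle: the difference between folding
#' the wild type and folding the mutant equals the difference between the
#' alchemical WT-to-mutant transformations in the unfolded and folded
#' states,
#' \deqn{\Delta\Delta G_{state} = \Delta G_{unfolded} - \Delta G_{folded},}
#' so \eqn{\Delta\Delta G_{state} < 0} means the mutant is thermodynamically
#' less stable than the wild type in that state.  Standard errors combine in
#' quadrature (the legs are independent simulations).
#'
#' @param unfolded A [leg_result()] with `leg = "unfolded"`.
#' @param folded A [leg_result()] with `leg = "folded_inactive"` or
#'   `"folded_active"`.
#' @return A [ddg()].
#' @export
state_ddg <- function(unfolded, folded) {
  stopifnot(inherits(unfolded, "leg_result"), inherits(folded, "leg_result"))
  if (unfolded$mutation != folded$mutation)
    stop("legs belong to different mutations: ", unfolded$mutation, " vs ",
         folded$mutation, call. = FALSE)
  if (unfolded$leg != "unfolded")
    stop("first argument must be the unfolded leg, got '", unfolded$leg, "'",
         call. = FALSE)
  if (!folded$leg %in% c("folded_inactive", "folded_active"))
    stop("second argument must be a folded leg, got '", folded$leg, "'",
         call. = FALSE)
  ddg(unfolded$dg - folded$dg, propagate_quadrature(c(unfolded$se, folded$se)))
}

#' Activation ddG from the two per-state ddG values
#'
#' Closes the activation thermodynamic cycle: comparing the inactive-to-
#' active transition free energy of mutant and wild type is equivalent to
#' comparing the alchemical legs in the two folded states,
#' \deqn{\Delta\Delta G_{activation} = \Delta\Delta G_{active} -
#'   \Delta\Delta G_{inactive},}
#' (the unfolded leg cancels).  A positive value means activation is more
#' favourable for the mutant than for the wild type.
#'
#' @param ddg_inactive,ddg_active [ddg()] values (or plain numerics, taken
#'   with zero standard error).
#' @return A [ddg()].
#' @export
activation_ddg <- function(ddg_inactive, ddg_active) {
  if (is.numeric(ddg_inactive)) ddg_inactive <- ddg(ddg_inactive)
  if (is.numeric(ddg_active)) ddg_active <- ddg(ddg_active)
  if (is.null(ddg_inactive) || is.null(ddg_active))
    stop("both per-state ddG values are required for the activation ddG",
         call. = FALSE)
  stopifnot(inherits(ddg_inactive, "ddg"), inherits(ddg_active, "ddg"))
  ddg(ddg_active$value - ddg_inactive$value,
      propagate_quadrature(c(ddg_inactive$se, ddg_active$se)))
}

#' Assembled thermodynamic-cycle result for one mutation
#'
#' Holds the per-state \eqn{\Delta\Delta G} values of a mutation and, when
#' both states are available, the activation \eqn{\Delta\Delta G} computed
#' by cycle closure.  The active-state value may be absent: for
#' juxtamembrane-domain mutants the active structure lacks the JM domain and
#' no active-state leg exists.
#'
#' @param mutation Mutation label.
#' @param ddg_inactive [ddg()] for the inactive (autoinhibited) state.
#' @param ddg_active Optional [ddg()] for the active state, or `NULL`.
#' @return An object of class `mutation_cycle` with fields `mutation`,
#'   `ddg_inactive`, `ddg_active` (possibly `NULL`) and `ddg_activation`
#'   (possibly `NULL`).
#' @export
mutation_cycle <- function(mutation, ddg_inactive, ddg_active = NULL) {
  if (is.numeric(ddg_inactive)) ddg_inactive <- ddg(ddg_inactive)
  if (is.numeric(ddg_active)) ddg_active <- ddg(ddg_active)
  stopifnot(inherits(ddg_inactive, "ddg"))
  act <- NULL
  if (!is.null(ddg_active)) {
    stopifnot(inherits(ddg_active, "ddg"))
    act <- activation_ddg(ddg_inactive, ddg_active)
  }
  structure(list(mutation = as.character(mutation)[1L],
                 ddg_inactive = ddg_inactive, ddg_active = ddg_active,
                 ddg_activation = act),
            class = "mutation_cycle")
}

#' @export
print.mutation_cycle <- function(x, ...) {
  fmt <- function(d) if (is.null(d)) "     --      " else
    sprintf("%6.1f +/- %.1f", d$value, d$se)
  cat(sprintf("%s: ddG_inactive %s | ddG_active %s | ddG_activation %s kJ/mol\n",
              x$mutation, fmt(x$ddg_inactive), fmt(x$ddg_active),
              fmt(x$ddg_activation)))
  invisible(x)
}

#' Classify a mutation as activating or deactivating
#'
#' Applies the two-dimensional stability rule: oncogenic (activating)
#' mutations destabilize the inactive autoinhibited state and/or
#' overstabilize the active state, while loss-of-function (deactivating,
#' piebald-type) mutations destabilize the active state.  With threshold
#' \eqn{\tau} (default 4 kJ/mol, on the order of the error typically seen in
#' computational free-energy estimates), the rule is applied in order:
#' \enumerate{
#'   \item `ddg_active < -tau` : deactivating;
#'   \item else `ddg_active > tau` or `ddg_inactive < -tau` : activating;
#'   \item else neutral.
#' }
#' The label becomes `indeterminate` when the value that decided the call is
#' smaller in magnitude than its own standard error.
#'
#' For mutations without an active-state leg (JM-domain mutants, whose JM
#' segment is presumed unstructured in the active state), the active-state
#' \eqn{\Delta\Delta G} is taken as 0 when `assume_active_zero = TRUE`.
#'
#' @param cycle A [mutation_cycle()].
#' @param threshold \eqn{\tau} in kJ/mol, > 0.
#' @param assume_active_zero Substitute `ddg(0, 0)` for a missing
#'   active-state value (default `TRUE`).
#' @return An object of class `classification` with fields `mutation`,
#'   `label` (`activating`, `deactivating`, `neutral` or `indeterminate`),
#'   `rationale` and `threshold`.
#' @export
classify_mutation <- function(cycle, threshold = 4.0,
                              assume_active_zero = TRUE) {
  stopifnot(inherits(cycle, "mutation_cycle"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive energy in kJ/mol", call. = FALSE)
  inact <- cycle$ddg_inactive
  if (is.null(inact)) stop("inactive-state ddG is required", call. = FALSE)
  act <- cycle$ddg_active
  if (is.null(act)) {
    if (!assume_active_zero)
      stop("active-state ddG missing for ", cycle$mutation,
           " and assume_active_zero = FALSE", call. = FALSE)
    act <- ddg(0, 0)
  }
  decide <- function(label, deciding, why) {
    if (abs(deciding$value) < deciding$se)
      list(label = "indeterminate",
           rationale = paste0(why, ", but |value| < SE"))
    else list(label = label, rationale = why)
  }
  res <- if (act$value < -threshold) {
    decide("deactivating", act,
           sprintf("ddG_active = %.1f < -%.1f destabilizes the active state",
                   act$value, threshold))
  } else if (inact$value < -threshold) {
    decide("activating", inact,
           sprintf("ddG_inactive = %.1f < -%.1f destabilizes the inactive state",
                   inact$value, threshold))
  } else if (act$value > threshold) {
    decide("activating", act,
           sprintf("ddG_active = %.1f > %.1f overstabilizes the active state",
                   act$value, threshold))
  } else {
    list(label = "neutral",
         rationale = sprintf("|ddG| <= %.1f kJ/mol in both states", threshold))
  }
  structure(list(mutation = cycle$mutation, label = res$label,
                 rationale = res$rationale, threshold = threshold),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("%s: %s (%s; tau = %g kJ/mol)\n", x$mutation, x$label,
              x$rationale, x$threshold))
  invisible(x)
}

#' Printed per-state ddG values for five KIT mutations
#'
#' The bundled reference table of per-state \eqn{\Delta\Delta G} values
#' (kJ/mol) for the KIT kinase mutations V559A, V560D, D816V (oncogenic) and
#' G812V, V620A (piebald), as used in the worked examples.  Provenance is
#' recorded per row in the `source` column:
#' \describe{
#'   \item{`printed`}{value printed in the source study's text.}
#'   \item{`reconstructed`}{D816V's inactive-state value, recovered as minus
#'     the wild-type-referenced activation baseline (19.8 +/- 0.5 kJ/mol).}
#'   \item{`synthetic_qualitative`}{JM-domain inactive-state values reported
#'     only as clearly destabilizing (negative, beyond the 4 kJ/mol
#'     threshold) without a printed number; the numeric stand-ins here are
#'     synthetic and carry only that qualitative content.}
#' }
#' G812V's inactive-state standard error is reported inconsistently at two
#' places in the source (0.5 and 0.4); both rows are kept, the second
#' flagged with `variant = TRUE` and excluded from analysis by default.
#'
#' @param include_variants Keep rows flagged `variant = TRUE` (default
#'   `FALSE`).
#' @return A data.frame with columns `mutation`, `state`
#'   (`inactive`|`active`), `ddg_kJ_per_mol`, `se_kJ_per_mol`, `source`,
#'   `variant`, `note`.
#' @export
kit_printed_ddg <- function(include_variants = FALSE) {
  path <- system.file("extdata", "kit_printed_ddg.tsv", package = "kitddg",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tab$variant <- as.logical(tab$variant)
  if (!include_variants) tab <- tab[!tab$variant, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Build mutation cycles from a per-state ddG table
#'
#' @param tab Data frame with columns `mutation`, `state`
#'   (`inactive`|`active`), `ddg_kJ_per_mol`, `se_kJ_per_mol` (a direct
#'   ddG table such as [kit_printed_ddg()]).
#' @return Named list of [mutation_cycle()] objects.
#' @export
cycles_from_ddg_table <- function(tab) {
  need <- c("mutation", "state", "ddg_kJ_per_mol", "se_kJ_per_mol")
  if (!all(need %in% names(tab)))
    stop("ddG table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(tab) == 0L) stop("ddG table is empty", call. = FALSE)
  bad <- !tab$state %in% c("inactive", "active")
  if (any(bad))
    stop("unknown state label(s): ", paste(unique(tab$state[bad]),
                                           collapse = ", "), call. = FALSE)
  muts <- unique(tab$mutation)
  out <- lapply(muts, function(m) {
    rows <- tab[tab$mutation == m, , drop = FALSE]
    pick <- function(st) {
      r <- rows[rows$state == st, , drop = FALSE]
      if (nrow(r) == 0L) return(NULL)
      if (nrow(r) > 1L)
        stop("multiple '", st, "' rows for mutation ", m,
             "; resolve variants first", call. = FALSE)
      ddg(r$ddg_kJ_per_mol, r$se_kJ_per_mol)
    }
    inact <- pick("inactive")
    if (is.null(inact))
      stop("mutation ", m, " has no inactive-state row", call. = FALSE)
    mutation_cycle(m, inact, pick("active"))
  })
  stats::setNames(out, muts)
}
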