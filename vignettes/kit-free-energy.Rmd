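---
title: "Free-energy inference of KIT mutation effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy inference of KIT mutation effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kitddg)
```

## The problem

KIT is a type 3 receptor tyrosine kinase whose kinase domain switches
between an inactive, autoinhibited conformation (juxtamembrane domain
blocking the active site, DFG motif "out") and an active conformation.
Point mutations bias this equilibrium: oncogenic mutations favour the
active state, piebaldism mutations the inactive one. A mutation's effect
can be quantified thermodynamically by how it changes the relative
stability of each conformational state, and those relative stabilities are
computable from *alchemical* free-energy calculations, in which a
nonphysical coupling parameter morphs the wild-type side chain into the
mutant one along fast nonequilibrium transitions.

`kitddg` implements everything downstream of the molecular dynamics: the
estimators that turn work samples into free-energy differences, the cycle
algebra that turns leg-level free energies into per-state and activation
ΔΔG values with propagated uncertainty, the classification rule, and the
structural metrics used as supporting evidence. Synthetic-data generators
stand in for the MD.

## Free-energy estimation from nonequilibrium work

Each alchemical transformation yields forward work samples $W_{f,i}$
($n_f$ transitions, WT→mutant) and reverse samples $W_{r,j}$ ($n_r$,
mutant→WT), at temperature $T$ with $\beta = 1/(k_B T)$,
$k_B = 0.008314463$ kJ/(mol·K). The Crooks fluctuation theorem,
$P_f(W)/P_r(-W) = e^{\beta(W - \Delta G)}$, links the two distributions to
the equilibrium free-energy difference $\Delta G$.

**BAR.** The primary estimator is the Bennett acceptance ratio in its
maximum-likelihood form: $\Delta G$ solves

$$\sum_{i=1}^{n_f} \frac{1}{1 + e^{\beta(M + W_{f,i} - \Delta G)}}
 = \sum_{j=1}^{n_r} \frac{1}{1 + e^{\beta(W_{r,j} + \Delta G - M)}},
 \qquad M = \beta^{-1}\ln(n_f/n_r).$$

The offset $M$ vanishes for equal counts, the usual design, but is kept so
unequal campaigns are handled correctly. The left side minus the right
side is monotone increasing in $\Delta G$, so we bracket the root by the
pooled work range ($W_f$ and $-W_r$) expanded by 10 kJ/mol and bisect —
deterministic and robust in preference to faster Newton-type iterations —
to an objective tolerance of $10^{-10}$. Because the objective runs from
$-n_r$ to $+n_f$, a finite sample always has a root; the bracketing
failure branch is retained defensively and reports the overlap diagnostic.

**Crooks crossing.** As a cross-check, $P_f(W)$ and $P_r(-W)$ cross
exactly at $W = \Delta G$. We fit each sample with a normal density by
moments (mean and SD — the simplest faithful reading of fitting a work
distribution; no maximum-likelihood density estimation) and return the
crossing between the two means, from the closed-form quadratic. Equal
fitted variances degenerate to the midpoint of the means; the quadratic
branch is taken only when the leading coefficient is numerically
non-negligible (relative threshold $10^{-12}$), since it is ill-conditioned
near equal variances. Zero variance or no crossing between the means is an
error, not a silent answer.

**Bootstrap uncertainty.** Standard errors come from resampling the
forward and reverse lists *independently* with replacement at their
original sizes and re-solving, 100 times by default. Independent
resampling is the natural choice because the two directions are separate
simulation campaigns with no pairing. The reported uncertainty is the SD
of the replicate estimates, interpreted as 1 standard error throughout
(the cycle arithmetic treats all ± values as 1 SD).

**Overlap diagnostic.** BAR degrades when the forward and negated-reverse
distributions stop overlapping. A histogram overlap coefficient
($\sum_b \min(p_b, q_b)$ on a shared binning, $\max(10,\sqrt{n})$ bins) is
attached to every estimate; values near 0 mean the ΔG should not be
trusted regardless of its formal error bar.

## Thermodynamic cycles and classification

Three alchemical legs exist per mutation: unfolded reference peptide
(GXG tripeptide in the source data), folded inactive, folded active.
Cycle closure gives

$$\Delta\Delta G_{state} = \Delta G_{unfolded} - \Delta G_{folded},$$

with the sign convention fixed so that negative values mean the mutant is
*less* stable than WT in that state. This orientation — rather than its
mirror — is forced by two facts in the source data: the stated reading
"ΔΔG_inactive < 0 ⇒ less stable", and the printed D816V arithmetic
(26.3 = 6.5 − (−19.8)). The activation value is

$$\Delta\Delta G_{activation} = \Delta\Delta G_{active} -
  \Delta\Delta G_{inactive} \;(= \Delta G_{folded,inactive} -
  \Delta G_{folded,active}),$$

the unfolded leg cancelling exactly (asserted as a property test). Errors
propagate in quadrature, which reproduces both printed combined
uncertainties in the KIT table (0.4 from 0.2/0.3 and 1.4 from 0.5/1.3) —
the package's justification for assuming independent legs.

**Classification.** With threshold $\tau$ (default 4 kJ/mol, the scale of
typical error in computational free-energy estimates vs experiment —
chosen so a −1.6 kJ/mol per-state effect counts as marginal), in order:
`ddg_active < −τ` ⇒ deactivating; else `ddg_inactive < −τ` or
`ddg_active > τ` ⇒ activating; else neutral. A call whose deciding value
is smaller in magnitude than its own SE is downgraded to `indeterminate`.
Whether τ should instead scale with each mutation's own uncertainty is not
decidable from the available data; a fixed τ exposed in `run_config()` was
chosen for transparency. JM-domain mutants have no active-state leg; their
active ΔΔG is taken as 0 (the JM segment is presumed unstructured, hence
mutation-insensitive, in the active state) when `assume_active_zero =
TRUE`.

**The bundled KIT table** (`kit_printed_ddg()`) records provenance per
row. Two caveats are stored explicitly rather than resolved silently:
D816V's inactive-state value is reconstructed (−19.8 ± 0.5, minus the
WT-referenced activation baseline); G812V's inactive-state SE appears as
both 0.5 and 0.4 in the source — both rows are kept, the second flagged
`variant` and excluded by default. V559A/V560D inactive-state values are
*synthetic* stand-ins (−8.0 ± 1.0) that encode only the qualitative
finding (destabilizing, beyond τ); conclusions about their magnitudes must
not be drawn from this table.

## Structural activation metrics

All coordinates are in nm; residues are addressed by author (PDB) numbers
so KIT sites (D810, F811, R791, K623, E640) need no renumbering.

- **Dihedrals.** Standard right-handed torsion via the atan2 formulation
  (cross-checked in tests against an independent implementation). Φ is
  C(i−1)–N–CA–C. Ψ is implemented as the *carbonyl* torsion N–CA–C–O by
  default — matching the metric definition used for the DFG/HDR
  descriptors here — with `convention = "next_n"` switching to the
  conventional N–CA–C–N(i+1); the two differ by 180° for ideal sp²
  geometry. Raw angle series are emitted; DFG in/out or spine
  aligned/broken binary calls need study-specific boundaries and are left
  to user-supplied thresholds.
- **Salt bridges.** Per frame, the minimum over all lysine amine-N ×
  carboxylate-O pairs (NZ × OE1/OE2 or OD1/OD2), symmetric in the
  chemically equivalent oxygen labels.
- **PCA.** Frames are least-squares superposed onto the mean structure of
  the selected atoms (iterated to convergence, since the mean moves with
  the fit), then the covariance is eigendecomposed (`prcomp`). No mass
  weighting (uniform weights; no masses are defined for the toy systems).
  "Backbone" means N, CA, C, O. The spine PCA restricts to the
  catalytic-spine residues 621, 603, 678, 798, 799, 800 and
  regulatory-spine residues 656, 644, 811, 790 (one listed token, "L7999",
  is read as a typographical duplicate of L799). External structures are
  projected by matching atoms on (residue number, atom name), superposing
  onto the model mean, and taking inner products with the modes.
  Degenerate input (all frames identical) is an error, not an empty model.
- **Subsampling.** `subsample_evenly()` picks indices
  $\mathrm{round}(k(F-1)/(n-1))$, half-up rounding for determinism, always
  including the first and last frames; the default n = 750 matches common
  practice for metric distributions.

## What the synthetic data does and does not emulate

`generate_cft_work_samples()` draws from the unique Gaussian pair
satisfying the Crooks relation exactly: $W_f \sim N(\Delta G + W_d,
\sigma^2)$, $W_r \sim N(-\Delta G + W_d, \sigma^2)$ with $\sigma^2 = 2
W_d/\beta$ (fluctuation–dissipation). This makes ground truth analytic, so
estimator bias and bootstrap calibration are testable. Real alchemical
work distributions can be skewed, heavy-tailed, or bimodal (slow degrees
of freedom), and forward/reverse dissipation can be asymmetric — none of
which the generator produces. Passing tests therefore demonstrate
correctness of the estimators *under the CFT-Gaussian model*, not
robustness to pathological work distributions; the overlap diagnostic is
the practical guard there. Default sample counts are 450 per direction,
the campaign size typical of nonequilibrium switching studies on kinases.

The peptide generator builds idealized backbone geometry (standard bond
lengths/angles, planar trans amides) by internal-coordinate chain
extension, so prescribed dihedrals round-trip to ~1e-12°; it carries no
side chains (salt-bridge fixtures place NZ/OE/OD atoms directly at
prescribed distances) and no physical energetics. The Gaussian-ensemble
generator plants exact low-rank covariance; planted-mode recovery tests
fit with superposition disabled because the toy frames share a fixed
global frame by construction, while rigid-motion invariance is tested
separately with superposition enabled.

## Problem sizes and reproducibility

The test suite uses n = 5000 work samples for estimator recovery (12
parameter combinations, 40 seeded cases), n = 10⁴ for the bias bound
(20 replicates, |bias| < 0.1 kJ/mol at 4 kJ/mol dissipation), 50
regenerated work sets for bootstrap calibration, 100 random targets for
dihedral round-trips, and 2000–5000 frames for PCA recovery — sizes at
which the statistical assertions have comfortable margins while the whole
suite runs in about two minutes on one core. All stochastic steps take
explicit integer seeds and preserve the caller's RNG state; identical
configuration and seeds give byte-identical output files (outputs embed
the package version and a config hash, never timestamps).

## Known limitations

- The per-leg ΔG values behind the KIT table are not recomputable here
  (they require ~μs-scale MD plus 450×2 alchemical transitions); the
  cycle/classification layer consumes printed per-state values, and the
  estimator layer is validated on synthetic work.
- `crooks_crossing_estimate()` is only as good as the normality of the
  work distributions; prefer BAR whenever the overlap is adequate.
- The ± values are treated as 1 SD everywhere; if a source reports another
  interval width, rescale before input.
- No Jarzynski (exponential-averaging) estimator and no autocorrelation
  analysis of work series are provided.
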