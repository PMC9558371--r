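# kitddg

Free-energy inference of kinase mutation effects from nonequilibrium work
samples, applied to the receptor tyrosine kinase KIT.

Point mutations in KIT shift its active–inactive equilibrium: oncogenic
mutations (e.g. D816V, V559A, V560D) drive constitutive activation, while
loss-of-function mutations (G812V, V620A) cause piebaldism. `kitddg`
implements the desk-scale statistical machinery for predicting which way a
mutation pushes that equilibrium from alchemical free-energy data:

1. **ΔG estimation.** Given forward and reverse work samples `W_f`, `W_r`
   from fast alchemical WT→mutant transitions, the Crooks fluctuation
   theorem, `P_f(W) / P_r(−W) = exp[β(W − ΔG)]` with `β = 1/(k_B T)`, ties
   the two work distributions to the equilibrium free-energy difference.
   The package estimates ΔG by the Bennett acceptance ratio (BAR)
   maximum-likelihood equation

   ```
   Σ_i 1 / (1 + exp[β(M + W_f,i − ΔG)]) = Σ_j 1 / (1 + exp[β(W_r,j + ΔG − M)]),
   M = β⁻¹ ln(n_f / n_r),
   ```

   solved by bracketed bisection, and alternatively by the crossing point
   of Gaussian fits to `P_f(W)` and `P_r(−W)`. Uncertainties come from a
   100-fold bootstrap over both work lists; a histogram overlap coefficient
   diagnoses the non-overlap regime where BAR degrades.

2. **Thermodynamic cycles.** Per-state relative stabilities close the
   folding cycle, `ΔΔG_state = ΔG_unfolded − ΔG_folded` (negative = mutant
   less stable than WT in that state), and the activation cycle gives
   `ΔΔG_activation = ΔΔG_active − ΔΔG_inactive` (positive = activation more
   favourable for the mutant). Standard errors propagate in quadrature.
   A threshold rule (τ = 4 kJ/mol by default) classifies each mutation:
   destabilizing the active state ⇒ *deactivating*; destabilizing the
   inactive state or overstabilizing the active state ⇒ *activating*.

3. **Structural activation metrics.** On multi-model PDB ensembles:
   DFG-motif Φ/Ψ (D810, F811) and HDR Φ (R791) backbone dihedrals, minimum
   K623–E640 / K623–D810 salt-bridge distances, and catalytic/regulatory
   spine and global backbone PCA with projection of external structures
   onto a reference covariance model.

4. **Synthetic data.** Generators for work samples that satisfy the Crooks
   relation exactly (Gaussians with `σ² = 2 W_diss/β`), idealized peptides
   with prescribed backbone dihedrals, prescribed salt-bridge geometries,
   and ensembles with planted low-rank covariance — so every stage of the
   pipeline is testable without running molecular dynamics.

## Worked example

```r
library(kitddg)

# synthetic transformation: true dG = 5 kJ/mol, 2 kJ/mol dissipated work,
# 450 transitions per direction at 310 K
ws  <- generate_cft_work_samples(dg_true = 5, dissipation = 2, seed = 1)
estimate_work_set(ws, "BAR", n_boot = 100, seed = 1)
#> dG = 5.1677 +/- 0.1059 kJ/mol  [BAR, 100 bootstrap]  synthetic

# bundled per-state ddG values of the five KIT mutations -> cycles + labels
res <- demo_kit()
res$scatter[, c("mutation", "ddg_inactive", "ddg_active", "ddg_activation", "label")]
#>   mutation ddg_inactive ddg_active ddg_activation        label
#> 1    V559A         -8.0        0.0             NA   activating
#> 2    V560D         -8.0        0.0             NA   activating
#> 3    D816V        -19.8        6.5           26.3   activating
#> 4    V620A        -13.7      -12.1            1.6 deactivating
#> 5    G812V         -1.6      -12.0          -10.4 deactivating

res$cycles$D816V
#> D816V: ddG_inactive  -19.8 +/- 0.5 | ddG_active    6.5 +/- 1.3 | ddG_activation   26.3 +/- 1.4 kJ/mol
```

The BAR estimate recovers the generating ΔG within its bootstrap error.
In the KIT table, D816V both destabilizes the inactive autoinhibited state
(ΔΔG_inactive = −19.8 kJ/mol) and overstabilizes the active state
(+6.5 kJ/mol), giving a strongly positive activation ΔΔG of 26.3 ± 1.4
kJ/mol — the signature of an activation-loop oncogenic mutation — while the
piebald mutations destabilize the active state. The juxtamembrane mutants
V559A/V560D have no active-state leg (the JM domain is unstructured in the
active state), so their active-state ΔΔG is taken as 0; their bundled
inactive-state values are qualitative stand-ins (see `?kit_printed_ddg`).

A thin command-line wrapper with subcommands `simulate-work`, `estimate`,
`cycle`, `metrics` and `demo-kit` is installed at
`system.file("scripts", "kitddg", package = "kitddg")`.

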