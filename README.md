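# hairpinxb

Quantifying a single weak halogen bond from solution NMR, by ensemble
deconvolution of a β-hairpin model peptide.

A halogen bond of 1–3 kJ mol⁻¹ in water is far below what chemical-shift
titrations can detect. The strategy implemented here embeds the
interaction across the strands of a cooperatively folding β-hairpin
(12 residues, central D-Pro–Gly type II′ turn) and reads its strength out
of the *folded population*: the σ-hole donor (a halogenated imidazole
side chain) and the Lewis-base acceptor (an ether/thioether side chain)
face each other across the strands, so a formed X···Y bond stabilizes the
fold, and a single-atom substitution (C–X → C–H, O/S → CH₂) provides a
reference compound that cannot form it.

The analysis is a two-stage ensemble deconvolution over a pool of
candidate conformers:

1. **Backbone stage** — population-averaged NOE distances and
   ³J(NH–Hα) couplings are fitted by non-negative least squares.
   NOE buildup rates σ over seven mixing times are calibrated internally
   against the geminal methylene pair, r = r_ref (σ_ref/σ)^{1/6} with
   r_ref = 1.78 Å; NOE restraints are fitted in r⁻⁶ space, where the
   population average Σₖ pₖ rₖ⁻⁶ is linear in the populations p, and J
   restraints through the Karplus relation
   J(φ) = A cos²θ + B cos θ + C, θ = φ − 60°. The solver minimizes
   ‖W(Ap − y)‖² + λ²(Σp − 1)² subject to p ≥ 0 (NNLS on the augmented
   system). The folded fraction is 100·Σ_{folded} pₖ, with conformers
   classified as folded hairpins by type II′ turn torsions (±30°), mean
   cross-strand Cα–Cα distance ≤ 6 Å, and ≥ 4 of the 6 designated
   interstrand hydrogen bonds.
2. **Side-chain stage** — ¹H,¹³C residual dipolar couplings
   (D = T_strong − T_weak from gel-compression coupling pairs) determine
   the side-chain geometry: a Saupe alignment tensor (5 components, via
   SVD) and conformer populations are optimized alternately against the
   RDCs, with the Cornilescu quality factor
   Q = rms(D_obs − D_calc)/rms(D_obs) (Q < 0.3 good, < 0.4 acceptable)
   and the design condition number (CN < 30 reliable) as diagnostics.
   Conformers are halogen-bonded when d(X···Y) ≤ ΣvdW (inclusive) and
   the C–X···Y angle exceeds 120° (exclusive), using Bondi radii.

Population differences convert to energies through the Boltzmann
relation ΔΔG = −RT ln(p/p_ref), and DFT dimer interaction energies are
reduced to relative values ΔΔE = ΔE − ΔE_ref for the energy/population
correlation report.

Because the original restraint tables are not machine-readable, the
package ships a first-class synthetic generator: idealized hairpin
conformers built in torsion space (NeRF), two-state folded/unfolded
pools with known ground-truth populations and alignment tensor, and
forward-simulated NOE/J/RDC tables with per-kind Gaussian noise — so
every fitting stage is validated by parameter recovery against known
truth.

## Worked example

```r
library(hairpinxb)

# a 20-conformer two-state pool, truth folded fraction 50%
cfg <- generator_config(seed = 11, n_folded = 10, n_unfolded = 10)
sim <- sample_pool(cfg)
obs <- simulate_observables(sim$pool, sim$truth, seed = 99)

# backbone stage: buildups -> distances -> NNLS populations
noe <- noe_distances_from_buildups(obs$noe)
m   <- build_design_matrix(sim$pool, noe = noe, j = obs$j)
fit <- fit_populations(m)
folded_fraction(fit, sim$truth$folded_labels)
#> [1] 45.54112

# side-chain stage: alternating SVD tensor / NNLS population fit
rfit <- fit_tensor_and_populations(sim$pool, obs$rdc)
rfit$q; rfit$cn
#> [1] 1.800798e-07
#> [1] 5.028301

# energetics: a 65%-folded compound vs the 22%-folded reference
boltzmann_ddg(0.65, 0.22)
#> [1] -2.685416
fold_ratio(0.65, 0.22)$fold_label
#> [1] "3-fold"
```

The recovered folded fraction (45.5%) sits within the method's ~5-point
accuracy of the 50% truth; the RDC fit interpolates the noiseless-scale
synthetic data (Q ≈ 0) with a well-conditioned tensor (CN ≈ 5); and
the Boltzmann arithmetic turns measured folded populations (22–65%)
into the 1–3 kJ mol⁻¹ stabilization range expected for a weak halogen
bond in water.

An end-to-end run (simulate → classify → fit both stages → energetics →
JSON report) is one call:

```r
run_full(list(seed = 7, generator = list(n_folded = 6, n_unfolded = 6),
              output_dir = "out"))
```

or, from a shell, via the thin CLI wrapper:

```sh
Rscript inst/cli/hairpinxb.R run-full \
    --config inst/extdata/demo_run.yaml --out out/
```

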