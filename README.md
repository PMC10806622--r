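# ndiskit

Neutron diffraction with isotopic substitution (NDIS) analysis for ion
hydration: from molecular configurations to difference-signal observables
and three-dimensional hydration density maps, built for tetrahedral solutes
such as the tetramethylammonium cation (TMA, N(CH₃)₄⁺).

## The problem

In aqueous solutions the neutron diffraction pattern is dominated by
water–water correlations. NDIS isolates solute–solvent structure by
subtracting patterns of chemically identical samples that differ only in
H/D labeling. For TMA — twelve equivalent non-exchangeable hydrogens, large
H/D contrast — two first-order differences (h12 vs d12 solute, in H₂O and
in D₂O) combine into a second-order difference that retains a single pair
correlation:

    ΔΔS_Hnon(Q) = 2 c_Hnon c_HW (b_D − b_H)² · (S_HnonHW(Q) − 1)

in the Faber–Ziman convention, with atomic fractions `c` taken over all
atoms in the solution and coherent scattering lengths `b`; weights are in
mbarn (1 fm² = 10 mbarn). Fourier inversion,

    g(r) − 1 = (1 / 2π²ρ₀) ∫ Q² (S(Q) − 1) W(Q) sinc(Qr) dQ,

with a termination window `W` (Lorch by default, Q_max ≈ 10 Å⁻¹), gives the
real-space signal ΔΔG(r) that simulations can be compared against. The
package implements this whole chain, plus the simulation-side analyses it
is compared with: partial radial distribution functions under periodic
boundaries, coordination numbers and ion-pair censuses, water-orientation
profiles, and permutation-based label-free alignment of solute
neighborhoods into bulk-normalized voxel density maps with tetrahedral
face/edge/corner site occupancies. A synthetic-data module generates
fixtures with known ground truth (homogeneous gases, Gaussian hydration
shells, planted anisotropic patterns, a 2 m TMACl-like box) so every stage
is testable without molecular dynamics output.

Who is it for: anyone turning MD trajectories (or tabulated partial g(r))
into NDIS observables, or quantifying 3D hydration anisotropy around
symmetric solutes where atom labeling is arbitrary.

## Worked example

```r
library(ndiskit)

comp <- tmaclComposition(2)          # 2 mol TMACl per 55.508 mol water
round(atomicFractions(comp), 5)
#>       N   C_TMA   H_non      Cl     O_W     H_W
#> 0.00988 0.03950 0.11850 0.00988 0.27408 0.54816

secondOrderPrefactor(comp)           # mbarn
#> [1] 140.7911
```

The fractions say: 11.85% of all atoms are solute hydrogens and 54.82%
water hydrogens; with b_H = −3.739 fm and b_D = 6.671 fm the single
surviving pair in the second-order difference is weighted by 140.8 mbarn.

A simulated real-space double difference from a model hydration shell
(12 water hydrogens in a Gaussian shell at 6 Å), passed through the
experiment's termination window:

```r
rdf <- analyticRdf(k = 12, r0 = 6, sigma = 0.3, rho = 0.01,
                   r = seq(0.02, 12, 0.02))
sig <- simulatedDdg(rdf, comp, window = windowSpec("lorch", 10))
i <- which.max(signalValues(sig))
c(r_peak = rGrid(sig)[i], mbarn = signalValues(sig)[i])
#>  r_peak   mbarn
#>    5.96   421.6
```

The shell survives the 10 Å⁻¹ termination with its peak within 0.05 Å of
the planted 6 Å. And a density map around an aligned solute, from a
fixture with hydration planted at the tetrahedron's faces:

```r
spec <- fixtureSpec("anisotropic", nSolutes = 10, pattern = "faces", seed = 7)
traj <- generateFixture(spec, nFrames = 60)
ref  <- pickReference(traj, "N", "C_TMA", seed = 0)
grid <- accumulateDensity(traj, "P", ref, "N", "C_TMA")
siteOccupancy(grid, ref, radius = 4.5)
#> SiteOccupancy at r = 4.5 A (relative to bulk):
#>   faces   mean 3.04e+03
#>   edges   mean 0
#>   corners mean 0
```

The planted face pattern is recovered: face sites far above bulk density,
edges and corners empty — even though every neighborhood was randomly
rotated and the carbon labels are never used in the alignment.

A YAML-driven pipeline (`runPipeline()`, stages synth → weights → rdf →
signal → densmap) ties the stages together and writes a manifest with MD5
hashes of every output; `inst/scripts/ndiskit.R` is a thin command-line
wrapper. See the vignette in `vignettes/` for the model, conventions and
numerical choices.

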