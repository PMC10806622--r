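---
title: "From configurations to NDIS observables and hydration density maps"
author: "ndiskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From configurations to NDIS observables and hydration density maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndiskit)
```

## The method

Neutron diffraction with isotopic substitution (NDIS) isolates individual
pair correlations in a liquid by subtracting diffraction patterns of
chemically identical solutions that differ only in isotope labeling. For a
tetrahedral cation such as tetramethylammonium (TMA, N(CH~3~)~4~^+^), four
samples — h12/d12 solute in H~2~O/D~2~O — yield two *first-order*
differences (all correlations involving the solute's twelve non-exchangeable
hydrogens) whose own difference, the *second-order* difference, retains a
single term:

$$\Delta\Delta S_{\mathrm{H_{non}}}(Q) \;=\;
  2\,c_{\mathrm{H_{non}}} c_{\mathrm{H_W}} (b_D - b_H)^2\,
  \bigl(S_{\mathrm{H_{non}H_W}}(Q) - 1\bigr),$$

in the Faber–Ziman convention, where $c_\alpha$ are atomic fractions over
*all* atoms in the solution (solute, counterions, water) and $b$ are
coherent scattering lengths. Weights are reported in mbarn
(1 fm^2^ = 10 mbarn). The real-space counterpart follows from

$$g(r) - 1 = \frac{1}{2\pi^2\rho_0}\int Q^2\,(S(Q)-1)\,W(Q)\,
  \frac{\sin Qr}{Qr}\,\mathrm{d}Q,$$

with $\rho_0$ the total atomic number density and $W$ a termination window.
The package implements this chain — composition → weights → partial RDFs →
structure factors → difference signals — plus a label-free, permutation-based
rigid alignment that turns trajectories into bulk-normalized 3D density maps
around the solute, read out at the tetrahedron's face, edge and corner
directions.

## Composition and weights

The concentration basis is molality: 1 kg of water is taken as 55.508 mol
(M = 18.0153 g/mol), so a 2 m TMACl solution contributes 2 formula units
(N + 4 C + 12 H~non~ + Cl) per 55.508 waters; every atom, including the
counterion, enters the fraction denominator. Scattering lengths default to
the standard tabulated (Sears) values

```{r}
scatteringLengths(defaultScatteringTable())
```

and are user-overridable (TSV, `readScatteringTable()`). With these inputs
the second-order prefactor of the 2 m solution evaluates to

```{r}
secondOrderPrefactor(tmaclComposition(2))
```

mbarn. The first-order tables (`firstOrderPrefactors()`) are built by
differencing the full single-sample weight tables, so pairs untouched by the
substitution cancel to machine zero rather than being dropped by an
analytic shortcut; the second order is available both as the direct
single-term assembly and as the difference of two first orders, and the two
routes agree to 1e-12 (a tested invariant). The sign convention is
$\Delta\Delta = \Delta S_{\mathrm{D_2O}} - \Delta S_{\mathrm{H_2O}}$ with
$\Delta S = S_{d12} - S_{h12}$, which makes the prefactor positive.

Because the inelasticity (Placzek) background is set by the ^1^H content,
the two first-order differences carry identical backgrounds;
`placzekCancellationCheck()` verifies that any common smooth background
cancels exactly in the second order, and, when no synthetic background is
injected, reports a smoothing-spline estimate of the residual smooth
component instead (an estimate of the signal's own baseline, not zero).

## Real-space estimators

Partial RDFs are histogram estimators over minimum-image distances in
orthorhombic boxes (triclinic input is rejected). Counts are normalized by
*exact* spherical-shell volumes $\tfrac{4}{3}\pi(r_+^3-r_-^3)$ rather than
the thin-shell approximation $4\pi r^2\Delta r$ — unbiased at small $r$,
and the brute-force oracle used in the tests applies the same contract.
Defaults: $\Delta r$ = 0.02 Å, $r_{\max}$ = 12 Å, bounded by the
minimum-image radius (half the smallest box edge). Pairs sharing a molecule
index are excluded, so a solute-N to solute-H RDF does not see the solute's
own hydrogens; self pairs are always excluded. For same-class RDFs the
estimator mean is $(N-1)/N$; the test suite's flatness checks account for
this and for the doubled variance of ordered pair counting.

Water orientation profiles use the convention that $\theta$ is measured
between the water dipole vector (O toward the midpoint of the two H) and
the *center-to-oxygen* vector: a dipole pointing at the ion therefore reads
$\cos\theta = -1$. Ion-pair censuses count anions in $[0, r_c)$ (contact)
and $[r_c, r_s)$ (solvent-shared) around each cation center; the defaults
$r_c$ = 5.5 Å and $r_s$ = 8 Å bracket the first two counterion shells of
the 2 m system and are user-overridable, since the minima of $g_{NCl}(r)$
shift with the force-field variant.

## Transforms and windows

Both transform directions use trapezoid quadrature on the stored uniform
grids (the grids are short; exactness is preferred over FFT speed), with
the integrand anchored to its analytic value 0 at the origin so the
$[0, Q_1]$ and $[0, r_1]$ segments are not dropped — without this anchor a
constant offset of order $Q_1^3 S(0)$ leaks into the inverse transform.
Defaults: $Q$ from 0.05 to 25 Å^-1^ in steps of 0.05, $r$ from 0.01 to
12 Å in steps of 0.01; the inverse transform refuses grids with
$\Delta Q \cdot r_{\max} \ge \pi/4$ (aliasing), and the forward transform
warns (or errors in strict mode) when $|g-1|$ has not decayed at
$r_{\max}$. On a band-limited Gaussian-shell model the forward transform
matches adaptive quadrature to better than 1e-3 and the unwindowed round
trip is exact to ~1e-13 RMS.

Experimental terminations are modeled by a window equal to 1 at $Q=0$ and
0 at $Q_{\max}$: the Lorch window $\mathrm{sinc}(\pi Q/Q_{\max})$ (default,
$Q_{\max}$ = 10 Å^-1^ — the standard choice in total-scattering practice)
or a raised-cosine taper. Windowing broadens the recovered 6 Å shell peak
but moves it by less than 0.05 Å, which is why peak positions, not peak
heights, are the window-independent observables used for comparison.
`simulatedDdg()` converts a simulated solute-H/water-H RDF into
prefactor·(g−1) in mbarn, optionally round-tripping it through the
experiment's window to mimic termination effects.

## Label-free alignment and density maps

Neighborhoods (all atoms within 10 Å of the solute center) are aligned on
the four methyl carbons without assuming any atom ordering: the Kabsch
superposition is minimized over a permutation set. The default set is all
4! correspondences; the 12 even permutations — exactly the correspondences
realizable by proper rotations of a regular tetrahedron, since its rotation
group acts on the vertices as A~4~ — are available as a faster search.
Only proper rotations (det = +1) are admitted; if the unconstrained optimum
is a reflection the best proper rotation is returned and flagged. For
bead-model solutes with no carbons, the k nearest first-shell atoms
(default k = 4) serve as alignment atoms — a documented approximation. The
representative reference conformation is chosen from a seeded subsample as
the member minimizing mean pairwise aligned RMSD, which is robust to
outlier geometries.

Densities are accumulated on a cubic voxel grid (0.5 Å voxels, 20 Å edge)
as counts per voxel volume per neighborhood, divided by the species' bulk
density — by default the global-box value $N/V$; a radial-shell estimator
(`shellDensityEstimate()`) is provided for small boxes where the global
value over-counts excluded volume. The declared bulk shell for validity
checks is 8–9.5 Å: with the 10 Å neighborhood cutoff, voxels just inside
10 Å are only partially filled, so the shell stops short of the cutoff.
Site occupancies are trilinear interpolations at the 4 face (−v̂), 6 edge
and 4 corner (+v̂) directions at a stated radius.

One subtlety is worth stating: for a *perfectly* symmetric rigid solute all
12 proper correspondences give numerically identical RMSD and the winner is
a floating-point tie-break. Accumulated maps are then invariant only up to
the tetrahedral symmetry — which is harmless, because the face/edge/corner
readout is itself symmetry-invariant. Exact rotation-equivariance holds
whenever the alignment geometry is even slightly asymmetric (thermal
noise), which is the realistic case and the one the tests exercise.

## The synthetic-data generator

The generator produces the statistical structure each stage needs, not
physically equilibrated liquids (no Monte Carlo equilibration, no
correlations beyond those planted):

* `ideal_gas` — uniform points; exercises flatness and normalization.
* `gaussian_shell` — centers with exactly k neighbors at N(r~0~, σ)
  distances; its closed-form RDF (`analyticRdf()`) integrates to exactly k
  excess neighbors, and because independently uniform centers remain
  uniform after convolution, cross pairs contribute an exactly flat
  background in the periodic box.
* `anisotropic` — rigid tetrahedral solutes under independent uniform
  rotations with one planted atom per face/edge/corner site at a set
  radius (0.3 Å jitter). Solute centers keep a 12 Å minimum separation so
  foreign planted atoms cannot enter another solute's readout radius.
* `tmacl_box` — 50 TMA (C–N 1.49 Å, C–H 1.09 Å, rigid tetrahedral),
  50 Cl and 1388 rigid 3-site waters (O–H 0.9572 Å, 104.52°) in a 37.0 Å
  cubic box: the 2 mol/kg composition at ~1.0 g/cm³, placed by
  minimum-distance rejection (2.5 Å between molecular anchors, safely
  below the random-sequential-packing limit) with uniform orientations.

Every generator call takes an explicit seed and restores the caller's RNG
state; identical spec + seed is bit-identical. What passing tests on these
fixtures shows is that the *estimators and transforms* are correct on data
with known ground truth; they do not show that any force field reproduces
real TMA hydration — the generator has no liquid structure, no
hydrogen-bond network and no solute–solvent correlations beyond the
planted ones.

## Problem sizes and numerical choices in the test suite

The suite runs on deliberately modest sizes chosen so every statistical
check still has the power it claims: flatness tests use 800 atoms × 8
frames with exact-Poisson, Bonferroni-corrected bands at a 3σ family
level; shell self-consistency uses 40 centers × 30 frames against the
closed form; planted-pattern recovery accumulates 10^4 aligned
neighborhoods (25 solutes × 400 frames) per pattern, at which the face
sites read far above 2× bulk and corner sites below 0.2× bulk; alignment
recovery and the brute-force 4! oracle run on tens of random rotations.
Tie-breaks: permutation search takes the first minimum; histogram bins are
left-open; coordination integrals interpolate linearly at the cutoff and
treat the $r=0$ integrand as 0.

## Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* No incoherent/inelastic scattering model beyond the constant-background
  cancellation check; no multiple-scattering or absorption corrections —
  raw experimental data reduction is out of scope.
* No structure refinement against experimental data (no EPSR-style
  fitting).
* Frames are weighted equally; no time-correlation correction is applied
  to statistical error estimates.
* The bead-model alignment (nearest-k neighbors) is a pragmatic stand-in
  for an unspecified original procedure and is documented as such.
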