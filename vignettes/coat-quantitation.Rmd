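---
title: "Quantifying a bacterial GBP1 coat: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a bacterial GBP1 coat: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesocoat)
```

`mesocoat` chains together the small quantitative steps needed to
characterize a mesoscale protein coat — the shell of thousands of GBP1
molecules that assembles on the surface of cytosolic Gram-negative bacteria.
This vignette is the package's account of the science behind each step: the
models, their assumptions, the tunable parameters, and the places where the
design was genuinely open and a choice had to be made.

## The molecule census

A fluorescence volume of a coated bacterium overestimates the true coat
volume because structured-illumination volumes are enhanced relative to EM
ground truth. The census divides twice:

$$N = \left\lfloor \frac{V_\mathrm{measured}}{c \cdot V_\mathrm{mol}} \right\rfloor$$

* `correction_factor` (c, dimensionless, default **3.0**) is the ratio of
  fluorescence to EM coat volumes. The default treats the calibration as a
  volume ratio, because that is how such calibrations are made (paired 3D-SIM
  and immuno-EM volumes of the same coats); an alternative reading as a
  linear-dimension ratio applied volumetrically would cube it, and is not
  supported here.
* `per_molecule_volume` (V_mol, nm³) is the van der Waals packing volume of
  one labeled molecule. For a fluorescent-protein fusion it is the sum of the
  two partners' volumes from `molecular_volume()`. The bundled constant
  `vmol_rfp_gbp1_synthetic = 110` nm³ is a synthetic stand-in of the right
  order for a ~67 kDa GTPase plus a ~26 kDa fluorophore, used by tests and
  examples so that no coordinate download is required; it is *not* a measured
  value, and any real census should compute V_mol from coordinates.

Counts are floored to integers (a coat contains a whole number of molecules);
uncertainty is carried separately as mean ± SD, never folded into the count.
A relative tolerance of 1e-9 is added before flooring so that a volume
constructed exactly as `c · N · V_mol` always inverts to `N` despite binary
round-off — the constructive round trip is exact by design.

### Packing volumes

`molecular_volume()` computes the volume of the union of atomic vdW spheres
on a regular grid over the padded bounding box. This is deliberately *not* a
per-atom Voronoi partition: the census only needs one number per molecule,
and a union of spheres is unambiguous, probe-extensible and easy to validate
against closed forms (single sphere, two-sphere lens) and an independent
Monte-Carlo rejection estimator. Defaults: `grid_spacing = 0.3` Å (empirically
< 3 % error on analytic test cases at tractable cost; halving the spacing
roughly quarters the discretization error), `probe_radius = 0` (bare vdW
union; set ~1.4 Å for a solvent-inflated envelope). A spacing so coarse that
no grid point falls inside any sphere is a degenerate input and errors.
Radii come from a bundled Bondi-style element table (`vdw_radii()`),
overridable per call; unknown elements get the carbon radius 1.7 Å with a
warning rather than an error, since exotic heteroatoms are rare and a census
is insensitive to a single radius.

## Cell geometry

Rod-shaped bacteria are modeled as spherocylinders; minicells and
outer-membrane vesicles as spheres. The spherocylinder convention here is
that `total_length` is **tip-to-tip including both hemispherical caps**, so
the surface area collapses to the single closed form `π·d·L_total` (the
degenerate case `L = d` is exactly a sphere). This convention is stated
explicitly because rod dimensions are often reported ambiguously; with it,
`surface_area`, `shell_volume` (difference of inflated and original solids)
and `extrapolate_count` (density × area, SD scaled linearly) are all exact
closed forms, cross-checked in the tests against quadrature and
voxel-counting oracles at 1 nm resolution.

## Assembly kinetics

`estimate_rate()` fits an ordinary least-squares line to the cumulative
count over the *growth phase*, defined as counts between 10 % and 90 % of
the final value. The windowing excludes the nucleation lag and the plateau;
the bounds are configurable because the underlying instruments and
segmentation pipelines differ in how much lag they record. A perfectly flat
trajectory returns rate 0 rather than erroring; fewer than three in-window
points is an error, since a slope from two points has no residual degree of
freedom. `completion_time(N, rate)` is the trivial `N / rate` in minutes —
kept as a named operation because it is the quantity compared against
observed encapsulation windows (a ~3×10⁴-molecule coat at ~10² molecules/s
completes in ~5 min, inside the observed 1–6 min window).

## The cooperative coating curve

Bacterial encapsulation versus protein concentration is strongly sigmoidal:
an all-or-none, cooperative transition summarized by a four-parameter Hill
model with half-maximal concentration ("coat Km") and Hill slope h. The fit
is bounded Levenberg–Marquardt (`minpack.lm`), and two numerical choices
matter:

* **Deterministic multi-start.** Steep curves (h ≈ 5) make single-start fits
  fragile. The fitter starts from a grid — km₀ = geometric mean of the
  concentrations × {¼, ½, 1, 2, 4}, crossed with h₀ ∈ {1, 4} — and keeps the
  best converged start by RSS. A seeded random jitter would do the same job;
  the grid was chosen so the fit is a pure function of the data with no RNG
  dependence at all. Bounds: h ∈ (0, 20], km ∈ (0, 10⁶] nM, bottom ∈
  [−0.5, 1], top ∈ [0, 1.5].
* **Free vs constrained asymptotes.** Whether published coating-curve fits
  constrain bottom/top to 0/1 is usually unstated. Both variants are
  provided (`constrain_range`); the free four-parameter fit is the default
  because fractions near the asymptotes carry measurement error and a free
  fit lets the data speak. Replicates are fitted pointwise, never on means,
  preserving the error structure.

**Identifiability.** On a two-fold dilution grid spanning 2000→15.6 nM, a
curve with km = 225 nM and h ≈ 5 places essentially one concentration inside
the steep transition. The Km is then well determined (the transition's
*position*), but the slope — the transition's *steepness* — is weakly
identified: its residual-sum-of-squares profile is nearly flat above the
true value, and the asymptotic standard error reported by `summary()` on
such fits is large. Single noisy realizations of the slope therefore scatter
substantially even at noise SD 0.03, while the Km recovers to a few percent.
This is a property of the experimental design, not of the fitter; a grid
with 1.5-fold steps through the transition would pin the slope far better.

## Equilibrium binding

Fluorescence-anisotropy titrations are fitted with the single-site
ligand-excess isotherm (hyperbola in protein concentration), estimating
(Kd, r_free, r_bound). The assumption is that the titrated protein is in
excess of the fluorescent LPS probe, which holds for micromolar binders
titrated against a 250 nM probe. For affinities approaching the probe
concentration (the caspase-4 case, Kd ≈ 313 nM ≈ probe), probe depletion
biases the hyperbolic Kd upward; `fit_kd(..., exact_binding = TRUE)`
switches to the exact quadratic bound-fraction form with the probe
concentration as a known constant. The hyperbola remains the default because
it is the conventional reported quantity and the two agree when Kd ≫ probe.
Signal units are pass-through (mP or % of maximal polarization); the fit is
unit-agnostic. Flat titrations (dynamic range ≤ 10 % of the maximum signal)
are refused as unidentifiable: `converged = FALSE` with diagnostics, never
an exception.

`lps_budget()` closes the loop between coat assembly and inflammasome
biology: released LPS molecules as a fraction of the ~2×10⁶-molecule
per-cell pool (released amounts below 1 % are flagged, since even sub-percent
release can exceed the caspase-4 affinity scale in a small assay volume —
the optional molar conversion makes that comparison explicit).

## Tomographic metrology

* **Conformer lengths** are shortest Euclidean point-to-surface distances
  from each GTPase-domain apex to the membrane: exact `| ‖p−c‖ − R |` for an
  analytic sphere, nearest-neighbor for a segmented point-cloud membrane.
  Shortest distance (not radial projection) is used because that is what
  contour-based measurement tools report; the two coincide exactly on
  spheres. Apexes inside an analytic sphere by more than 0.5 nm warn and use
  the absolute distance. Lengths are stored in Å (the structural-biology
  unit for these ~280 Å conformers); all geometry inputs are in nm.
* **Enumeration**: per-segment density = count/area; whole-cell count = mean
  density × total surface area; the SD across segment densities, divided by
  √n_segments and scaled by the area, is the propagated count SD. When the
  segments tile the whole surface the estimate is exact by construction and
  the SD reflects only placement unevenness.
* **Feasibility**: `ceil(thickness / closed_length)` closed conformers are
  needed to span a measured coat (2–3 for a 25–27 nm coat and a 12.89 nm
  closed conformer), while a single ~27.8 nm open conformer is consistent
  within a 2 nm default tolerance — the geometric argument for the
  open-extended coat architecture.
* **FSC**: per-shell normalized cross-correlation of 3-D Fourier
  coefficients; shells are integer-rounded radial frequency indices;
  resolution is 1/frequency at the first downward crossing of the threshold
  (default 0.143, the gold-standard half-map criterion), linearly
  interpolated between shells. Identical volumes never cross and report the
  Nyquist limit with `crossed = FALSE`. Volumes are plain R arrays: pairs
  come from `gen_halfmaps()` or from whatever reader the user's map format
  requires; no map-file I/O is bundled.

## What the synthetic generators emulate — and what they do not

Every analysis input has a seeded generator (`gen_titration`,
`gen_anisotropy`, `gen_trajectory`, `gen_minicell_field`, `gen_coat_volume`,
`gen_toy_structure`, `gen_halfmaps`). Each is a pure function of its
arguments: the seed is passed explicitly, the caller's RNG state is saved
and restored, and identical calls are byte-identical. Noise defaults (0.03
fraction units for titrations, 2 % of dynamic range for anisotropy, Poisson
counting for trajectories, 1.5 nm for conformer lengths) were chosen once to
match the error bars typical of the corresponding experiments.

The generators reproduce the *statistical structure the estimators assume* —
Gaussian or Poisson noise around the true model, area-uniform placement on
an ideal sphere, brickwall band-limited signal plus white noise. Real data
violate all of these in instructive ways: coating fractions are binomial
proportions with concentration-dependent variance, minicells are not perfect
spheres and segmentation masks are irregular, tomographic noise is neither
white nor isotropic (missing wedge), and measured conformer lengths mix two
conformational populations rather than one Gaussian. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators *under their own assumptions* — unbiasedness, invariances, exact
round trips — not robustness to instrument systematics.

Simulation sizes in the test suite and reproduction script are the study's
native scales where those are small (30,483 length measurements, 11,760
conformers, 24-point titrations) and reduced repeat counts (100–200 seeded
replicates) for the unbiasedness loops, which keeps the whole suite in the
tens of seconds on one CPU.

## Structure screens

`read_pdb()` parses ATOM records via `bio3d`, resolves alternate locations
to the highest-occupancy copy (ties by altloc label order), keeps the first
model, preserves the file's residue numbering, and annotates vdW radii.
`max_extent()` is the exact maximal pairwise atom-center distance (optionally
plus the two endpoint radii). `cys_pair_screen()` reports Cβ–Cβ distances
between two residue sets within a window (default 2–7 Å, the span where
cysteine substitution can form a disulfide staple), sorted ascending, plus
each residue's nearest partner regardless of window. Glycine has no Cβ; a
virtual Cβ is constructed from the backbone N/Cα/C frame with ideal
tetrahedral geometry, so glycine positions can be screened for *introduced*
cysteines. Note the screen measures Cβ–Cβ separations of the native
residues — not the S–S bond length of the modeled cross-link, which is
shorter (~2 Å) and requires side-chain modeling that is out of scope here.

## Known limitations

* The union-of-spheres volume is not a Voronoi packing volume; it excludes
  internal cavity bookkeeping. For census purposes (one number per molecule)
  the difference is absorbed by the correction factor's calibration.
* The hyperbolic Kd is biased upward when Kd ≲ probe concentration; use
  `exact_binding = TRUE` there.
* `enumerate_density` assumes segments sample the surface representatively;
  clustered coats on a partially segmented cell violate the mean-density
  extrapolation.
* The spherocylinder shell formula assumes an outward offset of a convex
  solid; it does not model septating or curved cells.
* No map-file or mmCIF I/O; coordinates come in as PDB, volumes as arrays,
  point sets as matrices/data frames.
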