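# mesocoat

Quantitative analysis of mesoscale protein coats on bacterial surfaces.

Interferon-inducible guanylate-binding protein 1 (GBP1) polymerizes into a
~10^4-molecule coat that encapsulates cytosolic Gram-negative bacteria,
disrupts the LPS outer leaflet and nucleates the caspase-4 inflammasome
platform. Characterizing such a coat quantitatively requires a chain of small,
testable calculations that span imaging modalities: converting fluorescence
volumes into molecule counts, fitting cooperative assembly curves and
equilibrium binding isotherms, measuring conformer lengths and surface
densities in cryo-electron tomograms, and screening atomic structures for
disulfide-staple candidates. `mesocoat` implements that chain as composable R
functions, together with seeded synthetic-data generators that emulate every
input, so the whole pipeline runs and is tested without any instrument data.

## What it computes

- **Molecule census** (`census_from_volume`): `N = floor(V_measured / c / V_mol)`,
  where `V_mol` is the van der Waals packing volume of one labeled molecule
  (from `molecular_volume`, a grid union of vdW spheres over atomic
  coordinates) and `c` is the fluorescence-enhancement correction (default
  3.0, calibrated against matched immuno-EM volumes).
- **Assembly kinetics** (`estimate_rate`, `completion_time`, `fit_hill`):
  molecules/sec from the growth phase of cumulative-count trajectories, and
  the cooperative coating curve
  `f(C) = bottom + (top − bottom)·Cʰ/(Kmʰ + Cʰ)` fitted by bounded
  Levenberg–Marquardt with deterministic multi-start, yielding the "coat Km"
  and Hill slope `h`.
- **Equilibrium binding** (`fit_kd`, `lps_budget`): single-site anisotropy
  isotherm `r(C) = r_free + (r_bound − r_free)·C/(Kd + C)` (with an optional
  probe-depletion quadratic form), and LPS release accounting against the
  ~2×10^6-molecule per-cell pool.
- **Tomographic metrology** (`measure_lengths`, `enumerate_density`,
  `feasibility`, `fsc`): apex-to-membrane shortest distances (conformer
  lengths), per-segment surface densities extrapolated to whole-cell counts,
  closed/open conformer stacking feasibility, and Fourier shell correlation
  with resolution read at the 0.143 threshold.
- **Structure screens** (`read_pdb`, `max_extent`, `cys_pair_screen`):
  maximal atomic extents and Cβ–Cβ distance windows (2–7 Å) for engineering
  disulfide cross-links, with virtual Cβ construction for glycine.
- **Synthetic data** (`gen_*`): seeded generators for titrations, isotherms,
  trajectories, minicell conformer fields, coat volumes, toy structures and
  FSC half-map pairs, each carrying its generating truth as an attribute.

## Worked example

```r
library(mesocoat)

# cooperative coating curve: 2-fold dilutions from 2 uM, 3 replicates
tit <- gen_titration(km = 225, hill_slope = 5.122, noise_sd = 0.03, seed = 42)
fit_hill(tit)
#> <hill_fit> coat Km = 225.8 nM, Hill slope = 6.758 (bottom 0.0108, top 0.997)
#>   RSS = 0.006126 over 24 points

# molecule census round trip at the reference coat size
v <- gen_coat_volume(29542, vmol_rfp_gbp1_synthetic, correction_factor = 3.0)
census_from_volume(v, vmol_rfp_gbp1_synthetic)
#> <coat_census> 29,542 molecules (V = 9.749e+06 nm^3 / 3 / 110 nm^3)

# encapsulation time at 103 molecules/sec
completion_time(29542, 103)
#> [1] 4.780259

# conformer metrology on a synthetic minicell
mini <- gen_minicell_field(radius = 150, n_conformers = 11760, seed = 11)
measure_lengths(mini$field)
#> <length_distribution> n = 11,760, mean = 279.9 A, sd = 15.1 A
enumerate_density(mini$field, mini$segment_areas)$count
#> [1] 11760

# resolution of a synthetic half-map pair with signal band-limited at 20 A
hm <- gen_halfmaps(signal_resolution = 20, seed = 101)
fsc(hm$vol1, hm$vol2, hm$voxel_size)
#> <fsc_curve> 33 shells, threshold 0.143: resolution 17.97 A
```

The coat Km lands within 1 % of the generating truth; the Hill slope is the
least-identified parameter of the four (a 2-fold dilution grid places only
one concentration inside the steep transition), so individual realizations
scatter around the truth noticeably more than the Km does — see the methods
vignette
(`vignettes/coat-quantitation.Rmd`) for the identifiability analysis. The
census, enumeration and length measurements recover their constructions
exactly or to well under 1 %.

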