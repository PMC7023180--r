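---
title: "Methods: simulating and clustering colorimetric sensor-array responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and clustering colorimetric sensor-array responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csaclust)
```

## The measurement model

A structural-color sensor cell is a periodic film that reflects, at
normal incidence and first order, the Bragg wavelength

$$\lambda = 2\, n_\mathrm{eff}\, d\,(1 + s),$$

where $d$ is the unswollen structure period, $n_\mathrm{eff}$ the
effective refractive index, and $s$ the fractional swelling caused by
analyte uptake. `csaclust` models the reflectance spectrum as a Gaussian
peak at $\lambda$ (FWHM `peak_width_nm`, default 30 nm; peak reflectance
0.9 on a 0.05 baseline) — the simplest shape consistent with a single
dominant reflected band. No attempt is made at transfer-matrix thin-film
optics or angle dependence; the simulator's job is to produce images
whose *statistical* structure (class-dependent ΔRGB patterns plus camera
noise) matches what the downstream analysis must cope with, not to be
photometrically faithful.

Swelling of cell (phage $p$, film $f$) exposed to analyte $a$ at
temperature $t$ follows a saturating uptake curve scaled by a
temperature gain:

$$s = \min\!\Big(s_\mathrm{max},\; s_\mathrm{max}\,
  \frac{e}{e + K_{p,a}}\; g_{a,t}\Big),$$

with exposure $e$ (default 1, arbitrary units), half-saturation
"affinity" $K_{p,a} > 0$ per (phage, analyte) pair, and gain $g_{a,t}$
per (analyte, temperature). The saturating form is the standard
single-site adsorption shape; the temperature gain encodes the
observation that higher temperature (higher vapor pressure) strengthens
the film reaction. Whether real responses saturate or reverse at high
temperature is unknown to us; `temp_gain` is therefore an explicit,
configurable dial, defaulting to the monotone profile 0.4 / 0.7 / 1.0 /
1.3 at 30 / 60 / 90 / 120 °C.

## Colorimetry

Spectra are rendered to 8-bit sRGB by integrating the reflectance
against the CIE 1931 2° colour-matching functions on a 10 nm grid over
380–780 nm, normalising so a flat unit spectrum has luminance $Y = 1$,
applying the linear-sRGB (D65) matrix and the sRGB transfer curve, and
rounding to integers; out-of-gamut channels are clipped and flagged. For
the colour-matching functions we use the published piecewise-Gaussian
analytic fit (Wyman, Sloan & Shirley 2013) rather than an embedded
table: it is accurate to about 1% of peak, has no transcription risk,
and every property the pipeline relies on (dominant-channel ordering,
smooth monotone shifts with swelling) is insensitive at that error
level. The test suite cross-checks the 10 nm path against direct 1 nm
integration. No chromatic adaptation is applied (the illuminant is
implicitly equal-energy); any *consistent* spectrum-to-RGB path works
here because both the reference and exposed images pass through the same
one.

## The default scenario

The generator's defaults are the study design, chosen once:

| parameter | default | why |
|---|---|---|
| analytes | E1, E2, E3, EE2 (estrogen); AMX, TET, PEN, CIP (antibiotic) | 4 + 4 two-class panel |
| temperatures | 30, 60, 90, 120 °C | four vapor-pressure conditions |
| chip | wild/RGD/EEEE rows × red/green/blue columns | 9 cells per pattern |
| $d$ per film | 216.7 / 183.3 / 150 nm, $n_\mathrm{eff} = 1.5$ | unswollen peaks at 650 / 550 / 450 nm |
| $s_\mathrm{max}$ | 0.12 | keeps swollen peaks inside the visible band |
| affinity $K$ | see `csaclust:::default_affinity()` | estrogens bind the EEEE film strongly, antibiotics the RGD film; wild responds moderately to everything; small within-class gradients keep same-class analytes distinct |
| `noise_sd` | 2.0 counts | realistic 8-bit camera noise; cell-mean noise after 1024-pixel averaging is ~0.06 counts, far below the tens-of-counts class contrast |
| cells / ROI | 48 × 48 px cells, 32 × 32 px centered ROI | ROI = 1024 px, a "~1000-pixel square" |

The "~1000-pixel square" averaging window is read as ~1000 pixels in
total (32 × 32 = 1024), not 1000 pixels on a side; both the ROI side and
the cell geometry are configurable.

What the simulator emulates: class-structured mean responses, their
temperature dependence, i.i.d. Gaussian pixel noise, quantisation to
8 bits, and full determinism from a single root seed (per-image noise
seeds are derived from it). What it does not emulate: spatially
correlated noise, illumination drift between the pre and post image,
chip misregistration, film inhomogeneity, and nonlinear camera response.
A pipeline that passes every test here can still fail on real
photographs for those reasons; the layout is taken from configuration
precisely because automatic registration is out of scope.

## Features and distance

The response signal is the *signed* per-cell change in mean 8-bit
channel values, ΔRGB = post − pre, kept at full floating precision (an
absolute-value option exists for display, off by default): "variation"
of RGB is directional, and discarding signs would fold distinct
spectral shifts together. Patterns are compared with the colour
distance

$$D(a, b) = \sum_{i=1}^{n} (\Delta R_i^a - \Delta R_i^b)^2 +
(\Delta G_i^a - \Delta G_i^b)^2 + (\Delta B_i^a - \Delta B_i^b)^2 ,$$

over the $n$ bins (cells) of the pattern. Colour-distance conventions in
sensor-array work vary between this squared sum and its square root, so
both dialects are implemented: `squared` (the default, and the
conventional input to Ward linkage) and `euclidean` (a true metric). The
choice is recorded in the run manifest so any downstream tree is
auditable. No channel or bin normalisation is applied.

Each analyte is measured at every temperature. How the four
temperatures combine into one pattern per analyte is a genuinely open
design point; the default is the `concatenated` mode (one
temperature-major 36-bin vector per analyte, i.e. 108 numbers), with a
`per_temperature` mode available that analyses each temperature's 9-bin
table separately. The mode is logged in the manifest.

## Clustering

`hierarchical_cluster()` implements agglomeration in-package via the
Lance–Williams recurrence. For `ward_d` the coefficients are
$\alpha_i = (n_i + n_k)/(n_i + n_j + n_k)$ (symmetric in $j$),
$\beta = -n_k/(n_i + n_j + n_k)$, $\gamma = 0$, applied to the input
distances as given — the "Ward.D" dialect. With squared-Euclidean input
each merge height is twice the increment of the error sum of squares
(for singletons $x, y$: $\Delta\mathrm{ESS} = \lVert x-y\rVert^2/2$
while the input distance is $\lVert x-y\rVert^2$); the test suite
verifies merge order and heights against a from-scratch ESS-increment
oracle on random point sets, and against `stats::hclust` as an
independent implementation. `ward_d2` (recurrence on squared distances,
square-rooted heights) is provided for sensitivity analysis, alongside
`single`, `complete` and `average`.

Numerical choices: distances are validated (symmetric, finite,
non-negative, zero diagonal, tolerance 1e-8) before clustering; exact
ties at the minimum are broken toward the lexicographically smallest
(left id, right id) pair — node ids are leaves $0..n-1$ in input order,
internal nodes $n..2n-2$ in merge order — and tie events are counted in
the run manifest so any tree is auditable; all five linkages are
reducible, so merge heights are monotone non-decreasing, which is
asserted on every run rather than assumed. Heights are reported exactly
as the recurrence produces them, with no rescaling.

Tree utilities: `cut_tree()` removes the last $k-1$ merges and labels
components $0..k-1$ in leaf order of first occurrence;
`cophenetic_matrix()` returns the lowest-merge heights (ultrametric by
monotonicity); `dendrogram_to_newick()` writes branch lengths as
height differences parent-to-child so cophenetic structure round-trips
through standard Newick parsers; `classify_unknown()` assigns a query
pattern the class of its nearest reference pattern (ties by reference
order) and reports the distance so callers can threshold weak matches.
The headline cut is $k = 2$ (estrogen vs antibiotic); $k$ remains a
user parameter.

## Verification strategy and problem sizes

The suite pairs every production path with an independent oracle:
brute-force loops for the colour distance (fuzzed pairs at 9 and 36
bins), from-scratch ESS agglomeration and exhaustive single linkage on
point sets of up to 8 points, a lowest-common-ancestor search for
cophenetic matrices, `ape` for Newick re-parsing, and exact round-trip
identity between generator ground truth and extracted features at zero
noise. Class-recovery checks run the full image pipeline (simulate →
render → extract → distance → Ward.D → cut) on the default 8 × 4 design
over 20 seeded replicates and score the adjusted Rand index of the
$k = 2$ cut against the generator's class labels; these sizes keep the
whole suite at a couple of minutes on one CPU while exercising every
stage end-to-end.

## Known limitations

- The optical model is deliberately minimal: Gaussian peak, no
  interference fringes, no angular effects, no illuminant model.
- Real film periodicities and refractive indices for phage bundles are
  not established here; the defaults are placeholders exposed in the
  scenario configuration.
- The simulator's class structure is injected through the affinity
  matrix; recovery results demonstrate that the *pipeline* separates
  classes whose contrast exceeds the noise, not that any particular
  chemistry does.
- `squared`-dialect distances are not a metric (no triangle
  inequality); the suite asserts only symmetry and non-negativity for
  that dialect, and the `euclidean` dialect when metric properties
  matter.
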