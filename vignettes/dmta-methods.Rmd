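---
title: "Methods: surface processing, ISO 25178-2 parameters and dietary discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surface processing, ISO 25178-2 parameters and dietary discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmta)
```

# The problem

Tooth microwear — the field of scratches and pits a few micrometres across
left by food and grit — carries a dietary signal. Dental microwear texture
analysis (DMTA) makes that signal quantitative: a gridded 3D height map of
a small patch of tooth surface is reduced to a vector of standardized areal
texture parameters (ISO 25178-2), and differences between individuals or
populations are tested statistically. In continuously tooth-replacing
animals such as sharks, homologous-facet sampling is impossible, so the
statistical layer must cope with teeth sampled from whole jaws, repeat
fields within a single tooth, and unknown-diet specimens evaluated by
projection rather than classification.

This vignette documents the model each stage implements, the tunable
parameters and their defaults, the numerical choices, and what the
synthetic-data tests do and do not demonstrate about real surfaces.

# Surface preprocessing

The chain (`standard_chain()`) is despike → restore voids → remove form →
high-pass filter, producing a mean-zero *scale-limited roughness surface*.

**Despiking** (`despike()`, default `k = 10`). Focus-variation data contain
single-point spikes that would otherwise be edited by hand. A point is
voided when its absolute deviation from the local 3×3 median exceeds
`k` times the global consistency-scaled median absolute deviation of the
heights. The MAD of the *heights* (not of the deviations) is used as the
scale: for smooth-but-textured surfaces the deviation distribution is
strongly leptokurtic, and a MAD taken on the deviations themselves sits so
far below its own tail that ordinary texture would be voided wholesale.
Against the height MAD, a genuine spike (tens of µm against sub-µm relief)
is detected exactly, and smooth periodic or random textures lose nothing.

**Void restoration** (`restore_voids()`). Non-measured points are filled by
solving the discrete Laplace equation with measured neighbours as boundary
values (sparse solve via the Matrix package). Harmonic fill reproduces
linear fields exactly and obeys the maximum principle, so filled values
never exceed the surrounding relief. More than 50% voids is treated as a
data-quality failure rather than something to interpolate over.

**Form removal** (`remove_form()`, default order 2). A least-squares
bivariate polynomial of total degree ≤ 2 is fitted on coordinates centred
and rescaled to [−1, 1] (conditioning on wide grids) and subtracted. The
residual is orthogonal to the fitted monomials, so adding any degree-≤2
form to a surface does not change its roughness.

**Filtration** (`spline_highpass()`, nesting index 0.025 mm). Waviness is
a frequency-domain areal low-pass on a mirror-extended grid; roughness is
the remainder, mean-subtracted. Two amplitude characteristics are offered
behind one interface: a spline characteristic, `1/(1 + (λc/λ)⁴)`, and the
ISO 16610-61 areal Gaussian, `exp(−π(αλc/λ)²)` with `α = √(ln 2/π)`. Both
transmit exactly 50% of a sinusoid's amplitude at the nesting index, which
is the property the tests pin down; the spline rolls off faster. Mirror
(reflective) extension was chosen because the 146 µm field is only ~6
nesting indices wide: end effects matter, and reflection avoids the
wrap-around leakage of a plain periodic FFT while keeping the filter
linear. No edge crop is applied by default; a crop (e.g. λc/2 per side) is
available and recorded in provenance, because whether one row of the
published fields was cropped during processing is not determinable from
the sources — the choice is therefore explicit, never silent.

One consequence of a non-brickwall filter is that the chain is only
approximately idempotent: re-filtering removes additional energy from the
transition band. For roughness concentrated well inside the passband
(correlation length ~1 µm against a 25 µm cutoff) the second pass changes
Sq by under 1%; for backgrounds with 2–3 µm correlation length the loss
reaches 3–6%. The idempotency test uses a passband-dominated surface for
this reason.

# The 23 texture parameters

Height parameters are plain area-weighted moments. The material-ratio
family derives from the Abbott–Firestone curve `c(p)`: heights sorted
descending, linearly interpolated onto a 1001-point uniform grid of
material ratios, so `c(0) = Sp` and `c(100) = −Sv` exactly. Volumes are
trapezoid integrals of the curve; the core family finds the 40%-width
secant of minimum slope (ties broken at the smallest starting ratio, with
a warning — a genuinely two-level surface has no unique flattest window),
fits the equivalent line to the curve over that window by least squares,
and derives Sk, Smr1, Smr2, and the area-equivalent triangle heights Spk
and Svk.

Sal and Str come from the FFT (circular) autocorrelation. Rays are marched
from zero lag in 360 directions with bilinear interpolation on the lag
grid; the crossing radius where the normalized ACF first falls to
`s = 0.2` (the conventional threshold; the sources do not state one) gives
the per-direction decay distance. Sal is the minimum; Str divides it by
the maximum, with rays that never decay capped at the rectangular lag
window boundary. A mean-zero field's circular ACF always dips below any
positive threshold somewhere, so the undefined case is flagged defensively
but arises only for degenerate inputs.

Sdq and Sdr use central differences, one-sided at edges.

The feature parameters are the least standardized part of legacy DMTA
software, so their definitions are fixed here explicitly: summits are
strict 8-neighbour interior maxima surviving Wolf-style prominence pruning
at 5% of Sz (configurable); prominence is computed exactly by a
descending union-find flood (C++); dales are treated symmetrically on the
inverted surface. Sds is the summit count per unit field area, Ssc the
mean of `−(z_xx + z_yy)/2` at summits, and S5z the mean height of the five
highest summits plus the mean depth of the five deepest dales (computed
over what exists, with a warning, when fewer than five survive). These
choices preserve the monotone behaviours the discrimination relies on
(fewer, larger features → lower Sds) and are checked against a brute-force
BFS prominence oracle.

Defaults that ISO leaves open and the sources do not state: volume
thresholds p = 10%, q = 80%; ACF threshold s = 0.2; pruning 5% of Sz.
Units: µm throughout, Sdr and Smr1/Smr2 in percent, Sds per µm². A reader
for deposited tables accepts a column map and a flag for Smr values stored
as ratios, since deposit conventions vary.

# The discrimination pipeline

For each parameter the homogeneity of group variances is tested twice —
Bartlett and Brown–Forsythe (median-centred Levene, implemented as a
classic one-way ANOVA of absolute deviations from group medians) — and
Welch's ANOVA with Satterthwaite degrees of freedom is used if *either*
rejects at 0.05; otherwise the classic one-way ANOVA. The OR-trigger is
the conservative reading of a protocol that names both tests without
stating the conjunction; which test fired is recorded per parameter so a
replication diff is diagnosable. Across the 23 parameters a
Benjamini–Hochberg step-up at FDR 0.05 flags the discriminating set; the
step-up is implemented directly (it is part of the method) and tested
against `p.adjust`.

Pairwise structure uses Tukey HSD with Tukey–Kramer standard errors for
unequal n, on the pooled within-group variance — applied after either
ANOVA path, as the source protocol does, with a warning when the variance
gate had fired since the pooled-variance assumption is then questionable.
The PCA parameter-selection rule is the union of parameters showing at
least one significant pair.

The PCA is on correlations: each selected parameter standardized to zero
mean and unit SD over the *training* records (known-diet specimens;
within-tooth repeats excluded), eigendecomposition of the correlation
matrix, components signed so the largest-magnitude loading is positive
(published figures may differ in sign; comparisons should use magnitudes
and variance shares). Unknown specimens are projected with the training
means and SDs — never re-standardized — so projection cannot alter the
fitted model.

Spearman correlations of PC1 against ordinal diet rank (ties expected) and
body length use midranks with a t-approximation p-value by default
(appropriate at n ≈ 24–30), with a seeded permutation alternative. The
correlation is computed per tooth, not per specimen; the sources are
ambiguous, and per-tooth is the finer-grained choice and is documented
rather than hidden. Diet ranks follow the ordered relative proportion of
elasmobranch prey (aquarium fish-only = 1 up to the largest wild
individual = 4); the within-tooth group and the unknown specimen are
excluded from rank correlations. Whether the within-tooth group enters the
ANOVA as a sixth group is a config switch
(`include_within_tooth_in_anova`), because the published design can be
read either way.

Subsampling robustness (`subsample_compare()`): k = 6 records drawn
without replacement from the comparison cohort, ANOVA + B–H against the
fixed reference cohort, repeated 10 times with an explicit seed.

# The synthetic generator

Backgrounds are stationary Gaussian random fields with autocovariance
`sq²·exp(−r²/ℓ²)`, synthesized spectrally (FFT of white noise shaped by
the root spectrum), giving exact expected variance and e⁻¹ ACF decay at
the correlation length. Wear features are *subtractive only* — scratches
are Poisson-placed line segments with Gaussian cross-section, pits are
Gaussian depressions — because wear removes material; this keeps the
height-distribution skew physically negative under pitting. The default
diet-level texture map rises monotonically in background Sq
(0.15–0.40 µm), scratch depth (0.3–0.8 µm) and pit depth (0.3–0.9 µm)
with densities of order 10⁻³–10⁻⁴ features/µm², so "rougher with more
elasmobranch prey" holds by construction; these magnitudes were chosen
once as plausible for shark enamel fields of this size and are recorded
per surface in the truth table. Within-tooth repeats are disjoint crops of
one larger parent field, which makes their between-sample variance smaller
than between-specimen variance by construction — mirroring the subsidiary
hypothesis the real design tests. The unknown-diet specimen is generated
at diet level 1 (its truth is in the table, and the analysis treats it as
unknown).

What the generator does *not* emulate: enamel microstructure, instrument
noise spectra and focus-variation artefacts, non-stationary wear
gradients, curvature of real tooth facets beyond a quadratic form, and
any taxon-specific feature morphology. Passing the end-to-end tests
therefore demonstrates that the pipeline recovers designed statistical
structure from surfaces with realistic magnitudes — not that it would
classify real shark diets correctly.

# Problem sizes and numerical notes

The generator default is the full instrument field, 332 × 252 samples at
0.44 µm (≈146 × 111 µm). Cohort-level tests run at reduced fields (64 × 48
to 128 × 96 samples) and the acceptance script runs the full design at
full size plus 300 null tables and 25 recovery seeds; these sizes are the
package's choice of a thorough-but-quick desk scale. Analytic oracle
fixtures use ≥ 64 samples per sinusoid period so discrete moments match
continuous closed forms well inside 0.5%.

A power note on subsampled comparisons: with k = 6 against 6 and a 2-SD
designed shift, per-parameter recovery after B–H correction is ≈ 0.55 (a
noncentral-t calculation with the B–H-adaptive threshold; simulation
agrees), rising to ≈ 0.96 at 3 SD. Recovery expectations in the tests are
set from that calculation, and the "significant differences in every
repetition" property is exercised at an overwhelming effect size, where it
is actually implied by the design.

Other numerical choices: the `.sur` writer stores heights as int32 with a
power-of-two scale (exactly representable in the float32 header), so
round-trip error is bounded by the quantization step, range/2³¹; ASCII
formats round-trip exactly. Degenerate inputs — constant surfaces
(Ssk/Sku undefined), fewer than five summits, singleton groups, all-tied
covariates — warn and flag rather than fail, except where the result would
be meaningless (PCA on a constant parameter is an error naming it).

# Known limitations

- The spline filter is the non-robust characteristic; outlier-resistant
  filtration and multi-scale (bandpass ladder) decomposition are out of
  scope.
- Feature parameters follow the documented summit definitions above;
  other software lineages (EUR 15178N vs ISO Spd/Spc/S10z) will differ
  numerically even on identical surfaces.
- Tooth-within-specimen nesting is not modelled (no mixed-effects layer),
  matching the protocol this pipeline reproduces.
- The `.sur` reader supports the package's own documented single-object
  dialect, not every variant of the commercial format family.
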