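# dmta: dental microwear texture analysis of gridded tooth surfaces

Dental microwear texture analysis (DMTA) quantifies the sub-micrometre 3D
wear textures on tooth surfaces as a dietary proxy: what an animal ate
leaves a statistical signature in the roughness of its teeth. This package
implements the full DMTA pipeline for gridded height maps — such as the
~146 × 111 µm focus-variation microscope fields used in shark tooth studies
— from raw point clouds to a multivariate dietary discrimination. It is
aimed at palaeobiologists and surface metrologists who want a scriptable,
reproducible alternative to GUI metrology software, with every processing
decision logged and testable.

## What it computes

**Scale-limited roughness surfaces.** A raw height map is despiked
(deviations from the local 3×3 median beyond *k*·MAD are voided, default
*k* = 10), voids are restored by harmonic (Laplace) interpolation, gross
tooth form is removed by a least-squares bivariate polynomial of total
degree 2, and the surface is band-limited with an areal filter (spline
characteristic 1/(1 + (λc/λ)⁴), or an ISO 16610-61 Gaussian, both with 50%
amplitude transmission at the nesting index, default λc = 0.025 mm).

**ISO 25178-2 texture parameters.** The 23 parameters used in shark DMTA:
height moments (Sq, Sa, Ssk, Sku, Sp, Sv, Sz); areal material ratio
(Abbott–Firestone) quantities — volumes Vmp, Vmc, Vvc, Vvv and the core
family Sk, Spk, Svk, Smr1, Smr2 from the minimum-slope 40% secant; spatial
parameters Sal and Str from the FFT autocorrelation; hybrid parameters Sdq
and Sdr; and feature parameters Sds, Ssc, S5z from prominence-pruned
(Wolf-style) summits. Every parameter has an independent brute-force oracle
in the test suite.

**Dietary discrimination.** Per parameter: Bartlett and Brown–Forsythe
tests gate between classic and Welch one-way ANOVA (Satterthwaite df);
a Benjamini–Hochberg step-up controls the false discovery rate at 0.05
across the 23 tests; Tukey HSD (Tukey–Kramer for unequal n) locates the
pairwise differences; a PCA **on correlations** of the pairwise-differing
parameters summarizes the texture space; specimens of unknown diet are
projected into that space using the training standardization; Spearman rank
correlations relate PC1 to ordinal diet rank and body length; and a
subsampling scheme (k = 6 teeth, 10 repetitions) checks robustness to
single-tooth sampling.

**Synthetic cohorts.** A generator produces Gaussian-random-field enamel
backgrounds (spectral synthesis, Gaussian autocorrelation) with subtractive
scratch and pit features whose density and depth rise monotonically with an
ordinal diet level, in cohorts mirroring a real study design (6 aquarium
teeth; 3 wild specimens × 6 teeth; 8 within-tooth repeat fields; 6 teeth of
an unknown-diet specimen). The generating truth table is the oracle for all
end-to-end tests — no microscope data needed.

## Worked example

```r
library(dmta)

# one synthetic worn surface at the study field of view
m <- gaussian_random_field(332, 252, dx = 0.44, dy = 0.44,
                           sq = 0.3, corr_len = 2, seed = 7)
m <- add_scratches(m, density = 8e-4, depth = 0.45, width = 1.5,
                   orientation_conc = 2, seed = 8)
m <- add_pits(m, density = 4.5e-4, depth = 0.5, radius = 1.2, seed = 9)

surf <- standard_chain(m)   # despike -> restore -> level -> filter
rec  <- compute_all(surf)   # the 23 ISO parameters
round(unlist(rec[1, c("Sq","Sa","Ssk","Sku","Sz","Sds","Sal","Str","Sdq","Sdr")]), 4)
#>      Sq      Sa     Ssk     Sku      Sz     Sds     Sal     Str     Sdq     Sdr
#>  0.2873  0.2290 -0.0985  3.0634  2.4576  0.0244  2.1824  0.9482  0.2932  4.1305
```

Sq = 0.287 µm is the RMS roughness after scale-limiting; the slightly
negative skew (Ssk = −0.10) reflects the subtractive pits and scratches;
Sds ≈ 0.024 summits/µm² and Sal ≈ 2.2 µm describe the density and lateral
scale of the texture; Str ≈ 0.95 says the surface is nearly isotropic
despite the oriented scratches (the background dominates).

A whole cohort and its analysis:

```r
des <- cohort_design(seed = 42)        # study-mirror design, 38 surfaces
ch  <- make_cohort(des)
# ... standard_chain() + compute_all() per surface -> specimen_table ...
rep <- full_analysis(tab, pipeline_config(stats = list(
         within_tooth_label = "2a", unknown_label = "5")))
rep$anova                 # 23-row ANOVA table with Welch flags and B-H column
rep$selected_parameters   # parameters with significant pairwise differences
rep$pca$explained_pct[1]  # PC1 % variance
rep$projections           # unknown specimen's records in the training PCA
```

The published worked example ships with the package:
`bh_adjust(published_anova_table()$p, fdr = 0.05)` flags exactly four
parameters — Sds, Sal, Sdq and Sdr — and
`pairwise_differing_parameters(published_pairwise_sets())` returns the
14-parameter union used for the PCA.

A command-line entry point wrapping the same functions is installed at
`inst/cli/dmta.R` with subcommands `simulate`, `preprocess`, `params` and
`analyze`.

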