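---
title: "Methods: simulating and analysing image-based abyssal megafauna surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing image-based abyssal megafauna surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `benthosurvey`. The package couples an analysis chain for
photographic megafauna surveys with a synthetic-data generator whose
defaults encode one concrete study setting: a horst-and-graben abyssal
landscape at 3950–4250 m depth with three landscape-type study areas
(Flat, Ridge, Trough), polymetallic-nodule cover, and a long-tailed
megafauna community sampled by zig-zag AUV photo-transects.

## The synthetic-data generator

### Bathymetry

`generate_bathymetry()` builds a depth raster as a base depth (4100 m)
minus a sinusoid across easting with ridge-to-trough wavelength
`ridge_spacing` (default 5 km, constrained to the 1–10 km spacing typical
of abyssal horst-and-graben terrain), a slow phase drift with latitude that
crenulates the crest lines, and smooth Gaussian noise (`noise_sd` 5 m,
correlation length 500 m). The default relief amplitude is 75 m: large
enough that ridge crests and trough floors fall into the BPI threshold
boxes used for classification, while keeping all depths inside the
configured 3950–4250 m range (the output is clamped to that interval as a
guard). A sinusoid is the simplest stationary model with a controllable
dominant wavelength; it makes the label-recovery property (cells under
crests classify as ridge) testable by construction.

### Nodule cover

`generate_nodule_field()` realises percent cover as a Gaussian random
field squashed through a logit link: white noise is smoothed to the patch
correlation length (default 50 m — "patchiness at tens of metres"), scaled
to `cover_logit_sd` (default 1.0) and shifted so the *realised* field mean
equals the requested mean cover exactly (the shift is solved by `uniroot`
on the realised field, so the calibration holds for every seed). Per-image
nodule draws are Poisson in number with expectation
`cover × footprint / mean nodule area`, with i.i.d. lognormal areas
(`meanlog 0.616`, `sdlog 0.775` cm²). Those lognormal parameters are the
unique solution to two conditions: mean nodule area 2.5 cm² and 90% of
nodules below 5 cm². Area means default to 10.1 / 6.3 / 3.8 % cover for
Flat / Ridge / Trough.

### Community

`generate_community()` realises morphospecies pools:

- **Abundance backbone.** Pool relative abundances are evenly spaced
  quantiles of Fisher's log-series. Quantiles, rather than random draws,
  keep the pool shape identical across seeds and avoid the occasional
  enormous draw that would swamp the normalised weights; stochasticity
  enters through area-level turnover and Poisson placement.
- **Calibration.** The observed community targeted is ~129 metazoan
  morphospecies at a survey effort of ~6,700 individuals (3 areas × 4
  units × 1320 m² at densities 0.49/0.47/0.32 ind m⁻²), with about a third
  of observed taxa rare (≤3 records). Under log-series + Poisson sampling
  a sizeable fraction of pool taxa escape detection, so the pool must be
  larger than the observed richness: a scan over pool size and log-series
  `x` fixed the defaults at `n_species = 190`, `x = 0.9995`, which yield
  ~129 observed morphospecies and a rare fraction of ~0.32 across seeds.
- **Turnover.** Per-area relative abundances are the pool weights times
  lognormal multiplicative noise (`area_turnover_sd = 0.3`, calibrated so
  a 3-area, 4-replicate survey shows a between-area PERMANOVA R² near 0.4
  — the landscape-scale separation strength the generator emulates — while
  leaving the rare-taxa fraction inside its target band); this produces
  the between-area compositional differences that the PERMANOVA/SIMPER
  stage detects, and species-level presence patterns (most taxa shared, a
  tail of single-area rarities).
- **Guilds and habits.** Guild labels (SF/DF/PS) are allocated over
  morphospecies by a deterministic greedy pass in decreasing expected
  survey abundance, so the *individual-weighted* guild mix tracks the
  78/16/4% suspension-feeder/deposit-feeder/predator-scavenger target
  closely in every realisation (random per-species labels would let the
  dominant species swing the mix by ±10%). Life habit is
  nodule-attached (NA) with probability 0.75 for suspension feeders and
  0.3 otherwise; individuals of NA taxa are flagged attached with
  probability 0.8.
- **Xenophyophores.** A separate 23-morphospecies pool at 2.22/4.09/1.33
  tests m⁻², with one dominant morphospecies fixed at 1.51/3.27/0.85
  ind m⁻² (so it alone constitutes >70% of all Ridge megafauna, and tests
  overall outnumber metazoans about six-fold). Xenophyophores carry no
  feeding-guild label and are excluded from metazoan metrics by default;
  `abundance_table(taxon = "both")` gives the joint mode.
- **Body sizes.** Individual length is `10 mm + lognormal`, with a
  per-morphospecies mean (`meanlog ~ N(2.6, 0.45)`, within-species
  `sdlog 0.4`) and width a Beta(2,3) fraction of length. These values give
  a mean individual biovolume near 3 ml, hence biomass densities of
  1.5–3 g fwwt m⁻² at the default densities — the right order for abyssal
  megafauna — with the heavy upper tail that makes biomass the
  slowest-stabilizing parameter.

Individuals are placed into images as independent Poisson counts with mean
`density × footprint`, i.e. a homogeneous Poisson process per area. The
expected density therefore equals the spec density exactly, which the
recovery tests verify within Monte-Carlo error.

### Survey

`simulate_survey()` lays a zig-zag of `units_per_area` straight segments
(default 40) with a random start, alternating between two east–west
lines; each segment is one sampling unit of length 1700 m with photographs
every 1.02 m (1.2 m s⁻¹ × 0.85 s). Altitude is truncated-normal (mean 3 m,
sd 0.4 m, physical limits 1.5–4.5 m) and the footprint follows the exact
`1.71 m² × (altitude/3)²` law. `standardize_units()` then applies the
image-selection chain: junction images (within 10 m of segment ends)
dropped, every second image dropped (overlap control), altitudes outside
2–4 m dropped, and a random permutation of the survivors cut at the first
prefix whose summed footprint enters 1321–1324 m²; finally 4 units per
area are selected by simple random sampling (how the original 4-of-40
selection was drawn is not stated anywhere we know of; simple random
sampling is the neutral choice). Units that cannot reach the window are
excluded with a warning. With these defaults a unit retains ~700–780
images. Because a cumulative-footprint step can (rarely) jump over the
3 m²-wide acceptance window, the permutation is retried up to 25 times
before exclusion.

The raw 120-unit survey generates ~200,000 image positions in about a
second; `run_pipeline()` defers specimen/nodule annotation
(`populate = FALSE`, then `populate_images()` after standardization) so
only the ~9,000 analysed images are annotated — mirroring the fact that
annotation effort is only spent on selected images.

### Sediment

No operation of the analysis chain generates its own sediment input, so a
small `generate_sediment()` closes the loop: per-area lognormal variation
around mean grain size 8.1/9.5/9.2 µm, TOC 0.42/0.41/0.44 %dw, CaCO₃
0.33/0.48/0.36 %dw and molar C:N 4.0/3.8/4.1, with class fractions laid
over six geometric size bins. TC and TN are back-computed from TOC, CaCO₃
and C:N, so `carbonate_cn()` recovers the targets.

## Terrain derivatives

BPI is computed in raw metres (elevation minus annulus mean, annulus
membership by cell-centre distance, FFT convolution with a mask for
nodata/edge awareness so edge cells use the available annulus cells). The
classification thresholds (ridge 50–100, trough −100 to −50, flat −50 to
50 m, with TRI caps 150/150/50 m) are treated as metres; a
`standardize = TRUE` flag provides the integer z-score GIS convention for
users whose thresholds are standardized — whether the original mapping
standardized first is not stated, so raw metres is the default and both
modes exist. TRI is the mean absolute elevation difference within the
radius (an RMS variant sits behind `variant = "rms"`; the index family has
several variants and only the radius is fixed by the setting emulated).
Boundary ties at |BPI| = 50 go to flat, making classification
deterministic; the flat box is applied last and wins.

## Diversity and rarefaction

Hill numbers are computed from first principles (`S`, `exp H′`, `1/D`);
the suite checks the ordering `S ≥ exp H′ ≥ 1/D ≥ 1` on 10⁴ random count
vectors and the values against vegan. Rarefaction interpolation uses the
exact hypergeometric expectation, written through `lgamma` ratios so
non-integer efforts (the area axis) are admitted and large binomial
coefficients do not overflow; at integer efforts it agrees with exhaustive
subset enumeration to 10⁻⁹. Extrapolation uses the Chao2 (sample mode) or
Chao1 (individual mode) estimate of undetected richness with the standard
exponential approach to the asymptote. Confidence intervals: interpolated
points use the analytic unconditional variance
`σ²(t) = Σᵢ(1−αᵢₜ)² − S(t)²/Ŝ` (non-negative by Cauchy–Schwarz, zero at
`t = 0`, positive at full effort when undetected species remain); no
settled analytic form exists for the extrapolated segment, so its band
comes from a percentile bootstrap over resampled units (or individuals),
recentred on the point estimate. Diversity rarefaction (`exp H′`, `1/D`)
is bootstrap-with-replacement with percentile intervals, 1000 replicates
by default.

## Composition analysis

All multivariate machinery is implemented directly (vegan serves only as
an independent cross-check in the tests): Bray–Curtis on square-root
*densities* (counts/area — not raw counts, since unit areas differ within
1321–1324 m²); PERMANOVA sums of squares from squared dissimilarities with
free permutation of unit labels, switching to complete enumeration of
label arrangements whenever that is no more work than the requested
permutation count (p is then exact — with 3 groups of 4 units there are
34,650 arrangements); pairwise follow-ups with Holm adjustment reported
alongside raw p; SIMPER as the exact per-species decomposition of each
cross-group pair's dissimilarity (the contributions sum to the mean
between-group dissimilarity by construction); Spearman's rho on mid-ranks
with an exact permutation p for n ≤ 7.

The nMDS minimises Kruskal stress-1 by alternating isotonic regression
(`stats::isoreg`, primary/"weak" tie treatment: tied dissimilarities are
ordered by current configuration distance, so ties carry no penalty) with
Guttman-transform updates and step halving, which guarantees the recorded
stress trace never increases; the best of `restarts` starts is kept, the
first start being classical scaling. On metric inputs the stress reaches
~0; with few points a perfect monotone embedding (stress 0) is a
legitimate optimum and is returned as such.

## Sampling-effort evaluation

`resample_parameter()` draws image subsets of increasing size from an
area's pooled images — with replacement for bootstrap parameters (density,
biomass, `exp H′`, `1/D`), without replacement for richness rarefaction —
and records the centre statistic, CV (= sd/mean over replicate values —
whether the original evaluations took CVs over replicate values or over
their means is not determinable, so the replicate-value convention is
used and stated here), percentile intervals, and the mean seabed area and
individuals per subset. The centre is the mean except for biomass, where
the median is used (the heavy biovolume tail makes the mean unstable).
Draws on which the parameter is undefined (e.g. diversity of an empty
subset) are redone up to a retry cap and flagged. At the full pool without
replacement every draw is the pool, so the centre equals the pooled value
and the CV is 0 — an endpoint identity the tests assert. Autosimilarity
draws two *disjoint* groups per replicate and reports
`100 × (1 − Bray–Curtis)` between their pooled square-root density
vectors.

Stabilization ("accuracy") needs an explicit criterion: the reported
minimum adequate size is the smallest grid size from which the centre
stays within ±5% of the terminal (largest-size) centre over at least 3
consecutive grid points. Both the tolerance and the window are arguments
and are echoed in the report, since conclusions of the form "parameter X
needs >N individuals" depend on them. The size grid is geometric in image
count (16 points from 10 images to the pool) because precision improves
as the square root of effort.

## Group comparisons

Per-metric GLM fitting (quasi-Poisson for counts, beta regression for
proportions, Tukey contrasts) is deliberately not reproduced;
`group_compare()` provides permutation one-way F tests with pairwise
mean-difference permutation tests (Holm-adjusted) as a distribution-free
replacement, and is labelled as such in the outputs. With 3 groups of 4
units the tests enumerate all label arrangements, so p-values are exact.

## Calibration and correctness checks

The suite's statistical checks run at reduced but adequate sizes, chosen
for stable verdicts on one CPU: type-I error of the permutation tests over
1000 null datasets of 10 units (the 2×5 design keeps the exact-test
granularity fine enough that the nominal 0.05 level is attainable);
CV-vs-size log-log slope on 200 replicate draws per size (theory: −1/2 for
a homogeneous Poisson community); effort curves at 200 replicates instead
of the 1000 used for production runs; density recovery over 10⁵ m²
simulated per area. `scripts/acceptance.R` runs the full 3 × 40-unit
design and writes all headline quantities as JSON.

## What the generator does and does not emulate

Emulated: depth range and ridge spacing; landscape-type contrasts in
density, nodule cover and hard-substrata; the long-tailed abundance
structure and rare-taxa fraction; guild and life-habit composition; the
altitude/footprint law and the full image-selection chain; nodule size
distribution and patchiness; a dominant xenophyophore.

Not emulated: spatial autocorrelation of the community within areas
(placement is homogeneous Poisson given the area, so design-based
autocorrelation mitigation cannot be studied); coupling of nodule-attached
fauna intensity to local nodule patches (attachment is a per-specimen
flag, not a spatial co-location); morphospecies identification error;
image overlap and double counting (the every-second-image discard is
applied to non-overlapping synthetic images); photorealistic imagery or
nodule delineation (the generator emits per-nodule areas directly,
emulating the delineation output contract). Passing tests therefore
demonstrate correctness of the estimators and the qualitative
effort-adequacy findings under idealised sampling, not robustness to
annotation error or fine-scale spatial structure in real imagery.

## Known limitations

- PERMANOVA on 4 replicate units per group has limited permutation
  resolution; exact enumeration is used automatically but small-n p-values
  remain coarse.
- The unconditional-variance interval is analytic only on the interpolated
  segment; the extrapolated band is bootstrap-based and ignores
  uncertainty in the Chao correction's functional form.
- The logit-Gaussian cover field matches mean and correlation length but
  not higher moments of real nodule mosaics; unit-level cover spread is
  realistic in magnitude but not calibrated.
- Biomass uses a single ellipsoid shape factor (hook provided per
  morphospecies) — colonial and encrusting forms are poorly served by any
  two-measurement volumetric proxy.
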