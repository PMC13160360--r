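---
title: "frontscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{frontscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frontscan)
```

frontscan analyses multifrequency echosounder backscatter together with
hydrography across an ocean thermal front: it cleans volume-backscattering
(Sv) grids, classifies integration cells into fish and macrozooplankton by
their frequency response, integrates abundance (NASC) along the transect,
locates the front from CTD sections and SST series, classifies water
masses, renders three-frequency colour composites, and relates abundance
to frontal structure statistically. This vignette documents the models,
the tunable parameters, the synthetic-data generator the test suite rests
on, and the design decisions taken where the procedure left genuine
freedom.

## The acoustic model and cleaning chain

A scientific echosounder records Sv (dB re 1 m$^{-1}$) per ping and depth
bin at each frequency (here 18, 38 and 120 kHz). The package's cleaning
chain mirrors standard post-processing practice and is *order-enforced*:
each operation stamps a processing stage onto the grid, and applying an
earlier-stage operation to a grid that already passed a later stage is a
contract error. The order is:

1. **Resampling** (`resampleToReference`) — all frequencies onto the
   38 kHz transducer's ping clock (nearest ping within a 2 s tolerance)
   and depth bins (linear interpolation in the linear power domain).
2. **Surface exclusion** (`excludeSurface`) — everything above the
   transducer near field, $\pi a^2 / \lambda$ for a circular transducer of
   active radius $a$, plus a 2 m buffer. With the default $a = 0.2$ m this
   removes roughly the top 12 m at 120 kHz, matching what near-field
   exclusion typically costs a hull-mounted survey.
3. **Bottom exclusion** (`detectAndExcludeBottom`) — per ping, the
   shallowest sample below a minimum depth with Sv at or above $-35$ dB is
   the seabed; everything from 1.5 m above it downward is the bottom dead
   zone and is masked. Manual per-ping overrides are first-class, because
   threshold detectors do fail on real seabeds.
4. **Background-noise removal** (`removeBackgroundNoise`) — the
   noise-at-the-receiver level is estimated from the data: power with the
   time-varied gain removed, $P = S_v - 20\log_{10} r - 2\alpha r$, is
   averaged (linear domain) in cells of 40 pings × 10 samples, and each
   ping block's noise is the minimum cell mean over depth, capped at a
   maximum. The noise is re-amplified with the TVG, subtracted in the
   linear domain, and samples with corrected SNR below 10 dB are masked.
   Because the synthetic generator uses exactly this additive model, noise
   subtraction is an *exact inverse* on noiseless fixtures — which is what
   makes the recovery tests sharp.
5. **Impulse-noise removal** (`removeImpulseNoise`) — after vertical
   smoothing, a sample is impulse noise when it exceeds the sample at the
   same depth $n$ pings before *and* after by more than 10 dB; flagged
   samples are replaced by the linear mean of the two comparison samples.
   Edge pings are compared one-sided. Two adjacent contaminated pings at
   context 1 shield each other — a documented limitation of the two-sided
   rule; the 5-sample × 5-ping setting (context 2) resolves pairs.
6. **Smoothing** (`smoothSv`) — 5 samples × 5 pings moving mean in the
   linear domain over unmasked samples; masked neighbours leave the
   denominator, and fully-masked windows stay masked.
7. **Minimum-Sv threshold** (`applySvThreshold`) — samples below
   $-80$ dB re 1 m$^{-1}$ are masked as too weak to originate from
   macrozooplankton or nekton. The boundary is kept: removal is strict
   `<`, so a sample at exactly $-80$ survives. The threshold is applied
   after smoothing, i.e. last in the chain.

All dB averaging anywhere in the package happens in the linear domain;
depth bins are half-open $[\mathrm{top}, \mathrm{bottom})$ with depth
positive down, and masks are monotone (no stage ever unmasks a sample).

Absorption coefficients come from the Francois–Garrison formulation
(boric-acid, magnesium-sulfate and pure-water terms), hand-implemented
because no installed package provides it; it is validated against an
independent term-by-term evaluation to four significant figures.

## Echo integration and classification

`computeMvbs` grids cleaned Sv into half-open integration cells (defaults:
3 m × 0.25 nmi for statistics, 1 m × 0.1 nmi for composites) as
$\mathrm{MVBS} = 10\log_{10}(\overline{10^{S_v/10}})$ over unmasked
samples. A cell is defined only when at least 30% of its samples are
unmasked; undefined cells are NA — never 0, which would be a $-\infty$ dB
observation, not missing data. Trailing partial cells are kept and
flagged so that NASC additivity holds over the whole transect.

`classifyCells` uses the dB difference
$\Delta = \mathrm{MVBS}_{120} - \mathrm{MVBS}_{38}$ in the upper 150 m
(the 120 kHz observational range limit): $\Delta \le 5$ dB is FISH,
$\Delta > 10$ dB is MACROZOOPLANKTON, the gap in between stays
UNCLASSIFIED, and cells without a defined MVBS are EXCLUDED. Below 150 m
any defined 38 kHz signal is assumed to be fish. Boundary semantics were
an open choice: "5 dB as the upper limit" is read inclusive and "over
10 dB" strict; both thresholds are parameters. Cells straddling 150 m are
assigned by their top edge (deterministic under half-open bins).
UNCLASSIFIED cells contribute to neither abundance series — the
conservative choice, since assigning them to either class would
fabricate signal.

`integrateNasc` computes the nautical area scattering coefficient
$\mathrm{NASC} = 4\pi \cdot 1852^2 \sum_{\mathrm{cells}} 10^{\mathrm{MVBS}/10}
\cdot \mathrm{thickness}$ (m$^2$ nmi$^{-2}$) per distance bin (default
0.1 nmi, configurable to 0.25 — both resolutions appear in survey
practice, so bin width is a parameter rather than a constant). Fish NASC
integrates the 38 kHz channel and macrozooplankton NASC the 120 kHz
channel. Grid columns are apportioned to bins by overlap length, making
the distance-weighted total invariant to bin-size changes.

## Hydrography

Water masses are classified by rules on absolute salinity, conservative
temperature and density: Atlantic ($S_A \ge 35.06$, $\Theta > 2$),
Modified Atlantic ($S_A \ge 35.06$, $0 < \Theta \le 2$), Warm Polar
($S_A < 35.06$, $\Theta > 0$); for $\Theta \le 0$: Polar when
$\sigma_\theta \le 27.97$, otherwise Intermediate ($\Theta > -1.1$) or
Cold Barents Sea Dense Water ($\Theta \le -1.1$). As printed, the
cold-water rows overlap; resolving density first and then temperature
makes the classes mutually exclusive and the classifier total, which a
test verifies against an independently coded rule table on a dense grid.

The subsurface front is located by averaging temperature over the
45–55 m band (below surface mixing), interpolating the band mean onto a
0.01° latitude grid, and taking the midpoint of the interval with the
largest absolute change; ties break toward the lowest latitude
(deterministic; real sections essentially never tie). The same
maximum-gradient rule applied to an SST series gives the surface front,
returning "absent" when no gradient reaches a configurable minimum
(0.5 °C per degree by default) — the summer situation of continuously
warm, weakly graded surface water. Whether the band average should use
every raw sample or bin means is unspecified in the procedure; bin means
are used. Distances to frontal features are signed haversine distances
(Earth radius 6371 km), positive north, because monotone covariates are
required downstream; a flag yields unsigned distances.

The maximum-gradient estimator has a resolution limit worth stating: for
wide fronts the gradient maximum flattens, and sensor noise moves the
argmax. With the generator's sensor noise (sd 0.002 °C, the level of
binned pumped-CTD data) recovery within one 0.01° grid step holds across
transition widths up to about 0.05°; beyond that the estimator degrades
gracefully but misses the 0.01° target increasingly often. Recovery
tests therefore sample widths in [0.02°, 0.05°].

Brunt–Väisälä stratification is
$N^2 = (g/\rho_0)\,\Delta\sigma_\theta/\Delta z$ at layer midpoints, with
$g = 9.81$ m s$^{-2}$ and $\rho_0 = 1025$ kg m$^{-3}$ exposed as
parameters (the upstream toolboxes do not print their constants).
Stability *classes* have no defaults: binning thresholds are
survey-specific configuration (`stabilityClasses`).

CTD inter-instrument calibration (`calibrateOffsets`) measures constant
offsets as mean(reference − target) over a depth window that must lie in
a stable layer — the window is refused when the reference's mean
|dΘ/dz| exceeds a threshold (default 0.02 °C m$^{-1}$), since a gradient
plus any depth mismatch masquerades as a sensor offset.

TEOS-10 conversion from practical salinity and in-situ temperature is
out of scope: inputs are accepted as already-converted conservative
temperature and absolute salinity. Where density is absent the package
offers `linearSigmaTheta`, a first-order expansion around cold Arctic
shelf water ($\Theta = 0$, $S_A = 34.8$, $\sigma_\theta = 27.95$); it is
a linearization — adequate for the simulator and for rule-based
classification near those conditions, not a general equation of state.

## Composites

Each frequency's MVBS is rescaled linearly onto the 256-level colour
scale, $255\,(x - \min)/(\max - \min)$ with the per-frequency transect
min/max (computed after masking) as the reference, assigned to red
(18 kHz), green (38 kHz) and blue (120 kHz), gamma-normalized with
$\gamma = 2$, optionally brightened (default factor 1, a no-op: the
appropriate brightening is display-dependent), and clipped to [0, 255].
Missing cells render black. Ship back-tracking segments are removable by
distance-cell exclusion before rescaling.

## Ecological statistics

Trawl catches are standardized by filtered volume (net mouth area ×
distance towed). Shannon–Wiener diversity uses natural logarithms — the
magnitudes this produces on realistic richness match reported values of
the index in this setting — and Simpson diversity is reported as
$1 - \sum p^2$ with the complement available. A flag excludes a pooled
taxon (e.g. a mixed-mesozooplankton fraction that is weighed but not
enumerated) from the indices while keeping its biomass in community
outputs.

Correlations are Kendall's $\tau_b$ (tie-corrected; tau-b is chosen over
tau-a because NASC series contain ties), with p-values from the normal
approximation and, for small untied samples, the exact null
distribution — equivalent to exhaustive permutation, which the tests
verify at n = 6. Multiple testing is controlled by Benjamini–Hochberg
step-up adjustment across the whole correlation table.

Community structure is tested with ANOSIM on Bray–Curtis dissimilarities
of square-root-transformed relative abundance (the square root
down-weights the few dominant taxa). ANOSIM is implemented in the
package: $R = (\bar r_B - \bar r_W)/(M/2)$ on tied-averaged ranks of all
pairwise dissimilarities, with significance from seeded label
permutation, $p = (1 + \#\{R^* \ge R\})/(1 + n_\mathrm{perm})$, 999
permutations by default (the permutation count is a parameter; no
canonical value exists). A full-enumeration mode covers small instances
and serves as its own oracle; the reference implementation in vegan is
used as an independent cross-check in the tests, never as the
implementation. NMDS, PERMANOVA and PERMDISP are deliberately not
reimplemented — vegan provides them to users who want them.

## The synthetic-data generator

Every input the pipeline consumes can be generated with planted ground
truth (`simulationConfig`, `simulateEchograms`, `simulateCtdTransect`,
`simulateSstSeries`, `simulateTrawlCatches`). The reference scene is a
600-ping northbound transect at 0.1 nmi spacing (76.7–77.7° N along
29.5° E), 250 m of water over a 230 m seabed, and a logistic thermal
front at 77.2° N of width 0.03° separating 3.2 °C / 35.2 g kg$^{-1}$
southern water from −1.8 °C / 34.3 g kg$^{-1}$ northern water — the
geometry and temperature contrast of a high-latitude frontal survey at
desk scale. Planted targets are rectangles with a peak 38 kHz Sv and
per-frequency offsets: fish schools with $\Delta_{120-38} \le 5$ dB and a
macrozooplankton layer with $\Delta_{120-38} = 12$ dB north of the front.
Noise is additive in the linear domain,
$S_v^{noise}(r) = N_0 + 20\log_{10} r + 2\alpha r$, with floors
(−135/−132/−130 dB at 18/38/120 kHz) set roughly 30 dB below the planted
signals so that the SNR-conditional recovery guarantees are exercised
rather than trivialized; whole pings at seeded indices gain a +20 dB
impulse; Gaussian dB jitter (sd 1 dB) stands in for sample-level
variability.

One master seed drives everything; each simulator derives its own
sub-stream, so adding a simulator call never shifts another's output,
and target geometry is configuration, not randomness.

What the generator deliberately does **not** emulate: species-specific
target strength, Rayleigh/Rice amplitude statistics of real aggregations
(the 1 dB jitter is far tamer), beam geometry, vessel motion, and patchy
real-world plankton morphology. Passing recovery tests therefore
demonstrates that the processing chain inverts its own stated model and
respects its contracts — not that survey data would classify with the
same accuracy. That calibration requires real calibrated recordings,
which are out of scope here.

Distributional parameters for backscatter variability are not prescribed
anywhere in the underlying procedure; the simulator's defaults are
documented choices, stated here and in `?simulationConfig`, and are not
claimed to match any particular survey.

## Numerical and degenerate-input choices

* Undefined MVBS is NA, never 0; empty NASC selections are 0 (a valid
  observation of absence).
* `-Inf` Sv is a legitimate value (zero backscatter), distinct from
  masked.
* Exact CSV round-trips serialize doubles with 17 significant digits.
* Maximum-gradient ties break toward the lowest latitude; the
  straddling-cell rule and half-open bins remove all other boundary
  ambiguity.
* Constant vectors leave Kendall's τ undefined (NA with a warning)
  rather than 0.
* Degenerate transects (single latitude), zero-volume tows, even
  smoothing windows, and out-of-range frequencies are rejected loudly.

## Problem sizes used by the tests

The suite runs the full reference scene (600 × 250 samples × 3
frequencies) through the entire chain, 100-seed front-recovery sweeps,
a 10⁵-point water-mass oracle grid, and 500-replicate ANOSIM null
calibration; the whole suite completes in about a minute on one core.
These sizes were chosen to make the statistical checks sharp (e.g. a
KS test on 500 null p-values) while staying desk-scale.

## Known limitations

* The linearized density anomaly drifts from TEOS-10 away from cold,
  moderately saline water; supply real $\sigma_\theta$ when you have it.
* The bottom detector is a threshold crossing; side-lobe echoes and
  steep slopes need the manual override path.
* The impulse filter cannot flag runs of contaminated pings longer than
  its context (inherent to the two-sided comparison).
* Front localization assumes an essentially meridional transect; no 2-D
  front surface is attempted.
* NASC from the 120 kHz channel stops at 150 m by construction; deep
  macrozooplankton is invisible to the acoustic series (net catches are
  the complementary observation).
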