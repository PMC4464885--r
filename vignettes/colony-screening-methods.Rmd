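---
title: "Methods: simulating and analyzing FRET biosensor colony screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing FRET biosensor colony screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screening problem

Ratiometric FRET biosensors read out a conformational change as the ratio
`R = I_acceptor / I_donor` of acceptor to donor emission under donor
excitation. Directed optimization of such sensors diversifies the linkers
between the ligand-binding domain and the fluorophores — a handful of
NNB-randomized codons already spans `20^4 = 160,000` amino-acid variants —
and then needs a way to measure, for hundreds of thousands of variants,
the basal ratio `R0` (ligand-free) and the relative ratio change
`ΔR/R = (R_max − R0)/R0` after ligand saturation. Plating transformed
*E. coli* at ~700–800 colonies per 10 cm plate, blotting onto white paper,
imaging under a wide-field CCD, spraying a permeabilization/ligand
solution, and imaging the response gives exactly that: each colony is one
variant, and a three-channel time-lapse
(donor-ex/donor-em, donor-ex/acceptor-em, acceptor-ex/acceptor-em)
contains everything needed to rank the library.

`fretscreen` implements the computational half of such a screen — colony
identification, per-colony ratio time series, scoring, pick selection and
spatial quality control — together with a ground-truthed synthetic plate
simulator that stands in for the camera rig, so every analysis stage can
be validated against known truth without an instrument.

## The forward model of the simulator

For each colony `i` at position `x_i` the expected (noise-free) channel
means obey

```
DD_i(t) = b_i                                   (donor ex / donor em)
DA_i(t) = b_i R0_i (1 + dRRmax_i d(x_i) s(t))   (donor ex / acceptor em)
AA_i(t) = b_i g_AA                              (acceptor ex / acceptor em)
```

so that `DA/DD = R(t) = R0 (1 + ΔR/R_max · d · s(t))`. Here `b_i` is the
colony's expected photon count per pixel at its center, `d(x)` in `[0, 1]`
is the spray deposition field, and `s(t) = 1 − exp(−(t − t_app)/τ)` is a
saturating-exponential response after the application frame (the
experimental traces plateau; no functional form is published, so the
simplest saturating kinetic is used). The direct-acceptor channel `AA` is
FRET-independent; an optional artifact mode multiplies both
acceptor-emission channels by `1 + a·s(t)`, emulating pH-driven acceptor
brightening, which is exactly the failure mode the `AA` channel is used
to flag.

Colonies are flat-top disks with a Gaussian-smoothed rim (`σ_rim = 1` px);
colony morphology beyond that is not modelled. Pixels receive Poisson
shot noise on the expected count, additive Gaussian read noise
(SD 3 counts), and are quantized to nonnegative integers (CCD counts).
Background is a constant autofluorescence level — 20 counts/px on white
paper, 60 plus low-frequency mottle on agar, the direction fixed by the
observation that blotting paper reduces background — under a mild
radially symmetric vignette (≥ 0.92 at the corners, "only a minor
decrease at the edges").

Three deposition models reproduce the documented spraying regimes:
`uniform` (`d ≡ 1`), `gun` (smooth radial decline
`d(r) = 1 − g (r/r_plate)^p`, default `g = 0.5, p = 1` — the improved
spray-gun protocol aimed at the plate center), and `bottle` (the radial
term times a patchy log-normal random field, default log-SD 0.5 at a
30 px correlation length — uneven hand spraying). The defaults are
calibrated qualitatively: bottle plates must show distinctly higher
spatial CV of ΔR/R than gun plates, mirroring the published 67% vs 37%
comparison; the exact CV values are properties of unshared wet-lab data
and are not reproduction targets.

### Study conditions (generator defaults)

Chosen once, as the conditions all tests and studies run under:

| parameter | default | rationale |
|---|---|---|
| colonies / plate | 750 | the documented target density |
| image / plate radius | 840 px / 395 px | keeps ~0.4 packing density at 18 px separation |
| colony radius | 3.5–5 px | dense plate, colonies distinguishable |
| min separation | 18 px | ≥ 3 maximal radii; thresholded rims cannot merge |
| `R0` library | LogNormal(log 0.95, 0.2) | TN-XXL-like prototype, moderate spread |
| `ΔR/R_max` library | LogNormal(log 1.0, 0.3) | moderate-diversity single-round library; calibrated so a 3x-median variant is a near-certain top-2% pick (the screen's design premise) |
| brightness | LogNormal(log 300, 0.2) photons/px | comfortable CCD budget at 4 s exposure |
| frames | 16 × 30 s, application at frame 4, τ = 30 s | baseline ≥ 4 frames; response window ≥ 9 τ after application |

Absolute photon budgets are conventions (no exposure calibration is
published beyond camera settings); what matters for validity is that the
relative error structure matches: at these defaults the per-colony R0
standard error is ~0.5% and the ΔR/R error ~1–2%, small against the
30% library spread, which is what makes a top-2% screen meaningful.
Replicate single-sensor plates (a `sdlog = 0` library) emulate the
published variability experiments.

What the simulator does *not* emulate: optical PSF blur and
bleed-through between channels (defaults 0, configurable), colony growth
during acquisition, paper-edge debris and particles (the published
outlier source), photobleaching, and day-to-day batch effects. Passing
tests therefore demonstrate correctness of the estimators against the
stated forward model, not robustness to every real-plate artifact.

## Colony identification

Detection runs on the first direct-acceptor frame, because that channel
is FRET-independent and bright regardless of a sensor's ratio state. The
intensity threshold is `center + 3·spread`. The classical choice computes
mean and SD over all pixels ("plain" mode); on a plate where colonies
cover ~6% of pixels that inflates both statistics, so the default
"robust" mode uses the median and the normal-consistent MAD
(`1.4826·MAD`), which is what `3σ of pixel intensity` should mean on a
background-dominated but colony-contaminated image. Both modes are
provided; neither is claimed to be what the original instrument software
computed. A constant image (MAD = 0) falls back to plain mode with a
warning.

The binary mask is cleaned by erosion (disk radius 1) followed by
morphological opening (disk radius 2). Both are implemented as exact
Euclidean-disk operations on the distance transform: erosion keeps a
pixel iff its distance to the nearest background pixel exceeds the
radius. Connected components (8-connectivity by default) become
candidate colonies; components below 20 px or above 10× the median
component area are discarded (debris and merged clumps), and components
intersecting a 5 px border frame are flagged `touches_border` and
excluded from ranking by default. Labels are renumbered by descending
area with centroid-based tie-breaks, making label order deterministic.
Touching colonies are *not* split: at the default separation the
simulator cannot produce merged pairs, and on real plates the plating
density is chosen so colonies stay distinguishable.

## Ratio quantification

Per colony, channel and frame the estimator is the mean over the
colony's labeled pixels minus a background estimate, and the ratio trace
is the ratio of the corrected means (not the mean of pixelwise ratios,
which is biased at low counts). The default background is the median of
a local annulus (1 px gap, 4 px wide, other colonies excluded): a global
per-frame median is also available, but under a multiplicative vignette
a single global value under-subtracts central colonies and
over-subtracts peripheral ones, which biases noise-free ratios by
several tenths of a percent — enough to violate the package's own
noise-free recovery contract. The local annulus tracks any
slowly-varying multiplicative field and makes background handling exact
to well below 0.1%. Whether the original pipeline background-subtracted
before ratioing is not documented; this default is a convention of this
package.

`R0` is the mean ratio over the baseline window (default: all frames
before application; the window must end at or before the application
frame). `ΔR/R = (R_resp − R0)/R0` with `R_resp` either the mean over a
response window (default: last 3 frames), the post-application maximum,
or the final frame ("endpoint", for slow multi-hour induction
experiments). Colonies whose baseline donor signal is not positive
cannot be ratioed; they are excluded with a message rather than failing
a 750-colony run. A colony is artifact-flagged when its direct-acceptor
intensity changes by more than 15% between baseline and response
windows — by construction of the forward model that channel only moves
under a FRET-independent gain.

## Scoring, ranking, selection

The screening score is `S = ΔR/R / sqrt(R0)`: selection is driven by the
response, with a square-root penalty that biases towards genuinely large
changes rather than merely low starting ratios. (The published
formulation "ΔR/R₀ divided by R₀^0.5" is compressed; it is read here as
the relative ratio change divided by the square root of the basal
ratio.) Ties break by higher ΔR/R, then lower R0, then colony id, making
the ranking a total order. Fraction-mode selection picks
`max(1, round(f·n))` colonies (default f = 0.02, the middle of the
documented 1–2.5% picking range); border-touching and artifact-flagged
colonies are excluded before ranking unless overridden. Whether the
original program auto-excluded border colonies is unknown; exclusion is
the conservative default since border detections are the documented
outlier source.

Control-referenced selection, for assays where the treatment itself
shifts apparent ratios (fluorescent inducers), picks every candidate
with `R0` strictly below *and* `ΔR/R` strictly above the mean of the
positive-control colonies.

## Spatial QC and the radial correction

Per-plate variability is summarized by the CV (`100·SD/mean`, sample SD)
of R0, ΔR/R and direct-acceptor intensity, plus position-dependence
bubble plots (colonies drawn at their positions, marker area ∝ value).
Bubble plots are indexed in image raster order; the published
bottom-right-to-top-left index order is under-specified and not claimed.

Because the gun-model decline is predictable, it can be taken into
account: `ΔR/R ~ a + b·(r/r_max)^p` is fitted by least squares (default
p = 1), with the center either the image center or fitted by a
coarse-to-fine grid search ("auto"). The correction is multiplicative,
`ΔR/R_corr = ΔR/R · d̂(0)/d̂(r)`, because deposition *scales* the
response in the forward model (`realized ΔR/R = ΔR/R_max · d`); an
additive correction would be wrong under that model. The parametric
radial form and the fitted-center option are additions of this package —
the published analysis shows the gradient only graphically. Extrapolation
is refused when the fitted profile falls below 10% of its central value
at any colony (`eps`): dividing by a near-zero prediction would amplify
noise without bound. In the noise-free matched-model case the correction
inverts the simulator exactly; this is tested.

Plate-vs-reference agreement is quantified by Pearson correlations of R0
and ΔR/R over colonies matched by id, and by top-k enrichment: how many
of the reference's top-m colonies appear in the plate's top-k picks
(the documented configuration is top-15 picks against the in-vitro
top 5). The published correlations (0.61 for R0, 0.30 for ΔR/R) and the
4-of-5 enrichment derive from unshared wet-lab data; the package instead
verifies the machinery on synthetic matched pairs with a planted
correlation, where the estimate must fall in the Fisher confidence band
and mean enrichment must rise monotonically with the planted correlation
and reach m exactly at correlation 1.

## Numerical and design choices

- **Coordinates and windows.** All file-facing coordinates are 0-based
  `(row, col)`, origin top-left; all frame windows are half-open
  `[start, end)`. Internally R's 1-based indexing is converted at the
  boundaries.
- **Determinism.** One master seed per run; each stage (layout, sensors,
  spray, mottle, noise, reference draws) derives its own sub-seed, so
  identical configs and seeds give bit-identical stacks, manifests and
  picks, and changing one stage's parameters does not perturb another's
  draws. RNG state of the caller is always restored.
- **Degenerate inputs.** Empty layouts, empty masks and empty selections
  are valid (empty outputs, warnings where useful); infeasible layout
  requests (dart-throwing budget exhausted) and windows that straddle
  the application frame are errors; a constant image degrades the robust
  threshold to plain mode with a warning.
- **Storage.** One 16-bit multi-page TIFF per channel (page = frame) with
  a JSON sidecar for acquisition metadata; counts are integers, so the
  round trip is lossless. Binary label images store the colony id per
  pixel. Every emitted CSV has a documented header and re-reads to the
  in-memory table.
- **Study sizes.** The Monte-Carlo studies use scaled-down plates chosen
  by the package: detection benchmarking renders 4 frames (detection
  uses one), the planted-winner study uses 500-colony plates with an
  8 × 60 s acquisition, and the spray-CV study uses 300-colony
  single-sensor plates over 20 seeds. These sizes keep the studies quick
  while leaving the per-colony error structure of the full-size default
  unchanged.

## Known limitations

- Merged colonies are accepted, not split; recall on plates denser than
  the default separation will degrade before precision does.
- The radial model is parametric; a patchy bottle field is deliberately
  outside its model class, and correction there is not expected to
  recover truth (only to not hurt much).
- The artifact flag detects multiplicative acceptor-gain artifacts; a
  donor-side artifact would pass it and surface only as a ratio change.
- Absolute intensities are conventions; only ratios and relative errors
  transfer to real instruments.
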