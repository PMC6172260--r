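---
title: "Estimating synaptic protein copy numbers by comparative synaptosome imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating synaptic protein copy numbers by comparative synaptosome imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosiquant)
```

## The measurement model

Fluorescence immunostaining reports protein amounts only up to an unknown,
session-specific gain: lamp intensity, camera settings, antibody lot and
labelling efficiency all enter multiplicatively. The comparative approach
cancels that gain by staining and imaging, in the same session and with the
same settings, a *reference sample with known copy numbers*: purified
synaptosomes whose average protein content per particle has been measured
biochemically. If antibody binding and detection act identically on both
samples — plausible for two thin samples processed as one batch — then for
every accepted synapse $i$

$$\widehat{N}_i \;=\; \frac{I_i}{\overline{I}_{\mathrm{synaptosome}}}\; N_{\mathrm{ref}},$$

where $I$ is the punctum's integrated fluorescence and $N_{\mathrm{ref}}$ the
reference copies per synaptosome. The assumptions worth stating explicitly:

* **Linearity** — intensity is proportional to bound antibody number, and
  antibody intensities sum linearly. The package tests this on synthetic
  $k$-antibody structures ($k = 1, 2, 3, 5$) and exposes the same check for
  real data through the single-antibody calibration: single primary
  antibodies, which carry roughly three secondary antibodies, should be about
  three-fold brighter than an individual secondary.
* **Equal staining efficiency** across the two samples; the design forces
  identical processing (one configuration governs both samples; only the
  detection threshold may differ, because background levels differ between a
  synaptosome lawn and a culture).
* **The reference value itself** — copies per synaptosome — is taken as given
  from biochemistry and its uncertainty is reported alongside, not propagated
  into the per-synapse SEM (no principled propagation formula exists for a
  ratio of sample means against an external reference; the two dispersions
  answer different questions).

## Pipeline stages and their parameters

**Detection.** Candidates are local maxima of the marker channel after
smoothing with an isotropic Gaussian of sigma `smoothing_sigma_nm` (default
480 nm — about the size of a synapse, so the filter acts as a matched filter
for synapse-scale blobs). Smoothing uses separable spatial convolution with
reflective padding: constants are preserved and borders are not dimmed, which
matters because the threshold is computed on the smoothed image. The default
threshold is `median + k * 1.4826 * MAD` with `k = 5`. The rationale is
reproducibility: a hand-picked absolute threshold cannot be transported
between datasets, while the robust rule tracks the background level and keeps
the threshold *low* — false positives are cheap here, because the later
R-squared filter removes them; false negatives are unrecoverable. An absolute
override exists (`detect_threshold_mode = "absolute"`) and the value actually
used is recorded in the detection result and the run report.

A maximum must be strictly greater than every pixel in a $(2r+1)^2$
neighbourhood, $r =$ `maxima_min_separation_nm` (default 480 nm) converted to
pixels; plateau ties are broken by the earliest row-major position, so an
exact plateau yields exactly one candidate. Maxima whose fitting region would
cross the image border are discarded, and maxima closer than the minimum
separation to a brighter one are suppressed. These neighbourhood conventions
are package decisions (the plateau and suppression rules have to be *some*
deterministic rule; the chosen ones are the simplest that make detection
translation-equivariant and reproducible).

**Fitting.** Each candidate is fitted in each raw channel over a square
region of `roi_side_nm` (default 2.2 µm, ~15 px at 160 nm pixels) with

$$f(x, y) = \mathrm{offset} + A\,
  e^{-(a\,\Delta x^2 + 2b\,\Delta x \Delta y + c\,\Delta y^2)},$$

reported as centre, spreads $\sigma_{major} \ge \sigma_{minor}$, orientation
$\theta \in [0, \pi)$ (the major axis lies along angle $-\theta$ in $(x, y)$),
amplitude and offset; the offset term absorbs local background, so no
background subtraction precedes analysis. The signal measure is the volume
above the offset, $2\pi A \sigma_1 \sigma_2$, which is robust to the
pixelation of the peak. Numerically the ellipse is optimised in the
quadratic-form coefficients $(a, b, c)$ rather than
$(\sigma_1, \sigma_2, \theta)$: the angle is unidentifiable for near-circular
spots and periodic, which strands Levenberg–Marquardt in axis-aligned local
minima, whereas $(a, b, c)$ is smooth and unambiguous. Starting values come
from the intensity-weighted covariance moments of the median-subtracted
region (centre start is the detected position); a centroid/isotropic restart
is attempted if the first fit degenerates. Box bounds keep the centre inside
the region, the implied sigmas within $[0.5\,\mathrm{px}, \mathrm{ROI}/2]$
and the amplitude non-negative, so pure noise cannot be "fitted" by a huge,
flat Gaussian with an enormous integral. Losses are plain unweighted least
squares, and goodness of fit is the ordinary
$R^2 = 1 - SS_{res}/SS_{tot}$ over the region's pixels. On noiseless
synthetic spots the fit recovers all parameters to machine precision; under
shot noise at peak SNR ≈ 10 the centre is good to ~0.1 px and the integral to
a few percent (both are tested).

**Filtering.** A candidate is accepted iff all three channel fits converged
and reached their thresholds — defaults 0.85 (marker), 0.70 (active zone),
0.60 (POI). Comparisons are inclusive: the protocol discards fits *below*
the threshold, so a value exactly at it passes. Rejected candidates carry the
failing channel names, and overlapping or fused puncta — fitted independently
with a single-spot model — are expected to fail here rather than being
segmented upstream.

**Quantification.** Copy numbers are computed per synapse and then
summarised (mean ± SEM over synapses), i.e. the mean-of-ratios reading, which
matches reporting per-synapse copy values on example synapses; the
alternative ratio-of-means is identical in expectation here because the
denominator is the same mean synaptosome intensity for every synapse. All
estimates are invariant under a common rescaling of both samples' intensities
(tested as a property).

## Single-antibody calibration

To compare stainings across laboratories without sharing synaptosome
preparations, intensities are expressed as *numbers of antibodies*:
a structure's integrated intensity divided by the mean intensity of a single
immunolabelled primary antibody. Antibody spots are detected on a
difference-of-Gaussians bandpass (scales: the imaging point-spread sigma and
three times it — the band that passes PSF-sized spots while removing pixel
noise and slowly varying background; the exact scales are package defaults,
chosen as the conventional DoG bracket), fitted on the raw image, and the
retained intensity population is summarised by a least-squares Gaussian fit
to its Freedman–Diaconis histogram; the fitted peak is the calibration mean
(the median is reported as a robust cross-check, and a histogram fit with
$R^2 < 0.5$ warns of a multimodal population, e.g. antibody clusters).
The histogram-peak route is preferred over the plain mean because it is
insensitive to a bright tail of unresolved antibody doublets.

Oversized spots are debris, not antibodies. The 50 nm FWHM cutoff is only
physically resolvable in super-resolution data, so it is applied when the
pixel size is ≤ 25 nm; at epifluorescence pixel sizes the package instead
rejects spots wider than twice the population's median FWHM, a sanity bound
that serves the same purpose at the achievable resolution. FWHM uses the
geometric mean of the fitted sigmas, $2\sqrt{2\ln 2}\,\sqrt{\sigma_1\sigma_2}
\cdot \mathrm{pixel}$, so elongated fits of equal area report equal width.

## The reference table

`load_reference()` returns 120 stainings of over 100 targets: mean primary
antibodies per synaptosome with dispersion (SEM over several hundred synapses,
or range-of-values over experiments — both conventions appear in the source
and are kept distinct), protein copies per synaptosome with SEM where
biochemically measured, and the staining conditions (vendor, catalogue
number, clonality, dilution, fixation, blocking, permeabilisation), since the
antibody numbers only transfer under the same conditions. Copy values that
were published as author estimates ("~200", "~100–200", "<100", "presumably
similar to ChromograninB") are stored as structured ranges and qualifiers
rather than invented floats, and targets never characterised biochemically
are flagged `not_determined`. Lookups are case-insensitive and must be
unambiguous; duplicate target rows (two vendors, two dilutions, or duplicate
rows differing only in dispersion convention) are disambiguated by catalogue
number, dilution, or dispersion kind, and ambiguous queries fail with the
candidate rows enumerated.

## What the simulator emulates — and what it does not

`simulate_field()` renders isotropic Gaussian puncta (the diffraction-limited
image of sub-resolution objects) at sub-pixel positions with a minimum
pairwise separation, on a constant background, with per-spot per-channel
amplitudes drawn log-normally (default CV 0.5, reflecting the broad
per-synapse intensity spread of real stainings) and Poisson shot noise.
Defaults: 160 nm pixels and a 480 nm FWHM point spread, the geometry in which
800 nm spans exactly 5 pixels. `simulate_pair()` makes a matched
synaptosome/culture pair sharing all imaging parameters, with the culture POI
amplitudes scaled by a ground-truth copy ratio — the *in silico* version of
staining the two samples in parallel. `simulate_antibody_field()` builds
calibration fields in which spot intensity is exactly $k$ antibody units
(linear summation by construction), with optional oversized "dirt" spots for
testing the debris rejection; its test geometry uses 20 nm pixels, a 31 nm
FWHM spot (a STED-scale point spread) and amplitude CV 0.15 — single
antibodies carry a narrow label load distribution compared to synapses.
Everything is deterministic given the seed.

Not emulated: realistic optics (Airy rings, aberrations), camera gain and
read-noise calibration, chromatic mis-registration, drift, photobleaching,
structured cellular background, and fused synapses. Passing tests therefore
show the *algorithm* is correct and unbiased under its own model — recall,
false positives, parameter recovery, end-to-end ratio recovery within 10% —
not that any particular microscope meets the model's assumptions; the
calibration's linearity check is the package's handle on the latter.

## Problem sizes and numerical choices

The validation suite runs simulated pairs of 2 × 150 spots per sample on
360 × 360 px fields for each planted ratio in {0.5, 0.77, 1.0, 1.5} — about
300 accepted synapses per sample, comparable to the per-protein synapse
counts in real datasets and enough that the log-normal amplitude spread
(CV 0.5) leaves the estimated mean ratio within a few percent of truth.
Calibration tests use 150 antibody spots, matching a typical coverslip field
census. Degenerate inputs are explicit errors, not silent results: images
smaller than the fitting region warn and return no candidates; zero-variance
regions make $R^2$ undefined and the fit is treated as failed; fewer than 10
retained calibration spots is an error; a sample with zero accepted synapses
aborts the run naming the failing stage. TIFF output stores intensities
divided by $2^{16}$ (an exact binary scaling) because the writer's float
range is $[0, 1]$; records CSVs round-trip numerics to 15 significant digits.

## Limitations

* The method is semi-quantitative: accuracy is bounded by the biochemical
  reference values and by the equal-staining assumption, not by the imaging
  statistics.
* Targets absent from the reference table cannot be quantified (the table
  covers cytoskeleton, vesicle cycle and postsynaptic density pathways, not
  the whole proteome).
* Thick samples (brain sections, organs) violate the equal-penetration
  assumption; sectioning to ~10 µm or a GFP-based penetration control is
  advised before applying the comparison.
* Antibody intensity summation can saturate on extremely bright structures;
  the calibration linearity check should be run per imaging system.
* Fused or overlapping synapses are rejected, not resolved; densely packed
  preparations lose a biased subset of bright puncta.
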