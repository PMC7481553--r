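---
title: "Quantifying lateral flow assay strips: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lateral flow assay strips: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The measurement problem

A lateral flow (immuno)assay strip carries one or more reagent lines — test
lines whose signal grows with analyte concentration, and a control line that
validates the run. Photographed through an emission filter, each line appears
as a horizontal band over a membrane background. Quantification means turning
such photographs into calibrated concentration estimates, which decomposes
into:

1. **Geometry** — crop the membrane area, split a batch photograph into
   per-strip lanes;
2. **Densitometry** — reduce each lane to a flow-axis intensity profile,
   localise up to six bands, and integrate each band's area under the profile
   (AUC) after subtracting the membrane background;
3. **Calibration** — average technical replicates, fit a linear model of
   signal on concentration per analyte and channel, and derive the key
   sensitivity measures LOB, LOD and LOQ by inverse prediction.

Duplex readout — two analytes on one test line, labelled with spectrally
distinct fluorophores (e.g. green- and red-emitting quantum dots) and imaged
through two bandpass filters — is handled by treating each emission channel
as an independent single-channel image of the same strip.

## Band measurement model

The flow axis runs along image rows. A lane's intensity profile is the
arithmetic mean of each row's pixels; a band's *raw AUC* is the plain sum of
profile values over the band window (rectangle rule — the simplest reading of
densitometric AUC). The background-corrected AUC is

$$\mathrm{AUC}_\text{corr} \;=\; \sum_{r \in \text{window}} \max\!\bigl(p_r - b,\, 0\bigr),$$

where $p_r$ is the profile value at row $r$ and $b$ the background level.
Negative residuals are floored at zero so that noise on the membrane cannot
cancel genuine faint-band signal.

### Background by Otsu's threshold

The background level is estimated per band, not per lane. Otsu's method —
the threshold over the pixel-value histogram maximising between-class
variance, with foreground defined as values at or above the threshold and
ties broken towards the smallest candidate — classifies the pixels of the
band window plus a flanking margin (default twice the window length on each
side, clipped to the lane). Three refinements matter in practice, all
motivated by measurable biases:

* **Background is the flanking membrane, not the window.** $b$ is the mean
  of sub-threshold pixels *outside* the window. Including the window's own
  pixels would let the band's Gaussian tails (which fall below the
  threshold) inflate the estimate by several percent of the band signal.
* **Sibling bands are excluded from the context.** When a faint test band
  sits near a bright control line, the control's shoulder pixels fall below
  Otsu's threshold and would contaminate the background estimate. Each
  band's context therefore excludes every other detected band's window.
  Without this, blank and near-LOD measurement variance was roughly four
  times larger in simulation, which distorts all blank-based key measures.
* **Degenerate input** (all context pixels identical) cannot be thresholded;
  the whole window is then treated as background, the corrected AUC is 0 and
  a warning is logged.

### Band localisation

Profiles are smoothed with a centred moving average (odd window, default 5
rows; edges replicated). In *free-detection* mode the `expected_n` most
prominent local maxima become band anchors (prominence measured above the
profile minimum; equal prominence keeps the topmost peak). Each window grows
outward from its peak until the smoothed profile drops below
`background + boundary_fraction × (peak − background)` (default 10%).
Overlapping neighbour windows are split at the midpoint between peaks.

In *reference-guided* mode the caller supplies the printed line positions —
on manufactured strips these are fixed by design — and each band's peak is
searched only within `search_halfwidth` rows (default 10) of its reference
position, with the window capped to that neighbourhood. This mode is what
the batch workflow uses, for two reasons: a blank strip has no test band, so
free detection would latch onto an arbitrary noise bump and, worse, could
mislabel the control line as the test line; and an absent band should be
measured *at its known position*, yielding an honest noise-level signal that
feeds the blank statistics. The window cap prevents noise-grown windows from
sprawling across half the strip on blank lanes.

The six-band ceiling reflects the most line-rich strips in routine use; by
default the bottom-most band is taken to be the control line.

### Saturation

Pixels clipped at the detector maximum ($2^{\text{bit depth}}-1$) produce
flat-topped peaks whose AUC underestimates the true signal.
`detect_saturation()` reports the at-maximum pixel fraction (image flagged
above 0.001 — a qualitative threshold, since even a small clipped area sits
exactly where the signal is largest), `measure_band()` flags any band window
containing an at-maximum pixel, and the calibration step excludes flagged
measurements from fitting by default (an `include_saturated` switch exists
for diagnostic use). Saturation is detected and reported, never silently
quantified.

## Calibration and key measures

Replicates are averaged per (analyte, channel, replicate group) with the
sample standard deviation ($n-1$ denominator); singleton groups get sd 0 and
a warning. The calibration model is ordinary least squares of mean signal on
concentration — the classic direction, inverted for concentration estimates:

$$\hat{c} = (y - \hat{\beta}_0)/\hat{\beta}_1.$$

Fitting on replicate means (rather than individual replicates) follows the
averaging-then-calibration workflow; at least three distinct concentration
levels are required. $R^2 = 1 - SS_{res}/SS_{tot}$ and the residual sd is
$\sqrt{SS_{res}/(n-2)}$. Optional weights allow e.g. $1/c$ weighting; the
model remains linear in its parameters.

The key measures use the standard blank-based definitions, computed in
signal units and converted to concentration by inverse prediction:

$$\mathrm{LOB}_s = \bar{x}_B + 1.645\, s_B, \qquad
  \mathrm{LOD}_s = \mathrm{LOB}_s + 1.645\, s_{low}, \qquad
  \mathrm{LOQ}_s = \bar{x}_B + 10\, s_B,$$

with $\bar{x}_B, s_B$ the blank mean and sd and $s_{low}$ the sd of the
lowest non-blank calibrant (falling back to $s_B$ when absent, with a logged
note). The `definitions_id` field records the formula set, making it
explicit and pluggable. A limit that maps below zero concentration — which
happens when the blank signal sits below the fitted intercept — is reported
as the literal label `"Negative"` rather than a meaningless negative
concentration. At least two blank replicates are required; with so few
blanks the sd estimate is itself noisy, and key measures from small designs
should be read as indicative.

## The synthetic strip simulator

Real assay images are rarely shareable, so every pipeline stage is exercised
against a ground-truthed simulator. The noise-free signal is

$$S(r, c) = B + g\,(r-1) + \sum_i A_i \exp\!\bigl(-(r-\mu_i)^2 / 2\sigma^2\bigr),$$

uniform across the strip width: background level $B$, per-row gradient $g$,
Gaussian bands of amplitude $A_i$ at centres $\mu_i$ with width $\sigma$.
Optional Gaussian blur (separable convolution, edge-replicated), additive
Gaussian noise (seeded), rounding to integer counts, and either clipping at
the representable range or a range error. Defaults: 120 × 30 px strips,
16-bit, test line at row 40 and control at row 90, $\sigma = 3$ px (a
realistic printed-line width at typical crop resolutions: FWHM ≈ 7 rows),
background 500 counts, noise sd 60 counts.

A duplex experiment pairs concentration levels of two analytes on the same
strips (analyte A read in the green channel, B in red), with a linear or
Langmuir (saturable binding) amplitude response, a constant control-line
amplitude, and a configurable `crosstalk` fraction of the other label's
amplitude leaking into a channel (0 = spectrally clean). The default
sandwich design spans 0–20 nM in 5 levels × 3 replicates with amplitude
slope 150 counts/nM and noise sd 60 — 2% of the maximum test-band amplitude;
`clinical_range_design()` spans 0–1000 nM and 0–60 pM, the clinically
relevant ranges of the CRP and IL-6 biomarkers.

Per-image seeds derive from the master seed as
`seed + 2·(strip−1) + channel_offset`, so each strip's two channel images
get independent noise while the whole experiment is bit-reproducible, and a
channel's images are pixel-independent of the other analyte's
concentrations when crosstalk is 0 — the basis of the duplex
non-interference test.

What the simulator deliberately does **not** model: membrane texture and
wicking kinetics, Poisson shot noise (additive Gaussian only — a read-noise
proxy), emission-spectrum overlap beyond the scalar crosstalk fraction, lane
skew or rotation. Passing tests therefore demonstrate correctness of the
measurement and calibration machinery on idealised strips, not performance
on any particular imager's artefacts.

## Numerical choices and degenerate inputs

* Geometry is 1-based and inclusive throughout, matching R indexing.
* Lane splitting distributes remainder columns to the leftmost lanes, so
  lanes always tile the image exactly.
* Otsu candidates are the distinct observed values; ties take the smallest
  threshold. The implementation (one cumulative pass over the sorted
  histogram) is tested for exact agreement with an exhaustive brute-force
  maximiser on 1,000 random arrays.
* Luminance collapse of RGB input uses ITU-R BT.601 weights
  (0.299, 0.587, 0.114), rounded to the nearest integer — fixed for
  reproducibility. Emission-filtered captures should instead select the
  matching colour channel, the default behaviour.
* Quantisation floor: a band of amplitude $A$ spread over $k$ rows carries
  per-row rounding error up to 0.5 counts, so relative AUC error up to
  roughly $k/(5A)$ can survive every correct processing step. Recovery
  within 2% of the analytic band integral is achieved for amplitudes ≳ 50
  counts at $\sigma = 3$; a 10-count band can sit several percent off purely
  from integer rounding in the capture.
* Reports contain no timestamps or hostnames, so identical inputs produce
  byte-identical HTML/Markdown — verified by rerunning the whole pipeline.

## Problem sizes used in the checks

The packaged checks run the sandwich design at 5 levels × 3 replicates
(30 images), the duplex non-interference comparison at 50 seeds × 2
conditions with 2 replicates, and the LOD operating check with 500 simulated
blanks plus 500 strips at the estimated LOD. These sizes give stable
pass/fail behaviour for the properties tested while keeping a full run in
the order of seconds to a few minutes.

## Known limitations

* Lane splitting assumes well-aligned vertical strips; there is no skew
  correction beyond whole-image rotation before entry.
* Cropping is manual by design — the one user-supplied geometry input.
* JPEG input is rejected: lossy artefacts bias band AUCs, and accepting
  them would invite silently degraded measurements.
* The LOB/LOD/LOQ formula set is one standard choice among several in the
  limit-of-blank literature; `definitions_id` names it so results are not
  confused across conventions.
* Nonlinear (4PL/5PL) calibration is out of scope; the model hook is limited
  to linear-in-parameters forms.
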