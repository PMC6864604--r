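---
title: "The lfaquant readout pipeline: model, conventions and synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The lfaquant readout pipeline: model, conventions and synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaquant)
```

## The measurement model

A lateral flow assay (LFA) strip develops two reddish bands on a pale
membrane: the control line (the assay ran) and the test line (intensity grows
with analyte). `lfaquant` models a photograph of such a strip, framed so the
lines fall in the centre cell of a 3×3 grid, and reduces it to a single
scalar readout, the test-to-control ratio

$$ T/C = \frac{S_\text{test}}{S_\text{control}}, \qquad
   S_\text{region} = \sum_{(x,y) \in \text{mask} \cap \text{region}} I_R(x,y). $$

The key assumption is multiplicative illumination: a change in lighting or
exposure scales all channels of all pixels by a common factor $k$. Both the
segmentation feature and the readout are ratios, so $k$ cancels twice:

- the **ratio image** $r = I_R / I_G$ used for masking is invariant under
  $I \mapsto kI$ (up to 8-bit rounding), and
- $T/C$ is a ratio of two sums taken from the same photograph.

The remaining model is a straight line between $T/C$ and log quantity,
$y = m\,x + b$ with $x = \log_{10}(q / q_\text{ref})$ and
$q_\text{ref} = 10$ fg by default, valid over the assay's dynamic range.

## Pipeline stages and their conventions

**ROI geometry.** `center_box(width, height)` takes the middle ninth using
floor division: `x0 = floor(w/3)`, `x1 = floor(2w/3)` (and likewise in `y`);
rectangles are half-open `[x0, x1) × [y0, y1)` with `x` the column and `y`
the row, zero-based. `line_regions()` splits the centre cell at
`y0 + floor(h·i/3)` for `i = 1, 2`: the upper third holds the control line
and the middle third the test line. `flipped = TRUE` instead reads the
control line from the bottom third, for strips photographed upside down.

**Segmentation.** The Otsu threshold is computed from the **control region
only** — it always carries a band, so its ratio histogram is reliably
bimodal, whereas a blank test region would make a test-region threshold
meaningless. Numerical conventions, all of which the test suite pins down:

- the histogram uses 256 uniform bins spanning the observed ratio range;
- all 255 cuts are scored by total intra-class variance, exhaustively;
- ties resolve to the smallest cut;
- the returned threshold is the *upper edge* of the cut bin;
- masking is strict: a pixel enters the mask only if `r > TH_mask`;
- pixels with $I_G = 0$ have no defined ratio and are excluded;
- a constant thresholding region is an error ("degenerate input"), not a
  silent threshold.

A multilevel variant (`otsu_levels = 3`) exists for scenes with more than
two intensity populations; the mask then uses the top threshold.

**Calibration.** `fit_calibration()` is ordinary least squares of $T/C$ on
$x$. The error term σ is the root-mean-square residual with divisor $N$
(population convention, not $N-2$); $R^2 = 1 - SS_\text{res}/SS_\text{tot}$;
the limits are $\text{LOD} = \text{LOB} + 1.645\,\sigma/m$ and
$\text{LOQ} = 10\,\sigma/m$, both on the $x$ (log-quantity) scale. LOB
defaults to 0 and becomes $\bar{y}_\text{blank} + 1.645\,s_\text{blank}$
when blank readings are supplied. Per-class coefficients of variation use
the $n-1$ sample standard deviation, in percent; a class with zero mean has
an undefined CV (`NA`).

**Classification.** Readings are first mapped to calibrated log-quantities
$\hat{x} = (T/C - b)/m$, so the classifier sees a scale on which classes are
equidistant. A one-vs-one linear SVM (via `e1071`, `scale = FALSE`) reduces
each pair to a scalar decision function $f(x) = wx + \beta$, re-oriented so
$f > 0$ always votes for the lower-indexed class regardless of data order;
degenerate pairs (no separating information) abstain. Prediction is by
majority vote, with ties broken by aggregate $|f|$ margin and then by the
lower quantity — the conservative call for an assay. Evaluation uses
stratified k-fold cross validation: within each class, readings are shuffled
by the seed and dealt round-robin into folds, so every fold sees every class.

## The synthetic strip generator

Real strip photographs are large, noisy and scarce, so the package includes
a forward model with exact ground truth. A `synthetic_strip_spec()` paints,
on a uniform grey background (default RGB 200, 200, 200), a control band and
a test band at a fixed band colour (default 160, 130, 130) inside the
correct grid-cell thirds, then multiplies by an illumination factor, adds
seeded Gaussian pixel noise, and rounds/clips to 8 bits.

The default `"coverage"` profile encodes band strength as the **painted
fraction of the line-region width**: a strength-$s$ test band covers a
centred stretch of $\text{round}(s \cdot w)$ columns at full band colour.
This choice has three properties that make the generator a usable oracle:

1. the control region is cleanly bimodal (background ratio 1.0 vs band ratio
   ≈ 1.23), so the Otsu threshold is stable under 8-bit quantisation;
2. the noiseless $T/C$ equals $s$ exactly (both bands share one red value,
   so the per-pixel sums are proportional to pixel counts), giving
   closed-form expectations at ~0.005 granularity on the default 600×600
   image;
3. illumination invariance is *exact*, not approximate: control and test
   band pixels quantise identically, so rounding cancels in the ratio.

An alternative `"flat"` profile blends the whole band rectangle between
background and band colour with weight $s$; it exercises the
intensity-blending regime and yields the closed-form signal
$S = n_\text{band} \cdot \text{round}(200 - 40s)$ at zero noise. A graded
blending profile is deliberately *not* the default: a continuum of ratios in
the control region has no histogram gap, and the Otsu cut then jitters under
quantisation, which is a property of such scenes rather than of the
pipeline.

What the generator emulates: band geometry, band colourimetry relative to
background, global illumination, and sensor noise. What it does not emulate:
membrane texture, vignetting and non-uniform lighting, band edge diffusion,
perspective distortion, and chemical kinetics — quantities fed to
`simulate_strip_set()` are mapped to strengths through an assumed
calibration line (`strength_for_quantity()` inverts the noiseless pipeline
numerically), not through binding chemistry.

All randomness is explicit: every spec carries a seed, `generate_strip()`
saves and restores the caller's RNG state, and `simulate_strip_set()`
derives one deterministic seed per strip.

## Problem sizes and known limitations

The packaged study sizes — five quantity classes spanning 10 fg–100 pg,
five readings per strip, three strip sets (75 readings), five-fold cross
validation, and 25-strip synthetic benchmarks — were chosen to exercise
every code path (ties, held-out splits, stratification) while keeping the
full test suite under a few minutes on one CPU.

Limitations worth knowing:

- the ROI is positional; there is no band *detection*, so a misframed
  photograph reads the wrong pixels;
- the calibration is linear in log quantity and will not flag hook-effect
  saturation at extreme quantities;
- σ uses the $N$ divisor, so it is biased low for very small calibrations;
- classification granularity is one decade; intermediate quantities are
  available only through `predict_quantity()` on the continuous line.

## Reproducing the headline numbers

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, against the installed package, the pooled per-class standard
deviations of the packaged readings, the calibration coefficients and error
metrics, the held-out decision-boundary check, the synthetic end-to-end
accuracy, the illumination-invariance bound, and seeded parameter-recovery
fits, writing each as `{"value": ..., "n": ...}`.
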