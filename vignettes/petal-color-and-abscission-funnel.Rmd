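---
title: "Methods: color-calibrated petal phenotyping and the abscission funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: color-calibrated petal phenotyping and the abscission funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petalfall)
```

`petalfall` quantifies two aspects of hierarchical floral abscission in
cherries: the color trajectory of petals across developmental stages, and
the stage-wise accounting of which flowers and fruits are shed at which
abscission gate. This vignette documents the models, the conventions that
had to be fixed for reproducibility, and the reasoning behind the
genuinely open design choices.

## 1. Color calibration

### Model

Each photograph contains a reference strip of six patches with known
("target") RGB values. Writing $X$ for the $6 \times 3$ matrix of measured
patch means and $T$ for the targets, the calibration estimates the
$3 \times 3$ matrix $M$ minimizing $\lVert X M^\top - T \rVert_F$ — an
ordinary least-squares linear map with **no intercept**. The model
therefore assumes the camera/illumination distortion is well approximated
by a single linear mixing of channels; offsets (flare, black-level error)
and nonlinearity (gamma) are outside the model.

Two decisions here were genuinely open and are package choices, not
established facts about any particular acquisition setup:

* **No intercept.** A $3 \times 4$ affine variant would absorb offsets but
  changes the estimand; we implement the strictly linear $3 \times 3$ map.
* **Fit on patch means, not all patch pixels.** With equal patch areas the
  two fits coincide in expectation; fitting on means (6 rows) makes the
  residual diagnostics directly interpretable per patch.

With six independent patches the system is over-determined and noise
averages down; with exactly three independent patches the fit
interpolates. The fit refuses charts whose measured matrix has condition
number above $10^8$, since a (near) rank-deficient chart cannot identify
$M$. The default synthetic chart (white, grey, red, green, blue, yellow)
has a rank-3 target matrix with condition number ≈ 6.

### Numerical conventions

These conventions are arbitrary in isolation but must be fixed once,
package-wide, for bit-reproducibility:

* **Pixel coordinates** are 0-based, $x$ = column, $y$ = row, origin
  top-left. The center of pixel $(x, y)$ is $(x + 0.5, y + 0.5)$; an
  axis-aligned rectangle $[0,w] \times [0,h]$ therefore rasterizes to
  exactly $w \times h$ pixels.
* **Point-in-polygon** uses the even-odd (crossing) rule on pixel centers;
  a center exactly on an edge counts as inside. The same rule is used for
  chart patches, petal ROIs, and phantom rendering.
* **Rounding** is half-away-from-zero (R's `round()` is half-to-even),
  applied once: the correction runs in floating point and is quantized to
  8-bit a single time, then smoothing operates on the quantized result.
* **Clipping** to $[0, 255]$ happens after rounding.

### Quantization and attainable accuracy

On noise-free synthetic charts the least-squares fit recovers the
generating distortion to machine precision ($\sim 10^{-16}$ relative
Frobenius error) *when given exact patch means*; `simulate_scene()`
exposes these as `measured_means_exact`. Patch means extracted from the
rendered 8-bit image carry up to $0.5/255$ per-channel quantization error,
which propagates to a relative recovery error of order $10^{-3}$ — that is
the accuracy floor of any 8-bit acquisition, not an estimator defect. With
per-channel noise of SD 2 over 64-pixel patches, recovery error is
≈ 0.3 %, and it decreases with patch area as averaging suggests.

One practical caveat the synthetic experiments surfaced: if a distortion
pushes a chart color outside the 8-bit gamut, the clipped patch mean is
biased and recovery degrades sharply. Real charts are designed (and
exposures chosen) to avoid this; the synthetic study conditions likewise
restrict random distortions to those keeping all patch colors in gamut.

## 2. Dominant-color palettes

The pipeline order is fixed as **correct → quantize → smooth → mask →
value-filter → count**:

1. Gaussian smoothing, default $\sigma = 1$ px, kernel truncated at
   $4\sigma$ (radius $\lfloor 4\sigma \rfloor$) and renormalized,
   edge-duplicating reflection at boundaries, separable implementation,
   requantized once. $\sigma = 0$ is the identity.
2. Each polygonal ROI is masked by the shared pixel-center rule.
3. Pixels with HSV value $V = \max(R,G,B)/255 < 0.5$ are excluded
   (strictly: $V \ge 0.5$ keeps), removing shadow and dark-background
   pixels. The threshold `v_min` is exposed; 0.5 is the default.
4. Frequencies are counted over **exact 8-bit triplets** — no binning —
   and the top $k = 20$ colors per ROI are kept (descending count, count
   ties broken by ascending lexicographic $(R,G,B)$). An ROI with fewer
   than $k$ distinct colors contributes all of them, with a warning.
5. Per-ROI lists are concatenated without deduplication and sorted by HSV
   hue $H \in [0,1)$, ties by ascending $(S, V, R, G, B)$; achromatic
   colors ($S = 0$) carry $H = 0$. The sorted palette renders as a
   horizontal bar of equal-width stripes.

The palette size is `n_rois × k` by construction. The standard
configuration used throughout the package's verification is **20 ROIs ×
20 colors = 400 entries**; both `n_rois` and `k` are plain configuration,
since different studies delineate different numbers of ROIs per image.
Whether smoothing should precede or follow correction is not identifiable
from the data themselves; the order above (smooth after quantized
correction) is the package's fixed convention.

Alternatives deliberately **not** implemented: perceptual color spaces
(CIELAB), clustering-based palettes (k-means), automatic petal
segmentation. Exact counting keeps the operation order-invariant and
oracle-checkable.

## 3. The abscission funnel

### Fate model

Five events are tracked per flower, in DPA (days post-anthesis): petal
abscission, flower pedicel–peduncle (PP) abscission, calyx abscission,
fruit PP abscission, peduncle-branch abscission. The branching structure
is:

* **flower PP gate** — with probability $p_\mathrm{flowerPP}$ the whole
  (typically unfertilized) flower is shed; otherwise the flower proceeds
  to calyx abscission, the marker of early fruit development.
* **fruit PP gate** — among calyx-abscised fruits, probability
  $p_\mathrm{fruitPP}$ of being shed; the complement is the final fruit
  set.

Petal shedding is *not* a branching gate: it occurs on both fates (either
before the flower PP event, or together with it in species that retain
petals on unfertilized flowers), so it is summarized by timing and by the
number of petals present at the flower PP gate. The funnel reports, per
gate, the entering count, the event count, the **absolute** proportion (of
all classifiable flowers) and the **conditional** proportion (of gate
entrants); by construction the absolute proportion equals the product of
conditional proportions along the path, and terminal fates
(`shed_at_flowerPP`, `shed_at_fruitPP`, `retained`) partition the cohort
exactly.

Records carrying no gate information (no flower PP event, no calyx event,
not retained — e.g. damaged or lost flowers) go to a separate **censored**
bucket that is reported but excluded from all denominators; silently
dropping them would bias proportions, and imputing a fate would be
invention.

The **peduncle rule** is checked by joining flower records to a
per-peduncle event table: a pedicel counts as shed when its flower's fate
is one of the two shedding fates, and the report contrasts the abscission
frequency of peduncles whose pedicels are all gone against those retaining
at least one.

### Statistics

Figure-legend-style group contrasts are implemented in the package with
independently verifiable semantics, all two-sided (one-sidedness is never
assumed):

* **Welch's t** with Welch–Satterthwaite degrees of freedom.
* **Mann–Whitney** with midranks; exact two-sided p by full enumeration of
  rank assignments when $n_a + n_b \le 12$ with no ties (the bound keeps
  enumeration under $\binom{12}{6} = 924$ splits), otherwise a Normal
  approximation with tie and continuity corrections.
* **Kruskal–Wallis + Dunn.** The phrase "one-way ANOVA with Dunn's post
  hoc" is internally inconsistent — Dunn's procedure is defined on the
  pooled ranks that follow a Kruskal–Wallis test, not on ANOVA — so the
  package implements tie-corrected Kruskal–Wallis followed by Dunn's
  pairwise $z$ statistics with Bonferroni adjustment (the conventional
  default; the adjustment method is exposed).

Under simulated nulls (Normal samples, $n = 30$ per group, 10,000
replicates) both two-sample tests hold their size at $\alpha = 0.05$
within Monte-Carlo error.

## 4. The synthetic-data generator

The generator is the package's ground truth, and its defaults are the
study conditions all verification runs under.

**Scenes.** A phantom image contains the six-patch chart at its target
colors, petal-shaped ROIs painted with known color compositions (colors
assigned in contiguous raster-order blocks, so per-color pixel counts are
exact), and a dark background (default RGB 30,30,30, below the $V < 0.5$
threshold). The distortion is applied as
$\mathrm{measured} = \mathrm{clip}(\mathrm{round}(M_\mathrm{true}^{-1} p +
\varepsilon))$ with i.i.d. per-channel Gaussian noise added *before*
quantization — the simplest model that exercises least-squares averaging —
so the fitted correction estimates $M_\mathrm{true}$ directly.

**Cohorts.** Fates are drawn by the sequential Bernoulli gates above.
Default gate probabilities are 0.426 and 0.730 (Yoshino-type season; the
*P. sargentii*-type configuration uses 0.719 / 0.732 with
`petals_at_flowerPP = TRUE`, giving a final fruit set below 8 %). Event
days are Normal per event — defaults centered at 3.5 / 9 / 14.5 / 19 / 29
DPA for petal, flower PP, calyx, fruit PP, and peduncle events, SDs of
0.8–3 days chosen as realistic within-season spreads since per-event SDs
are study-specific — truncated at zero and forced monotone along each
flower's path by **whole-path resampling** (up to 100 attempts, then an
error): resampling approximately preserves the marginal distributions
where clipping would distort them. Fruit and seed sizes are log-normal
(CV 0.25) with abscised-group means at 38.5 % (fruit) and 16.7 % (seed) of
the retained-group means. Flowers sit 2–4 per peduncle on five trees;
once all of a peduncle's pedicels are shed, it abscises with probability
0.95, and never while a pedicel remains. Every simulation call runs on a
single seeded RNG stream and restores the caller's RNG state, so identical
seed and parameters give byte-identical CSV output.

**What the generator does not emulate** — and therefore what passing tests
do *not* demonstrate about field data: illumination gradients, lens
distortion or photorealistic petal texture; correlations between event
timings within a flower beyond path monotonicity (timings are independent
given fate); tree- or peduncle-level random effects on fates; censoring
mechanisms. Recovery of gate probabilities from synthetic cohorts shows
the estimator is consistent under the stated model, not that any
particular field estimate is correct.

## 5. Problem sizes and runtime envelope

Verification runs use: 100 random distortions for zero-noise matrix
recovery and 20 for the noisy case (64-px patches, noise SD 2); a
20-ROI × 20-color phantom for the palette pipeline; 20 seeded cohorts of
2,000 flowers for funnel parameter recovery (each conditional proportion
within 3 binomial SEs); and 10,000 null replicates at $n = 30$/group for
test calibration. These sizes give stable Monte-Carlo estimates while
keeping the full suite fast on a single CPU.

## 6. Known limitations

* The calibration model is strictly linear; offset or gamma distortions
  alias into $M$ and inflate patch residuals (which are reported, so such
  misfit is visible).
* Exact 8-bit counting makes palettes sensitive to single-level color
  differences; that is intentional (it preserves oracle-exactness) but
  means palettes from heavily dithered images list many near-duplicates.
* The funnel treats flowers as exchangeable; clustered designs (trees,
  peduncles) should interpret the binomial SE heuristics accordingly.
* The CSV schema encodes absence as empty cells; numbers in event columns
  are otherwise trusted, so upstream unit errors (e.g. hours instead of
  days) are not detectable beyond the ordering checks in
  `validate_records()`.
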