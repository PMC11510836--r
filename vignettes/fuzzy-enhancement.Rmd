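---
title: "Fuzzy local-contrast enhancement: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy local-contrast enhancement: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzycontrast)
```

## The model

`fuzzycontrast` treats an 8-bit grayscale image as a fuzzy set: every
pixel intensity `f(x, y)` is paired with a membership degree
`μ(f(x, y)) ∈ [0, 1]` expressing how strongly the pixel belongs to a
reference intensity class. Enhancement proceeds in three stages.

**Fuzzification.** Intensities are min–max normalized to `u ∈ [0, 1]`
and mapped through a Cauchy-type membership function
`μ_i = 1 / (1 + ((u − c_i)/σ_f)²)` around each cluster center `c_i`,
aggregated across centers by the fuzzy union (pointwise maximum). We use
the squared (Cauchy) distance deliberately: an unsquared linear distance
in the denominator is unbounded and changes sign around the center, so
it cannot serve as a membership degree, while the squared form is
symmetric, bounded in `(0, 1]`, and maximal exactly at a center. The
classical INT (intensification) operator, `μ′ = 2μ²` below one half and
`μ′ = 1 − 2(1 − μ)²` above, then sharpens the fuzzy partition; its fixed
points are exactly `{0, ½, 1}` and it is monotone, so it reorders
nothing.

**Local features.** All features are computed on an odd `n × m` sliding
window (default 3×3) with symmetric border reflection, so feature maps
always have the image's dimensions. Three features can drive the
enhancement exponent:

* *histogram spread* `h_F = (f_max − f_min)/h_max`, the window's
  intensity range over its histogram's tallest bin — near zero in flat
  regions, largest in near-binary regions;
* *fuzzy entropy*
  `ε = −a Σ_i [μ_i ln μ_i + (1 − μ_i) ln(1 − μ_i)] / ln(nm)`, where
  `μ_i` is the relative frequency of pixel `i`'s intensity within the
  window and `0·ln 0 := 0`. The sum runs over the window's `nm` pixels,
  matching the per-pixel definition of `μ_i`; natural logarithms are
  used in both the sum and the normalizer (the base only cancels when
  the two match). Note the formula vanishes on homogeneous windows —
  informal descriptions of fuzzy entropy sometimes expect the opposite
  — and is invariant to any relabeling of the intensities because it
  depends only on the count multiset;
* *fuzzy standard deviation*
  `σ = sqrt(Σ_j (f_j − M_W)² μ_j / Σ_j μ_j / (nm))`, the
  membership-weighted dispersion about the window's arithmetic mean
  `M_W`. The mean is local — a window statistic, not an image-wide one —
  because the feature must respond to the neighbourhood it describes.

**Contrast stretch and reconstruction.** The per-pixel local contrast
`C = (max_W f − min_W f)/255` is stretched about the pivot `Ĉ` (the
mean of the contrast map; the median is available) by a two-branch power
law with exponent `α < 1` taken from the chosen feature, then each pixel
is rebuilt by the mean-anchored gain `f′ = M_W + (f − M_W)(C*/C)`. This
gain rule exactly realizes the target contrast `C*` for the window's
extreme pixels under the range definition of `C` and degrades gracefully
for interior pixels; it also preserves which side of the local mean a
pixel lies on, so structure is amplified, never inverted.

## Tunable parameters

| Parameter | Default | Units / range | Rationale |
|---|---|---|---|
| `centers`, `sigma_f` | 0.5, 0.25 | normalized intensity | one mid-gray class; σ_f covers the full range smoothly |
| window `n × m` | 3×3 | pixels, odd | smallest window resolving local texture; 5×5 supported |
| `alpha_min`, `alpha_max` | 0.4, 0.9 | exponent, `0 < α ≤ 1` | α < 1 brightens mid-range contrast; band avoids both identity (α = 1) and overshoot (α → 0) |
| `s` | 1 | shape exponent > 0 | linear feature-to-α response |
| `hist_center`, `hist_scale` | 0, π | spread units | α peaks at zero spread (flat regions protected); π-width bell |
| `entropy_coeff` `a` | 1 | scale > 0 | entropy enters only through a min–max rescaling, so `a` is a free scale |
| `R`, `A0`, `B0` | 1, 0, 0 | contrast units | R = 1 is the largest feasible local contrast; zero biases keep the transform continuous at the pivot (continuity requires B0 = 0, since B0 shifts only the lower branch) |
| `variant` | histogram | — | which feature drives α; the dataset builder always emits all three |
| working `size` | 512×512 | pixels | classifier input size; bilinear resize before enhancement; `NULL` keeps native size |

The exponent maps are clamped to `[alpha_min, alpha_max]` for any input,
and the stretched contrast to `[0, R]`. There is no generally applicable
theory for optimal `α` bounds or biases; the defaults are a compromise
between contrast gain and artifact suppression, and every run can echo
its fully resolved configuration as JSON.

## Numerical conventions and degenerate inputs

* Constant images normalize to all zeros rather than raising; every
  contrast feature is then zero, the transform's degenerate guard
  returns the map unchanged, and the reconstruction guard (`C < 1e-6`
  means unit gain) passes the image through bit-identically.
* A constant entropy or dispersion map collapses its exponent map to a
  constant (`alpha_min` for entropy, `alpha_max` for zero dispersion)
  instead of dividing by zero; windows whose memberships sum to zero
  contribute zero weighted dispersion.
* The contrast transform falls back to the identity unless
  `C_min < Ĉ < C_max` holds strictly.
* Intensity reconstruction and defuzzification round half up and clamp
  to `[0, 255]`; base R's round-half-to-even is deliberately not used so
  that results match the common imaging convention.
* Border handling is symmetric reflection (edge row/column included);
  windows are therefore always full-size, and translation equivariance
  holds for interior pixels.
* `ε_min`/`ε_max` and `σ_max` are per-image map statistics, not fixed
  constants, so the exponent always uses the image's own dynamic range.

## Dataset builder

Each source image yields exactly three enhanced outputs (histogram,
entropy, std — a fixed order matching the three classifier branches), so
an input folder of `N` images becomes `3N` outputs. The 75/15/10
train/test/validation split is assigned *at source level*, stratified by
class, with `floor(0.10·N_class)` validation and `floor(0.15·N_class)`
test sources and the remainder to train; all three variants of a source
inherit its split. Splitting before tripling is a deliberate leakage
guard: the three variants of one radiograph are near-duplicates, and
letting them straddle train and test would inflate evaluation metrics.
The split permutation is drawn from a seed mixed with the class name, so
a rerun with the same seed reproduces the manifest exactly and the
global RNG state of the caller is left untouched.

## Classifier shape calculus

The concatenated classifier has three structurally identical branches
(conv 64 → pool → conv 128 → pool → conv 256 → pool), channel
concatenation, conv 512 → pool → conv 1024 → pool, and a
1024/512 dense head with 0.5 dropout and a 2-unit softmax. Same-padding
convolutions with 2×2/stride-2 pooling are the only convention under
which the branch halving sequence 512 → 256 → 128 → 64 and the trunk
sizes 64×64×768 → 32×32×512 → 16×16×1024 are all consistent, so that
convention is applied uniformly — including to the lighter single-branch
model (conv 32/64/128, dense 256/128), which is a separate architecture,
not the concatenated trunk reused. Branch weights are independent: the
three inputs are different transforms of the same radiograph, and tied
weights would force one filter bank to serve three differently
distributed inputs. `shape_trace()` is pure integer arithmetic and needs
no deep-learning backend; `build_model()` requires one (keras or torch)
and raises a typed capability error when none is installed. The training
preset (Adam, learning rate 0.001, batch 32, 50 epochs, early stopping
with patience 10 on validation loss) realizes binary cross-entropy as
categorical cross-entropy over the 2-unit softmax, which is equivalent
for one-hot labels. No class weighting is applied by default even though
typical chest-X-ray collections are imbalanced toward pneumonia.

## The synthetic fixture generator

`generate_fixture_image()` emulates the gross structure of a chest
radiograph: a dark mediastinal background with a mild vertical gradient,
two brighter elliptical lung fields, low-contrast horizontal rib bands,
Gaussian pixel noise (sd 8 by default), and — for the pneumonia class —
a few bright Gaussian-profile opacity blobs confined to the lung fields
(three blobs of peak amplitude 40 by default), mimicking consolidation.
Every image's randomness derives from `(seed, class, index)` via a
counter-based stream split, so any subset regenerates bit-identically
regardless of order, and setting `noise_sd = 0, opacity_count = 0`
removes the class signal entirely.

What the generator does *not* emulate: anatomically plausible texture,
scanner characteristics, exposure variation, or real intensity
histograms. Tests passing on these fixtures therefore demonstrate the
*algorithmic* contracts — tripling, split hygiene, determinism, feature
and transform mathematics — not clinical image quality; no-reference
quality scoring (e.g. BRISQUE) is exposed only as a pluggable scorer
hook, never reimplemented. Test problem sizes are chosen small on
purpose: 16×16 images for the brute-force oracle comparisons, 32×32 for
the full-scale dataset-tripling run (5856 sources), and 3×3/5×5 windows
— the vectorized maps agree with naive per-pixel loops to 1e-9 relative
at those sizes, and larger images only repeat the same arithmetic.

## Known limitations

* The enhancement is contrast-driven only; it has no notion of anatomy
  and will amplify noise in near-flat regions if `alpha_min` is pushed
  low.
* `quality_report()` requires an externally supplied scorer; absolute
  quality numbers depend entirely on that scorer and are not
  reproducible from this package alone.
* `build_model()` is a constructor contract; smoke training requires a
  deep-learning backend and is exercised only where one is installed.
* 16-bit and multi-channel pipelines are out of scope; color inputs are
  collapsed to luminance with a warning.
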