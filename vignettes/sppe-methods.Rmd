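---
title: "Sub-region voting for flour-image classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-region voting for flour-image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sppe)
```

## The problem and the model

Flour milled from hulled (malting) barley cultivars carries husk fragments
and a slightly different colour than flour from hull-less (naked) cultivars.
A computer-vision system can separate the two classes from flatbed scans of
flour portions, but the discriminating evidence is partly *local*: husk
fragments and colour blemishes occupy small patches of the sample. A
descriptor computed over the whole region of interest (ROI) dilutes that
evidence; concatenating descriptors of many sub-regions preserves it but
multiplies the feature dimension by the number of regions.

The sub-region voting ensemble implemented here takes a third route. Each ROI
is partitioned into a three-level spatial pyramid: Level 0 is the ROI itself,
Level 1 its four quadrants, Level 2 the four quadrants of each Level-1 tile —
21 regions, of which the 20 Level-1/2 tiles become independent training rows.
Every tile is described by the same 55 features, a **single** classifier
$f$ is fitted on all sub-region rows (each inherits its sample's label), and
a new sample is classified by a weighted vote over its 20 tile predictions:

$$\mathrm{score}(c) \;=\; \sum_{r \in \text{L1}} w_1\,[f(x_r)=c] \;+\;
  \sum_{r \in \text{L2}} w_2\,[f(x_r)=c], \qquad
  \hat y \;=\; \arg\max_c \mathrm{score}(c),$$

with $w_1 = 1/3$ and $w_2 = 1/12$ by default, so each level contributes the
same total mass $4w_1 = 16w_2 = 4/3$ and the score mass is always
$4w_1 + 16w_2 = 8/3$. A contamination confined to one quadrant touches one
Level-1 and four Level-2 voters, shifting the score by at most
$w_1 + 4w_2 = 2/3 < 4/3$: a localized artifact can never overturn a
consistent majority, which is the robustness argument for the method. The
feature dimension stays 55 regardless of pyramid depth, versus
$21\times55 = 1155$ for the concatenated spatial-pyramid baseline (`spp`
mode) and 55-on-the-whole-ROI for the traditional baseline.

### Tie handling

With the default weights an exact $4/3$ vs $4/3$ tie is reachable (all four
Level-1 voters against all sixteen Level-2 voters). Ties are resolved by the
same model's prediction of the Level-0 region — the most holistic view of the
sample, which otherwise does not vote — and, if no Level-0 row is available,
by the training-set majority class. This is this package's completion; the
method description defines no tie rule.

## ROI extraction

The pipeline is: mean-of-RGB monochrome conversion → Otsu threshold on the
256-bin histogram (ties to the smallest threshold) → foreground mask →
4-connected hole filling → centre of mass → square growth → crop.

Choices the method description leaves open, fixed here:

* **Foreground polarity.** Flour is brighter than the scanner backing, so
  foreground is *above* the threshold; `invert_foreground = TRUE` flips to
  `<= t` (the Otsu low class is `<= t`, which matters when the dark mode sits
  exactly at the tie-broken threshold).
* **Square growth** starts at the single pixel nearest the rounded centre of
  mass and grows the side by one ring at a time, re-centring and clamping at
  the image border, while all covered pixels are foreground. On a disk of
  radius $r$ this recovers the inscribed square (side $\lfloor r\sqrt2
  \rfloor \pm 1$); on an all-true mask it recovers the whole image.
* **No extra margin** is removed beyond the mask boundary, and ROIs are not
  forced to even sides; the pyramid's floor split handles odd sides
  (first tile gets $\lfloor S/2\rfloor$ rows/columns).

ROIs smaller than 8 px per side are rejected: two halvings would produce
sub-pixel tiles.

## The 55 features

Per region: 30 colour, 6 intensity, 10 LBP, 5 co-occurrence, 4 FFT values,
in a fixed order with fixed names (`feature_names()`).

**Colour (30).** RGB is converted to HSV (all channels scaled to $[0,1]$)
and to CIE L\*a\*b\* (sRGB input, D65 white, 2° observer; L\* in $[0,100]$,
a\*/b\* native signed). For each channel: pixel mean and pixel standard
deviation, plus the standard deviation, excess kurtosis and skewness of the
channel's 256-bin histogram **counts**. The histogram statistics treat the
256 bin counts as a data series; they are deliberately distinct from the
pixel-level moments (otherwise "std of H" and "std of H histogram" would be
the same number). Histogram ranges are fixed per channel — $[0,1]$ for
H/S/V, $[0,100]$ for L\*, $[-128,128]$ for a\*/b\* — so the features are
comparable across regions.

**Intensity (6).** Intensity is the per-pixel RGB mean. Mean, standard
deviation, Shannon entropy (base 2, hence bounded by 8 bits for 256 bins) of
the normalised histogram, and the three histogram-count moments.

**LBP (10).** Rotation-invariant uniform local binary patterns, 8 discrete
radius-1 neighbours, on the intensity image. A neighbour scores 1 when
*strictly brighter* than the centre, so a flat region codes as the all-zeros
pattern (bin `lbp_0`); patterns with more than two circular 0/1 transitions
share the non-uniform bin `lbp_9`. The histogram is normalised to 1.
Interpolated circular sampling (as in some libraries) is *not* used; with
radius 1 the discrete neighbourhood is the common choice and keeps the
90°-rotation invariance exact.

**Co-occurrence (5).** Symmetric, normalised 256-level grey-level
co-occurrence matrix at offset (0, +1) — distance 1, angle 0°, no
re-quantisation. Entropy ($-\sum p\log_2 p$), inertia ($\sum(i-j)^2p$),
energy ($\sum p^2$), correlation, homogeneity ($\sum p/(1+(i-j)^2)$). A
constant region concentrates all mass in one diagonal cell: entropy and
inertia 0, energy and homogeneity 1, and correlation is *defined* as 1
(degenerate, perfectly matched pairs; the zero-variance formula is 0/0).

**FFT (4).** The method's source names four spectral statistics without
formulas; the definitions here are this package's documented completion. The
2-D DFT of the mean-subtracted intensity image gives a power spectrum; the
DC bin is removed, conjugate (Hermitian) bin pairs are **folded** into one
bin each, and the folded spectrum $P$ is normalised to 1. With $d(u,v)$ the
Euclidean frequency distance from the origin: energy $\sum P^2$, entropy
$-\sum P\log_2 P$, inertia $\sum d^2P$, homogeneity $\sum P/(1+d^2)$ —
radial distance playing the role the grey-level difference $|i-j|$ plays for
the co-occurrence statistics. Folding matters: a real single-frequency tone
splits its mass over two conjugate bins, and only after folding does it give
the intuitive extreme (energy 1, entropy 0). A spectrally empty (constant)
region returns all four as 0.

Skewness and kurtosis are moment-based throughout, kurtosis reported as
excess (normal → 0); standard deviations are population (each region is a
complete pixel population).

## Learners

Base classifiers are injected behind a `fit(X, y, meta)` / `predict(state,
X, meta)` contract (`meta` carries row provenance; learners ignore it, test
spies use it to audit grouping). Shipped learners: `knn` (FNN, Euclidean,
k = 5), `tree` (in-package CART: Gini impurity, vectorised exhaustive split
search, pruning by minimum node size 4 and depth cap 20), `forest` (bagged
CART, 100 trees, 7 features per split, seeded), `logistic` (glmnet ridge
logistic, $\lambda = 10^{-3}$). The tree and forest are implemented here
because no CART/C4.5/random-forest package is available in the target
environment; the logistic model explicitly stands in for a polynomial-kernel
SVM for the same reason. Features are z-scored with training statistics
inside `sppe_fit`, so scale-sensitive learners behave sensibly.

## Evaluation protocol

All evaluation is **grouped at the sample level**: the 20 sub-region rows of
a sample travel together. `loso_evaluate` runs leave-one-sample-out (or
grouped k-fold), re-fitting the model per fold and asserting — hard, not as
a warning — that no sample id appears on both sides. Kennard–Stone selection
(`kennard_stone_split`) operates on z-scored Level-0 descriptors, seeding
with the two mutually most distant samples and greedily adding the max–min
sample, ties to the smallest index; with 90 of 110 samples it reproduces the
canonical 81.8 % / 18.2 % split and 1800/400 sub-region rows. Metrics follow
the standard confusion-matrix definitions; zero-denominator recall/precision
is `NaN` with a warning, and reports show per-class plus macro averages
("naked" is the designated positive class in binary summaries — the source
material never states one, so both per-class rows are always emitted).

## The synthetic world

`generate_dataset` emulates the design of the original data: 14 malting +
8 naked cultivars × 5 images = 110 images (70/40). Each image is a bright
flour disk on a dark scanner background (margin 24 px of a 256² frame),
coloured in L\*a\*b\*: class mean (72, 4, 18) for malting vs (75, 1, 15) for
naked — a 3-unit gap per channel, i.e. three cultivar-offset standard
deviations ($\sigma = 1$), the "colour gap 3σ" condition — plus a
per-cultivar offset shared by a cultivar's images, per-pixel granular noise
($\sigma_L = 3$, $\sigma_{a,b} = 1$), and Poisson-placed dark elongated
ellipses ("husk fragments", 6–14 px long, 1–3 px wide) at class densities
3.5 vs 1.0 per 10⁴ px — naked flour carries fewer husk fragments, which
gives the texture features genuine class signal. Everything derives from one
seed; identical configs are bit-reproducible. `localized_artifact` corrupts
exactly one pyramid quadrant (dense dark speckle or blur) for the
robustness scenario, and `hard_cultivar = TRUE` plants one naked cultivar at
the malting colour mean, mimicking the hull-less-from-malting-genetics
confusion observed in real data.

What a green test on this world establishes — and what it does not: the
generator produces unimodal, ellipse-speckled, colour-shifted disks. It does
not model scanner optics, illumination gradients, flour clumping, focus
variation or genuine husk morphology. Passing the recovery criteria shows
the pipeline's plumbing and the ensemble arithmetic are sound and that the
method's local-contamination robustness argument holds on data with the
stated structure; it says nothing about accuracy on real barley images.

One testing subtlety: leave-one-*sample*-out keeps the held-out sample's
cultivar mates in training, so with several images per cultivar any colour
gap yields near-perfect accuracy (the analogue of the real data's
cultivar-level confusions). The monotonicity-in-gap property is therefore
tested with one image per cultivar, making LOSO a leave-one-cultivar-out
test where the configured gap is the only class signal.

## Numerical choices and degenerate inputs

* Otsu ties → smallest threshold; single-grey-level images are a named
  error, not a silent mask.
* Hole filling: 4-connected background flood (the stricter connectivity:
  diagonal-touching foreground seals a hole); idempotent by construction.
* Histogram binning: `floor(256 · (x − lo)/(hi − lo))` clamped to 0..255.
* Grey levels for texture: intensity rounded to integers 0..255.
* All-zero spectra, single-class training sets, sub-8-px ROIs, centres on
  background, and incomplete pyramids raise errors naming the offending
  sample.
* `image_side < 32` is rejected in the generator config (the disk would not
  survive ROI extraction and two halvings).

## Known limitations

* The J48 and SVM entries of the original comparison are approximated by
  CART and ridge logistic regression respectively (environment constraint,
  see the learner section); the comparison grid's *structure* is faithful,
  the learner family is not identical.
* The FFT feature formulas and histogram-moment conventions are completions,
  not recovered intent; they are fixed, documented and oracle-tested, but a
  different completion would produce different (equally valid) values.
* Pyramid depth is fixed at three levels; no overlapping or sliding windows.
* Pure-R feature extraction processes a 110-image, 256² world in about a
  minute; it is not optimised for production throughput.
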