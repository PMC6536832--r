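---
title: "Methods: segmentation evaluation and food-name standardization for buffet imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation evaluation and food-name standardization for buffet imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fakefoodr)
```

## The problem

Fake-food buffet (FFB) experiments photograph meals that participants
assemble from replica foods. Automating their analysis needs two
computations: (i) deciding, for every pixel of a photograph, which food
class it shows (semantic segmentation), and (ii) mapping each recognized
food-class *name* onto a food classification system (FoodEx2-style codes
and categories) so it can be joined to a food composition database (FCDB)
and converted into nutrient intake. `fakefoodr` implements the data
handling, augmentation, evaluation and name-standardization machinery for
this workflow. The segmentation model itself is external: any pixel-level
classifier can feed the pipeline through prediction masks, and a
nearest-palette-colour baseline closes the loop on synthetic scenes.

## Data model

A photograph is an 8-bit RGB array; its ground truth is a single-channel
label mask of identical width and height whose entries are class indices
(0 = background). Masks are stored as 8-bit single-channel PNGs holding raw
indices rather than palette colours: the encoding is lossless, round-trips
bit-identically, and validates trivially against the class registry. The
registry maps contiguous indices to food-class names and palette colours;
the buffet study setting has 55 food classes plus background. Coordinates
are row-major with the origin at the top-left and 0-based class indices.

A food *item* is one 4-connected component of one non-background class.
Connectivity had to be fixed somewhere: 4-connectivity is the conservative
choice (it never merges regions that touch only diagonally) and makes item
counts deterministic.

## Dataset split

`split_dataset()` draws a simple random split into training (70 %),
validation (10 %) and testing (20 %) subsets. Fractional subset sizes are
resolved as validation = round-half-up(0.10 N) and testing =
round-half-up(0.20 N), with training taking the remainder. For N = 121 this
gives (85, 12, 24) — the only triple consistent with a seven-variant
training expansion totalling 631 images. The split is not stratified by
food content; with a shared class pool across images, simple randomization
is adequate and keeps the procedure a pure function of the seed.

## Augmentation

Four steps, applied jointly to the image and its mask so labels stay
aligned:

* rotations by 90°, 180°, 270° (clockwise) — bijections on pixels, so the
  per-class histogram is conserved exactly; 90°/270° swap width and height;
* horizontal flip — an involution;
* additive colour noise, image only: per-pixel, per-channel Gaussian with
  `noise_sigma` (default 10 intensity units on the 0–255 scale), clipped.
  Ground-truth labels are categorical facts about the scene and must not
  change under photometric noise, so the mask is returned bit-identical.
  The noise distribution and magnitude are package choices; Gaussian noise
  at sigma 10 (≈ 4 % of the intensity range) is a conventional mild
  photometric perturbation;
* border zoom: `zoom_border` (default 0.25) of each dimension is removed in
  total — 12.5 % per side — by cropping the central
  `floor((1 − f)·dim)` window (any odd leftover pixel goes to the trailing
  side) and resizing back to the original resolution. "Removing 25 % of the
  borders" admits more than one reading; removing 25 % of each dimension,
  centred, is fixed here and configurable. The image is resized bilinearly;
  the mask with nearest-neighbour, because interpolating categorical labels
  would invent classes. Items lying wholly inside the removed border
  disappear — by design, matching what zooming does to a real photograph.

The variant set of a training pair is {original, three rotations, flip,
noise, zoom}: seven variations per image, read as *including* the original.
The arithmetic forces this reading: 85 training images × 7 + 12 + 24 = 631,
whereas an eight-variant reading would give 716. Validation and testing
pairs are never augmented.

## Segmentation measures

Evaluation pools one global confusion matrix over all evaluated images (the
elementwise sum of per-image matrices) and computes four measures on it:
pixel accuracy, mean per-class accuracy, mean IU and frequency-weighted IU,
with the background included as a class. Pooling pixels — rather than
averaging per-image scores — weights every pixel equally and matches the
"total pixels" phrasing of the measure definitions; with heterogeneous
class layouts per image the two conventions differ, so one had to be fixed.

Empty classes need a convention that never divides by zero: a class absent
from both truth and prediction is excluded from the mean accuracy and mean
IU averages; a class that is predicted but never true contributes an IU of
0 to mean IU (its recall is undefined and it is excluded from mean
accuracy). Classes absent from the truth carry zero weight in the
frequency-weighted IU by construction.

All four measures lie in [0, 1] and equal 1 exactly when the confusion
matrix is diagonal. The test suite checks the implementation against a
brute-force per-pixel double-loop oracle on masks up to 20 × 20 and
verifies invariance under simultaneous class relabeling.

## StandFood name standardization

The chain has four stages.

**Profiling.** The name is lowercased, tokenized on non-letters, stripped
of function words ("with", "and", "of", ...), tagged and lemmatized into
noun / adjective / verb lemma sets. Tagging is a bundled deterministic rule
set rather than a statistical model: lexicon adjectives are adjectives,
"-ing" tokens are verbs (gerunds), "-ed" tokens are participial adjectives,
everything else is a noun. This keeps the whole chain reproducible with no
model download, and it reproduces the practically important failure mode
that motivates the fallback: "dressing" and "herring" are not tagged as
nouns, so names like "French dressing" yield an empty noun set. The
lemmatizer strips English plural suffixes ("herrings" → "herring",
"berries" → "berry"); it is intentionally minimal and can mis-lemmatize
("tomatoes" → "tomatoe"), which is harmless here because catalogue and
query pass through the same rules.

**Retrieval and weighting.** Candidates are exactly the catalogue entries
whose name shares at least one noun lemma with the query, via a noun index
built at catalogue load. Each candidate is scored with a
part-of-speech-weighted Jaccard similarity,

```
weight = (3·|noun ∩| + 2·|adj ∩| + 1·|verb ∩|) /
         (3·|noun ∪| + 2·|adj ∪| + 1·|verb ∪|),
```

which honours noun primacy, is symmetric, bounded in [0, 1], and equals 1
iff all three lemma sets coincide — so a name that appears verbatim in the
catalogue always wins (exact-match dominance). The 3/2/1 coefficients are
configurable. Ties are broken by smaller edit distance between normalized
names, then by code, making the ranking total and the result reproducible.

**Levenshtein fallback.** When the query has no nouns, or no catalogue name
shares one, the chain switches to Levenshtein distance (unit-cost
insert/delete/substitute, case-insensitive, whole normalized names) and
returns the nearest entry. On the toy catalogue this resolves "herring" to
"herrings" (distance 1) and "French dressing" to "salad dressing".

**Classification and post-processing.** A transparent lexicon rule set
assigns one of the four FoodEx2 categories: names with ≥ 2 food nouns
joined by connectors, or containing a recipe term, are composites
(aggregated with ≥ 3 nouns or a recipe term, else simple); otherwise a
process-term hit ("dried", "smoked", "juice", "sauce", ...) makes a
derivative; otherwise raw. Post-processing reconciles this with the matched
entry's category: the match overrides the classifier only when it is strong
— weight ≥ 0.5, or fallback distance ≤ 2 — and the result is flagged. The
thresholds are package defaults chosen so that an exact or near-exact match
(which carries the catalogue's curated category) dominates the heuristic
classifier, while weak partial matches do not; both are configurable. No
accuracy claim is made for this rule classifier on real catalogues — the
published accuracies of the learned classifier it stands in for required
the full FoodEx2 and a national FCDB.

## Synthetic scenes and the baseline segmenter

`generate_scene()` emulates the *geometry* of buffet imagery: 5–15
non-overlapping food regions (discs, rectangles, blobs) per 500 × 375 scene
— buffet photographs average over eleven items — painted in each class's
palette colour plus mild uniform texture (± 8 intensity units), with the
exact class index in the mask. Items are laid out one per cell of a coarse
grid so no item occludes another and every drawn class is present. Palette
colours sit on the {0, 85, 170, 255}³ grid, so distinct classes differ by
at least 85 units in some channel; since the ± 8 texture cannot bridge half
that gap, nearest-colour decoding (`baseline_segment()`) recovers the
ground truth *exactly* — a geometric property of the fixture, not a tuned
threshold. This gives the pipeline an end-to-end identity check: scene →
baseline segmentation → evaluation must yield all four measures = 1, and
every ground-truth class must standardize and link.

What the generator does *not* emulate: photorealistic food appearance,
occlusion and stacking, illumination variation, camera noise statistics, or
class-imbalance patterns of real buffets. Tests passing on these fixtures
therefore validate the *computational* pipeline — I/O, augmentation
algebra, measure arithmetic, matching logic — not recognition performance
on photographs, which is the segmentation model's burden, out of scope
here.

`perturb_mask()` relabels each pixel independently with probability *p* to
a uniformly random *different* class, so expected pixel accuracy is exactly
1 − p and measured accuracy must fall within binomial error of it — the
recovery property used to test the evaluation stack at the 500 × 375
working resolution (187 500 pixels; 3 binomial standard deviations at
p = 0.1 is ≈ 0.002).

## Numerical and degenerate-input conventions

* Split requires N ≥ 3 (three subsets must be populable); evaluation of an
  empty subset and description against an empty catalogue are errors.
* Masks with labels outside the registry fail at read time with the
  offending value named.
* `max.col` ties in nearest-colour decoding resolve to the lowest class
  index (ties cannot occur on clean synthetic scenes; the convention
  matters only for adversarial inputs).
* All stochastic operations (split, noise, scene generation, perturbation)
  are pure functions of their integer seed via `withr::with_seed`, so runs
  are reproducible byte for byte; `run_experiment()` echoes its resolved
  config into the report.
* Test and acceptance problem sizes — scenes of 100 × 80 to 150 × 120 for
  end-to-end runs, 121 miniature pairs (12 × 9) for the augmentation
  arithmetic, one full 500 × 375 scene for the recovery property — were
  chosen so the whole suite completes in about a minute while every
  property is still exercised at a statistically meaningful size.

## Known limitations

* The rule tagger and lemmatizer are English-only and lexicon-driven;
  retargeting to another catalogue vocabulary means editing
  `standfood_lexicons()`.
* The category classifier is a transparent heuristic; on names outside its
  lexicons it defaults to "raw".
* The weighting formula and post-processing thresholds are principled
  stand-ins, not fitted to any reference corpus.
* The baseline segmenter is a decoder for synthetic palettes and is not
  meaningful on photographs; real studies should supply external prediction
  masks.
* Published study-scale accuracy figures (pixel accuracy of a trained
  network on real buffet photographs; matching accuracy against a full
  FoodEx2 and a national FCDB) are not reproducible from this package
  alone, as they require data and trained weights that are not distributed;
  the package's tests replace them with exact arithmetic, oracle-agreement
  and recovery properties.
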