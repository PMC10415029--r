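---
title: "Methods: from labeled image streams to nutrient intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from labeled image streams to nutrient intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutricam)
```

## The problem

Wearable-camera dietary assessment pairs an egocentric camera (one image
every 10–15 s over a wear day) with sensor-based food-intake detection that
labels each image 0 (no intake) or 1 (intake). A human annotator then
identifies the foods visible in the intake images and estimates portions,
and nutrient intake is computed against food-composition databases.
Reviewing every image of a day is prohibitively slow; the central economy
of the approach is that only images inside detected eating episodes need
review. `nutricam` is a headless implementation of this pipeline: the
upstream intake classifier and the image pixels themselves are out of its
scope — it consumes the labels, and replaces the interactive GUI with a
scriptable annotation model.

## Episode segmentation

Let the intake-labeled images of a day have timestamps $t_1 < \dots < t_k$
and let $\Delta$ be the capture interval. Each intake image is treated as
occupying $[t_i, t_i + \Delta)$. Two consecutive intake images belong to
the same episode when the non-intake time between them,
$t_{i+1} - t_i - \Delta$, is at most the merge gap $g$; maximal chains
under this relation form episodes. An episode therefore starts at its first
intake image and ends at its last intake image plus $\Delta$, so a lone
intake image spans one capture interval. Episodes whose merged run contains
fewer than `min_images` intake images are dropped, and the dropped image
ids are returned in an attribute so no intake evidence disappears silently.

Two parameters matter:

* `merge_gap` (seconds, default **60**): non-intake time bridged within an
  episode. Intake detection operates on short epochs, and chewing pauses,
  conversation or a put-down fork produce brief label gaps inside a real
  meal; at a 15 s capture interval a 60 s gap tolerates up to four
  consecutive missed images. Detection-performance figures in this domain
  are conventionally computed on comparable sub-minute smoothing windows.
* `min_images` (default **1**): minimum intake images per episode. The
  default keeps every detection, leaving the true/false judgement to the
  reviewer rather than to a threshold; raising it trades recall for fewer
  spurious single-image episodes.

The implementation is vectorized (run-length grouping over the gap
predicate). The test suite checks it against a deliberately different
brute-force oracle — every intake image starts as its own one-interval
episode and adjacent episodes are merged pairwise until fixpoint — over a
thousand random label sequences with randomized interval, gap and
minimum-image settings.

## Review burden

For projects totalling $T$ images of which $D$ fall inside detected
episodes, the reviewed share is $100\,D/T$ percent and the review reduction
is $100 - 100\,D/T$; the two are complementary by construction, and display
values round half away from zero to whole percents while machine-readable
output keeps full precision. Whether "detected images" should count
in-episode images or individually labeled-1 images is ambiguous in
study-level reporting; `review_metrics()` reports both (`detected_images`
and `labeled_images`) and uses the in-episode count for the percentage,
since that is the set a reviewer actually opens.

## Food-composition databases

Composition tables are published as CSV in house dialects. A declarative
column map (YAML, shipped in `inst/extdata/dialects.yaml`, overridable)
describes each dialect: id/description/group columns, the energy column
and unit, per-100 g nutrient columns with units, and one of three
portion-table encodings (paired description/weight columns; a single
household serving; an inline `label=grams; ...` column). Loading unifies
rows into one record model with these conventions:

* Energy is standardized to kcal at load (kJ sources divided by 4.184);
  no other cross-database standardization is attempted — values reflect
  each table's local recipes and analytical conventions, and harmonizing
  them is a research task, not a loading step.
* Cells that fail numeric parsing (after handling thousands separators and
  simple fractions) become missing values, never zero; missingness is
  carried through to summaries as completeness flags, because zero-filling
  would silently bias totals downward.
* Rows without an id or description are skipped and counted.
* Every record gains a synthesized `gram` portion of weight exactly 1 if
  its source lacks one, so direct gram entry is always possible.

Search uses four rank tiers on the case-folded description — exact match,
prefix, all query tokens present, substring — with ties broken by database
priority then food id. The tier scheme is this package's own design (no
published convention exists for this tool class); it is deterministic by
construction, which the tests assert.

## Annotation model

An annotation session holds the sensor-episode verdicts (true/false, last
verdict wins, re-review allowed), the annotator-created eating episodes,
and their food items. Meal labels are free text with
breakfast/lunch/dinner/snack as the expected values. A meal's start/end can
be explicit or auto-populated as the min/max of linked-image timestamps
(max extended by one capture interval); auto-population is idempotent in
the linked set. Meals may overlap in time and an image may be linked to
two meals — a drink can genuinely span a meal — but both produce warnings
since they usually indicate a slip. Sessions persist as versioned JSON;
derived quantities are recomputed from the recorded portions at load, so
the file stores only primary annotator input. The same file is the batch
input for the headless CLI.

## Portion arithmetic

Annotators enter amounts as decimals or simple fractions ("1/3", "2 1/2").
Amounts are exact rationals throughout: consumed = initial − leftover is
computed on numerator/denominator pairs, so one cup minus a third of a cup
is exactly two thirds — not 0.66666…7. When initial and leftover are in
different portion units both are converted to grams through the food's
portion-weight table, subtracted there, and re-expressed in the initial
unit; when the units agree this reduces to the same exact subtraction. A
leftover exceeding the initial amount (compared in grams) is an error.
Grams are `amount × gram_weight(portion)`; nutrients scale linearly,
`value_per_100g × grams / 100`. Totals roll up item → episode → day by
summation in insertion order at each level, which makes the conservation
identities bit-exact, and missing source nutrients are excluded from sums
and counted in a per-nutrient incompleteness column.

Reports render grams and kcal to 2 decimals (re-parsing agrees with memory
to half a rendering unit), durations as hh:mm:ss, and CSV is the canonical
export format — dependency-light, diffable, and losslessly re-parseable,
where a spreadsheet mirror would add nothing computational.

## Synthetic data: what it emulates and what it does not

`simulate_day()` emulates the capture regime, not the sensor physics: images
at a fixed cadence over a wear period, ground-truth eating episodes, and
independent per-image Bernoulli label noise (probability `fp_rate` of a
spurious intake label outside episodes, `fn_rate` of a missed one inside).
The defaults describe a realistic field day: 12.5 h imaged every 15 s
(3000 images) with four meals of 12, 15, 8 and 16 minutes — 204 in-episode
images and a 6.8% reviewed share, matching the order of magnitude reported
for real deployments (≈3000 images/day, ≈200 food images, ≈7% reviewed).
Independence is the simplest falsifiable noise model; real classifier
errors are temporally correlated (a chewing bout missed is missed for
several epochs), so passing recovery tests here demonstrates the
segmentation logic, not field performance. Published upstream
classification figures (≈87% F1, 17.3% false-negative rate) describe real
sensor data and are deliberately not simulation targets; `fn_rate = 0.17`
is used in tests only as a plausible stress level.

`toy_food_truth()` generates food tables with macronutrient-consistent
energy (4/4/9 kcal/g for protein/carbohydrate/fat plus noise), a
configurable share of missing nutrient cells (default 5%), and random
portion tables; the same seed renders identical logical content into every
dialect, which is what makes dialect-equivalence testable. Toy databases
are tiny stand-ins for real composition tables and make no nutritional
claims.

`evaluate_detection()` matches detected to true episodes by temporal
overlap (any overlap by default; a minimum-overlap fraction of the truth
episode is configurable). With zero detections precision is undefined and
reported as 0 with an explicit flag. Episode-level precision/recall/F1 and
image-level confusion counts are both reported.

## Numerical and degenerate-input choices

* Rational amounts reduce by GCD; decimals with up to 9 places are exact;
  pathological doubles degrade to double precision rather than erroring.
* Timestamps are UTC instants; comparisons never go through wall-clock
  strings. Projects require strictly increasing timestamps and reject
  labels outside {0, 1}.
* All-zero label days yield an empty episode list, not an error; an empty
  annotation day summarizes to zeros; an empty registry refuses to search.
* Display rounding is half-away-from-zero (13/200 → 6.5% → 7%), matching
  how study tables are conventionally rounded, and is applied only at
  display time. Published Ghana-study counts round to 14% under this rule
  while the source table prints 15%; the package reports what it computes.

## Problem sizes used in the checks

The shipped verification uses 1000 random label sequences of length
10–5000 for oracle equivalence, 100 simulated annotated days for the
conservation identities, 200 noisy days (FP 2%, FN 17%) for episode
recall, and 20 noise-free days for exact boundary recovery; the acceptance
script re-runs scaled versions of the same computations from a single seed.
These sizes give stable statistics for the properties being checked while
keeping a full run in a few minutes on one core.

## Known limitations

* Portion estimation accuracy is the annotator's, not the software's; no
  image-based portion inference is attempted.
* No nutrient imputation or recipe decomposition: a missing nutrient stays
  missing, a composite dish is whatever its database row says.
* Cross-database totals mix each table's conventions; the completeness
  flags mark missingness but not methodological heterogeneity.
* The label-noise model is independent Bernoulli; temporally correlated
  classifier errors will merge or split episodes in ways the simulations
  do not exercise.
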