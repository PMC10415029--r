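# nutricam

Headless dietary assessment from wearable-camera image streams.

Egocentric cameras (typically eyeglasses-mounted, imaging every 10–15 s)
paired with chewing/motion sensors produce, for each participant-day,
thousands of images each carrying a binary food-intake label from an
upstream classifier. Turning that stream into nutrition data requires four
steps that `nutricam` implements as a library plus a small CLI:

1. **Episode segmentation** — contiguous runs of intake-labeled images
   become sensor-detected eating episodes (SDEEps). Runs separated by at
   most `merge_gap` seconds of non-intake time are merged; episodes with
   fewer than `min_images` intake images are dropped (and reported). An
   episode spans from its first intake image to its last plus one capture
   interval.
2. **Sensor-guided review** — only in-episode images need human review.
   `review_metrics()` quantifies the saving: with `T` total and `D`
   in-episode images, the reviewed share is `100·D/T` percent and the
   review reduction is `100 − 100·D/T` percent.
3. **Annotation** — reviewers mark each SDEEp true/false, create annotated
   eating episodes (meals/snacks) with linked images, and attach food items
   matched against any combination of food-composition databases
   (USDA-SR-like, FNDDS-like, branded-products-like and FAO-table CSV
   dialects are supported out of the box).
4. **Nutrient computation** — per item, consumed amount = initial −
   leftover (exact rational arithmetic: 1 cup − 1/3 cup = 2/3 cup,
   exactly), converted to grams through the food's portion-weight table,
   then scaled against per-100 g nutrient values:
   `nutrient = value_per_100g · grams / 100`. Totals roll up item → episode
   → day with missing source nutrients flagged, never zero-filled.

A synthetic-data module generates toy food databases in every supported
dialect and simulated participant-days with known ground-truth episodes and
configurable per-image false-positive/false-negative label rates, plus an
episode-level precision/recall/F1 evaluator.

## Worked example

```r
library(nutricam)

# a simulated 12.5 h day: 3000 images at 15 s, four meals, 204 intake images
sim <- simulate_day(seed = 1)
eps <- detect_episodes(sim$project)          # 4 episodes
review_metrics(sim$project, eps)[, c("total_images", "detected_images",
                                     "pct_reviewed", "pct_reviewed_display")]
#> # A tibble: 1 × 4
#>   total_images detected_images pct_reviewed pct_reviewed_display
#>          <int>           <int>        <dbl>                <dbl>
#> 1         3000             204          6.8                    7
```

Only 204 of 3000 images (6.8%, displayed 7%) fall inside eating episodes —
the share a reviewer must actually look at.

```r
# annotate: a toy database, one meal, one food with a leftover
csv <- tempfile(fileext = ".csv")
make_toy_database("sr", n_foods = 20, seed = 1, path = csv)
reg <- register_db(food_registry(), load_food_db(csv, "sr", "toy"))
rec <- search_foods(reg, "rice")[1, ]

day <- day_annotation(sim$project, eps)
day <- review_episode(day, 1, "true")
day <- add_meal(day, "lunch")
day <- add_food_item(day, 1, rec, "solid",
                     initial_amount = "1", initial_portion = "teaspoon",
                     leftover_amount = "1/3", leftover_portion = "teaspoon")
food_items(day)[, c("description", "consumed_amount", "consumed_grams", "energy_kcal")]
#> # A tibble: 1 × 4
#>   description  consumed_amount consumed_grams energy_kcal
#>   <chr>        <chr>                    <dbl>       <dbl>
#> 1 Rice, stewed 2/3                        3.8        9.33
```

The consumed amount is the exact fraction 2/3 of a teaspoon; this food's
teaspoon weighs 5.7 g, so 2/3 × 5.7 = 3.8 g consumed, scaled against the
record's per-100 g energy. `summarize_meals()`,
`summarize_day()`, `export_report()` and `db_usage_report()` aggregate and
export the Table-style outputs; `autoplot()` draws the label timeline and
per-meal energy.

## CLI

`exec/nutricam` wraps the same functions for shell use:

```sh
nutricam simulate --seed 5 --out outdir
nutricam episodes --project outdir/project.json --merge-gap 60
nutricam metrics  --project outdir/project.json
nutricam db-search --query rice --path outdir/toydb_sr.csv --dialect sr --name sr
```

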