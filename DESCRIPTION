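Package: nutricam
Title: Sensor-Guided Annotation and Nutrient Analysis for Wearable-Camera
    Dietary Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Headless toolkit for dietary assessment from wearable-camera
    image streams with per-image food-intake labels. Derives sensor-detected
    eating-episode boundaries from binary label runs, restricts human review
    to in-episode images and quantifies the resulting review burden, loads
    heterogeneous food-composition database CSV dialects into a unified
    searchable registry, records annotated eating episodes with food items
    and portions, converts initial/leftover portions to consumed grams via
    per-food portion-weight tables, computes energy and nutrient intake on a
    per-100 g basis, and exports item, episode and daily summary tables.
    Includes a synthetic-data generator for image streams and toy food
    databases with known ground truth, and an episode-level detection
    evaluator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
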