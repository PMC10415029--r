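#' Toy food-composition ground truth
#'
#' Deterministically generates a plausible food table: descriptions composed
#' from base foods and preparations, food groups, per-100 g nutrient values
#' and a portion-weight table per food. The same seed always produces the
#' same logical content, so the same truth can be rendered into any CSV
#' dialect and the loaded records compared field-by-field.
#'
#' @param n_foods number of foods (>= 1).
#' @param seed RNG seed.
#' @param missing_rate share of non-energy nutrient cells left empty,
#'   emulating incomplete composition tables (default 0.05).
#' @return a tibble: `food_key` (1..n), `description`, `group`,
#'   `energy_kcal`, `protein_g`, `fat_g`, `carbohydrate_g`, `fiber_g`,
#'   `calcium_mg`, `iron_mg`, and a `portions` list-column
#'   (`label`/`gram_weight`).
#' @export
toy_food_truth <- function(n_foods, seed = 1, missing_rate = 0.05) {
  if (n_foods < 1) stop("n_foods must be >= 1", call. = FALSE)
  withr::local_seed(seed)
  bases <- c(
    "Rice", "Beans", "Chicken", "Beef", "Fish", "Maize", "Cassava",
    "Plantain", "Yam", "Milk", "Bread", "Egg", "Groundnut", "Spinach",
    "Tomato", "Potato", "Sorghum", "Millet", "Banana", "Orange"
  )
  preps <- c(
    "raw", "boiled", "fried", "roasted", "stewed", "steamed", "dried",
    "grilled", "baked", "porridge"
  )
  groups <- c(
    "Cereals and grains", "Legumes", "Meat and poultry", "Fish",
    "Vegetables", "Fruits", "Dairy and eggs", "Roots and tubers"
  )
  measures <- c("cup", "tablespoon", "teaspoon", "piece", "slice", "serving")
  measure_g <- c(cup = 240, tablespoon = 15, teaspoon = 5, piece = 60,
    slice = 30, serving = 150)

  desc <- character(n_foods)
  used <- character(0)
  for (i in seq_len(n_foods)) {
    repeat {
      d <- paste0(
        sample(bases, 1), ", ", sample(preps, 1),
        if (stats::runif(1) < 0.3) paste0(", ", sample(c("with salt", "no salt added", "local recipe"), 1)) else ""
      )
      if (!d %in% used) break
    }
    used <- c(used, d)
    desc[i] <- d
  }

  protein <- round(stats::runif(n_foods, 0, 30), 2)
  fat <- round(stats::runif(n_foods, 0, 40), 2)
  carb <- round(stats::runif(n_foods, 0, 80), 2)
  energy <- round(4 * protein + 9 * fat + 4 * carb + stats::runif(n_foods, -10, 10), 1)
  energy <- pmax(energy, 5)

  blank <- function(x) {
    x[stats::runif(length(x)) < missing_rate] <- NA_real_
    x
  }

  portions <- lapply(seq_len(n_foods), function(i) {
    k <- sample(0:3, 1)
    labs <- if (k > 0) sample(measures, k) else character(0)
    tibble::tibble(
      label = labs,
      gram_weight = round(unname(measure_g[labs]) * stats::runif(k, 0.8, 1.2), 1)
    )
  })

  tibble::tibble(
    food_key = seq_len(n_foods),
    description = desc,
    group = sample(groups, n_foods, replace = TRUE),
    energy_kcal = energy,
    protein_g = blank(protein),
    fat_g = blank(fat),
    carbohydrate_g = blank(carb),
    fiber_g = blank(round(stats::runif(n_foods, 0, 12), 2)),
    calcium_mg = blank(round(stats::runif(n_foods, 0, 300), 1)),
    iron_mg = blank(round(stats::runif(n_foods, 0, 15), 2)),
    portions = portions
  )
}

#' Write a toy food-composition CSV in a given dialect
#'
#' Renders a [toy_food_truth()] table into one of the supported CSV dialects
#' (see [food_dialects()]). The same seed yields the same logical content in
#' every dialect, enabling dialect-equivalence tests: loading any rendering
#' must produce the same unified records.
#'
#' @param dialect one of [food_dialects()].
#' @param n_foods number of foods.
#' @param seed RNG seed.
#' @param path output CSV path.
#' @param truth optionally, a precomputed [toy_food_truth()] table to render.
#' @return a list: `path`, `truth`.
#' @export
make_toy_database <- function(dialect, n_foods = 25, seed = 1, path,
                              truth = NULL) {
  maps <- load_dialect_maps()
  if (!dialect %in% names(maps)) {
    stop("unknown dialect '", dialect, "'", call. = FALSE)
  }
  if (is.null(truth)) truth <- toy_food_truth(n_foods, seed)

  fmt <- function(x) {
    ifelse(is.na(x), "",
      format(x, trim = TRUE, scientific = FALSE, digits = 15)
    )
  }
  id <- switch(dialect,
    sr = sprintf("%05d", 1000 + truth$food_key),
    fndds = as.character(11000000 + truth$food_key),
    branded = as.character(400000 + truth$food_key),
    fao = sprintf("F%04d", truth$food_key)
  )

  p1 <- purrr::map(truth$portions, function(p) {
    if (nrow(p) >= 1) list(lab = p$label[1], wt = p$gram_weight[1]) else list(lab = "", wt = NA_real_)
  })
  p2 <- purrr::map(truth$portions, function(p) {
    if (nrow(p) >= 2) list(lab = p$label[2], wt = p$gram_weight[2]) else list(lab = "", wt = NA_real_)
  })

  out <- switch(dialect,
    sr = tibble::tibble(
      NDB_No = id,
      Shrt_Desc = truth$description,
      FdGrp_Desc = truth$group,
      Energ_Kcal = fmt(truth$energy_kcal),
      `Protein_(g)` = fmt(truth$protein_g),
      `Lipid_Tot_(g)` = fmt(truth$fat_g),
      `Carbohydrt_(g)` = fmt(truth$carbohydrate_g),
      `Fiber_TD_(g)` = fmt(truth$fiber_g),
      `Calcium_(mg)` = fmt(truth$calcium_mg),
      `Iron_(mg)` = fmt(truth$iron_mg),
      GmWt_Desc1 = purrr::map_chr(p1, "lab"),
      GmWt_1 = fmt(purrr::map_dbl(p1, "wt")),
      GmWt_Desc2 = purrr::map_chr(p2, "lab"),
      GmWt_2 = fmt(purrr::map_dbl(p2, "wt"))
    ),
    fndds = tibble::tibble(
      `Food code` = id,
      `Main food description` = truth$description,
      `WWEIA Category description` = truth$group,
      `Energy (kcal)` = fmt(truth$energy_kcal),
      `Protein (g)` = fmt(truth$protein_g),
      `Total Fat (g)` = fmt(truth$fat_g),
      `Carbohydrate (g)` = fmt(truth$carbohydrate_g),
      `Dietary fiber (g)` = fmt(truth$fiber_g),
      `Calcium (mg)` = fmt(truth$calcium_mg),
      `Iron (mg)` = fmt(truth$iron_mg),
      `Portion description 1` = purrr::map_chr(p1, "lab"),
      `Portion weight 1 (g)` = fmt(purrr::map_dbl(p1, "wt")),
      `Portion description 2` = purrr::map_chr(p2, "lab"),
      `Portion weight 2 (g)` = fmt(purrr::map_dbl(p2, "wt"))
    ),
    branded = tibble::tibble(
      fdc_id = id,
      description = truth$description,
      branded_food_category = truth$group,
      calories_per_100g = fmt(truth$energy_kcal),
      protein_per_100g = fmt(truth$protein_g),
      fat_per_100g = fmt(truth$fat_g),
      carbohydrate_per_100g = fmt(truth$carbohydrate_g),
      fiber_per_100g = fmt(truth$fiber_g),
      calcium_per_100g = fmt(truth$calcium_mg),
      iron_per_100g = fmt(truth$iron_mg),
      household_serving_fulltext = purrr::map_chr(p1, "lab"),
      serving_size_g = fmt(purrr::map_dbl(p1, "wt"))
    ),
    fao = tibble::tibble(
      Code = id,
      `Food name` = truth$description,
      Group = truth$group,
      `Energy (kJ)` = fmt(truth$energy_kcal * 4.184),
      `Protein (g)` = fmt(truth$protein_g),
      `Fat (g)` = fmt(truth$fat_g),
      `Carbohydrate (g)` = fmt(truth$carbohydrate_g),
      `Fibre (g)` = fmt(truth$fiber_g),
      `Calcium (mg)` = fmt(truth$calcium_mg),
      `Iron (mg)` = fmt(truth$iron_mg),
      Portions = purrr::map_chr(truth$portions, function(p) {
        if (nrow(p) == 0) "" else paste(p$label, p$gram_weight, sep = "=", collapse = "; ")
      })
    )
  )
  readr::write_csv(out, path, na = "")
  list(path = path, truth = truth)
}

#' Simulate a participant-day image stream with intake labels
#'
#' Generates one wearable-camera day at a fixed capture cadence with known
#' ground-truth eating episodes and per-image Bernoulli label noise: inside
#' a true episode an image is labeled intake with probability `1 - fn_rate`,
#' outside with probability `fp_rate`. The defaults emulate a realistic
#' recording day: a 12.5 h wear period imaged every 15 s (3000 images) with
#' four eating episodes (12, 15, 8 and 16 minutes — 51 min of eating, 204
#' in-episode images, a 6.8% reviewed share).
#'
#' @param seed RNG seed; a fixed seed reproduces the project byte-for-byte.
#' @param day_length_h wear duration in hours.
#' @param capture_interval seconds between images (default 15).
#' @param true_episodes data frame with `offset_s` (episode start relative to
#'   the first image) and `duration_s`; episodes must not overlap.
#' @param fp_rate,fn_rate per-image false-positive / false-negative label
#'   rates in `[0, 1]`.
#' @param participant_id,day_id,start_time identifiers for the generated
#'   project; recording starts at `start_time` on `day_id`.
#' @return a list: `project` (a [camera_project()]) and `truth` (tibble of
#'   ground-truth episode `start`/`end` instants).
#' @examples
#' sim <- simulate_day(seed = 42, fp_rate = 0.02, fn_rate = 0.17)
#' sim$truth
#' @export
simulate_day <- function(seed = 1, day_length_h = 12.5, capture_interval = 15,
                         true_episodes = default_true_episodes(),
                         fp_rate = 0, fn_rate = 0,
                         participant_id = "sim", day_id = "2024-05-01",
                         start_time = "06:00:00") {
  if (fp_rate < 0 || fp_rate > 1 || fn_rate < 0 || fn_rate > 1) {
    stop("fp_rate and fn_rate must lie in [0, 1]", call. = FALSE)
  }
  true_episodes <- tibble::as_tibble(true_episodes)
  stopifnot(all(c("offset_s", "duration_s") %in% names(true_episodes)))
  eps <- dplyr::arrange(true_episodes, .data$offset_s)
  if (nrow(eps) > 1) {
    gap_ok <- eps$offset_s[-1] >= (eps$offset_s + eps$duration_s)[-nrow(eps)]
    if (!all(gap_ok)) stop("true episodes must not overlap", call. = FALSE)
  }
  day_s <- day_length_h * 3600
  if (any(eps$offset_s < 0 | eps$offset_s + eps$duration_s > day_s)) {
    stop("true episodes must lie within the day", call. = FALSE)
  }

  withr::local_seed(seed)
  t0 <- parse_instant(paste(day_id, start_time))
  offsets <- seq(0, day_s - capture_interval, by = capture_interval)
  ts <- t0 + offsets
  inside <- rep(FALSE, length(offsets))
  for (i in seq_len(nrow(eps))) {
    inside <- inside |
      (offsets >= eps$offset_s[i] & offsets < eps$offset_s[i] + eps$duration_s[i])
  }
  p_one <- ifelse(inside, 1 - fn_rate, fp_rate)
  label <- as.integer(stats::runif(length(offsets)) < p_one)

  project <- camera_project(
    participant_id, day_id, capture_interval,
    tibble::tibble(
      image_id = sprintf("img%05d", seq_along(offsets)),
      timestamp = ts,
      label = label
    )
  )
  truth <- tibble::tibble(
    episode_id = seq_len(nrow(eps)),
    start = t0 + eps$offset_s,
    end = t0 + eps$offset_s + eps$duration_s
  )
  list(project = project, truth = truth)
}

#' @rdname simulate_day
#' @export
default_true_episodes <- function() {
  tibble::tibble(
    offset_s = c(1.5, 6, 9, 11) * 3600,
    duration_s = c(12, 15, 8, 16) * 60
  )
}

#' Score detected episodes against ground truth
#'
#' Episode-level precision/recall/F1 under an interval-overlap matching
#' rule: a detected episode is a true positive when its overlap with some
#' ground-truth episode is at least `min_overlap` of that truth episode's
#' duration (default any positive overlap); a truth episode is recovered
#' when some detection matches it. With zero detections and nonzero truth,
#' precision is undefined and reported as 0 with `precision_undefined =
#' TRUE`. When the project is supplied, image-level confusion counts
#' (label vs ground-truth occupancy) are included.
#'
#' @param truth ground-truth episode tibble (`start`/`end`).
#' @param detected a [detect_episodes()] tibble.
#' @param min_overlap minimum overlap fraction of the truth episode
#'   (0 = any temporal overlap).
#' @param project optional [camera_project()] for image-level counts.
#' @return a one-row tibble: `n_truth`, `n_detected`, `tp_detected`,
#'   `truth_recovered`, `precision`, `recall`, `f1`,
#'   `precision_undefined`, and (with a project) `img_tp`, `img_fp`,
#'   `img_fn`, `img_tn`.
#' @export
evaluate_detection <- function(truth, detected, min_overlap = 0,
                               project = NULL) {
  truth <- tibble::as_tibble(truth)
  detected <- tibble::as_tibble(detected)
  overlap_s <- function(a1, a2, b1, b2) {
    pmax(0, as.numeric(pmin(a2, b2)) - as.numeric(pmax(a1, b1)))
  }
  matches <- function(d_start, d_end) {
    if (nrow(truth) == 0) {
      return(logical(0))
    }
    ov <- overlap_s(d_start, d_end, truth$start, truth$end)
    need <- if (min_overlap > 0) {
      min_overlap * as.numeric(truth$end - truth$start, units = "secs")
    } else {
      0
    }
    if (min_overlap > 0) ov >= need else ov > 0
  }
  tp_flags <- vapply(seq_len(nrow(detected)), function(i) {
    any(matches(detected$start[i], detected$end[i]))
  }, logical(1))
  recovered <- vapply(seq_len(nrow(truth)), function(j) {
    if (nrow(detected) == 0) {
      return(FALSE)
    }
    ov <- overlap_s(truth$start[j], truth$end[j], detected$start, detected$end)
    need <- if (min_overlap > 0) {
      min_overlap * as.numeric(truth$end[j] - truth$start[j], units = "secs")
    } else {
      0
    }
    if (min_overlap > 0) any(ov >= need) else any(ov > 0)
  }, logical(1))

  n_det <- nrow(detected)
  n_tru <- nrow(truth)
  precision_undefined <- n_det == 0
  precision <- if (n_det == 0) 0 else sum(tp_flags) / n_det
  recall <- if (n_tru == 0) 1 else sum(recovered) / n_tru
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  out <- tibble::tibble(
    n_truth = n_tru,
    n_detected = n_det,
    tp_detected = sum(tp_flags),
    truth_recovered = sum(recovered),
    precision = precision,
    recall = recall,
    f1 = f1,
    precision_undefined = precision_undefined
  )
  if (!is.null(project)) {
    ts <- project$images$timestamp
    in_truth <- rep(FALSE, length(ts))
    for (j in seq_len(n_tru)) {
      in_truth <- in_truth | (ts >= truth$start[j] & ts < truth$end[j])
    }
    lab <- project$images$label == 1L
    out$img_tp <- sum(lab & in_truth)
    out$img_fp <- sum(lab & !in_truth)
    out$img_fn <- sum(!lab & in_truth)
    out$img_tn <- sum(!lab & !in_truth)
  }
  out
}

#' Simulate an annotation session over detected episodes
#'
#' Builds a complete annotated day for testing and demonstration: detects
#' episodes on the project, marks each as a true detection, creates one meal
#' per episode (cycling breakfast/lunch/snack/dinner), links the in-episode
#' images, and attaches 1–4 food items per meal drawn from the registry with
#' random portions and leftovers. The session timestamps are set so the
#' annotation duration is defined.
#'
#' @param project a [camera_project()].
#' @param registry a [food_registry()] with at least one database.
#' @param seed RNG seed.
#' @param episodes optional [detect_episodes()] tibble.
#' @return a [day_annotation()].
#' @export
simulate_annotations <- function(project, registry, seed = 1,
                                 episodes = NULL) {
  stopifnot(inherits(project, "camera_project"), inherits(registry, "food_registry"))
  if (length(registry$dbs) == 0) stop("registry is empty", call. = FALSE)
  withr::local_seed(seed)
  if (is.null(episodes)) episodes <- detect_episodes(project)
  started <- max(project$images$timestamp) + 3600
  day <- day_annotation(project, episodes, started = started)
  labels <- c("breakfast", "lunch", "snack", "dinner")
  dbs <- names(registry$dbs)
  amounts <- c("1", "1/2", "1/3", "2/3", "3/4", "1 1/2", "2", "0.5", "150")
  for (i in seq_len(nrow(episodes))) {
    day <- review_episode(day, episodes$episode_id[i], "true")
    day <- add_meal(day, labels[(i - 1) %% length(labels) + 1])
    id <- length(day$meals)
    imgs <- episode_images(project, episodes[i, ])
    linked <- imgs$image_id[imgs$label == 1L]
    if (length(linked) == 0) linked <- imgs$image_id[1]
    for (im in linked) day <- link_image(day, id, im)
    for (k in seq_len(sample(1:4, 1))) {
      db <- sample(dbs, 1)
      recs <- registry$dbs[[db]]$records
      rec <- recs[sample(nrow(recs), 1), ]
      opts <- portion_options(rec)
      portion <- sample(opts$label, 1)
      initial <- sample(amounts, 1)
      # leftover: none, or a proper fraction of the initial amount
      leftover <- if (stats::runif(1) < 0.5) {
        "0"
      } else {
        format(parse_amount(initial) * parse_amount(sample(c("1/4", "1/3", "1/2"), 1)))
      }
      day <- add_food_item(day, id, rec,
        form = sample(c("solid", "liquid", "semi-solid"), 1),
        initial_amount = initial, initial_portion = portion,
        leftover_amount = leftover, leftover_portion = portion
      )
    }
  }
  day$finished <- started + stats::rpois(1, 1093)
  day
}
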