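#' Consumed amount from initial and leftover portions
#'
#' The consumed amount of a food item is the initial amount minus the
#' leftover amount. When both are recorded in the same portion unit the
#' subtraction is exact rational arithmetic: an initial amount of 1 cup with
#' a leftover of 1/3 cup gives a consumed amount of exactly 2/3 cup. When
#' the two portions differ (say a cup served, tablespoons left over), both
#' are converted to grams through the food's portion-weight table, subtracted
#' there, and the result is expressed back in the initial portion's units —
#' which reduces to the same-unit subtraction whenever the units agree.
#'
#' @param initial initial amount: number, fraction string or
#'   [parse_amount()] result.
#' @param leftover leftover amount (default 0).
#' @param initial_portion,leftover_portion portion labels; needed only when
#'   they differ, together with `portions`.
#' @param portions a portion-option tibble ([portion_options()]) used to
#'   convert between differing portion units.
#' @return an exact amount (`nc_amount`) in the initial portion's units.
#' @examples
#' consumed_amount(1, "1/3") # exactly 2/3
#' @export
consumed_amount <- function(initial, leftover = 0, initial_portion = NULL,
                            leftover_portion = NULL, portions = NULL) {
  initial <- parse_amount(initial)
  leftover <- parse_amount(leftover)
  if (as.numeric(leftover) < 0) {
    stop("leftover amount must be >= 0", call. = FALSE)
  }
  same_unit <- is.null(initial_portion) || is.null(leftover_portion) ||
    identical(initial_portion, leftover_portion)
  if (same_unit) {
    if (leftover > initial) {
      stop("leftover exceeds the initial amount", call. = FALSE)
    }
    return(initial - leftover)
  }
  if (is.null(portions)) {
    stop("portions table required when initial and leftover portions differ",
      call. = FALSE
    )
  }
  gi <- portion_weight(portions, initial_portion)
  gl <- portion_weight(portions, leftover_portion)
  grams <- as.numeric(initial) * gi - as.numeric(leftover) * gl
  if (grams < 0) {
    stop("leftover exceeds the initial amount (in grams)", call. = FALSE)
  }
  parse_amount(grams / gi)
}

portion_weight <- function(portions, label) {
  i <- which(portions$label == label)
  if (length(i) != 1) {
    stop("unknown portion '", label, "'", call. = FALSE)
  }
  portions$gram_weight[i]
}

#' Convert a portion amount to grams
#'
#' Grams are the amount times the gram weight of one unit of the portion,
#' taken from the food's portion-weight table.
#'
#' @param amount a number, fraction string or amount object; must be >= 0.
#' @param portion portion label.
#' @param portions portion-option tibble ([portion_options()]).
#' @return grams (numeric).
#' @examples
#' opts <- tibble::tibble(label = c("cup", "gram"), gram_weight = c(240, 1))
#' amount_to_grams("2/3", "cup", opts) # 160
#' @export
amount_to_grams <- function(amount, portion, portions) {
  amount <- as.numeric(parse_amount(amount))
  if (amount < 0) stop("amount must be >= 0", call. = FALSE)
  amount * portion_weight(portions, portion)
}

#' Energy and nutrients for a consumed weight
#'
#' Scales a food record's per-100 g nutrient values to a consumed weight:
#' each nutrient contributes `value * grams / 100`. Nutrients missing in the
#' source record stay missing and are listed in `missing_nutrients` so that
#' downstream totals can be flagged as incomplete instead of silently
#' treating the gap as zero.
#'
#' @param grams consumed weight in grams (>= 0).
#' @param record one-row food records tibble.
#' @return a list: `grams`, `energy_kcal`, `nutrients` (tibble of
#'   `nutrient`/`value`/`unit` scaled to the consumed weight; missing values
#'   stay `NA`), `missing_nutrients` (character).
#' @export
nutrient_intake <- function(grams, record) {
  if (grams < 0) stop("grams must be >= 0", call. = FALSE)
  stopifnot(is.data.frame(record), nrow(record) == 1)
  nut <- record$nutrients[[1]]
  scaled <- dplyr::mutate(nut, value = .data$value * grams / 100)
  energy <- scaled$value[scaled$nutrient == "energy"]
  if (length(energy) != 1 || is.na(energy)) {
    stop("record has no energy value", call. = FALSE)
  }
  list(
    grams = grams,
    energy_kcal = energy,
    nutrients = scaled,
    missing_nutrients = nut$nutrient[is.na(nut$value)]
  )
}

#' Per-meal nutrition summary
#'
#' One row per annotated eating episode with the number of foods and the
#' summed consumed weight and energy over its items.
#'
#' @param day a [day_annotation()].
#' @return a tibble: `aeep_id`, `meal_label`, `start`, `end`, `n_foods`,
#'   `weight_g`, `energy_kcal`. Zero rows for a day without meals.
#' @export
summarize_meals <- function(day) {
  stopifnot(inherits(day, "day_annotation"))
  base <- meals(day)
  if (nrow(base) == 0) {
    return(tibble::tibble(
      aeep_id = integer(0), meal_label = character(0),
      start = lubridate::as_datetime(numeric(0)),
      end = lubridate::as_datetime(numeric(0)),
      n_foods = integer(0), weight_g = numeric(0), energy_kcal = numeric(0)
    ))
  }
  sums <- purrr::map_dfr(day$meals, function(m) {
    tibble::tibble(
      aeep_id = m$aeep_id,
      n_foods = nrow(m$items),
      weight_g = sum(m$items$consumed_grams),
      energy_kcal = sum(m$items$energy_kcal)
    )
  })
  dplyr::left_join(
    dplyr::select(base, "aeep_id", "meal_label", "start", "end"),
    sums,
    by = "aeep_id"
  )
}

#' Daily nutrition summary
#'
#' Aggregates the per-meal summaries to the day: meal and item counts, total
#' consumed weight and energy, per-nutrient totals (with the set of items
#' missing each nutrient counted as incomplete rather than zero-filled), and
#' database usage over the annotated items.
#'
#' @param day a [day_annotation()].
#' @return a one-row tibble: `participant_id`, `day_id`, `n_aeep`,
#'   `n_foods`, `weight_g`, `energy_kcal`, plus attributes `nutrient_totals`
#'   (tibble of `nutrient`/`total`/`unit`/`n_missing_items`) and `db_usage`
#'   (see [db_usage()]).
#' @export
summarize_day <- function(day) {
  stopifnot(inherits(day, "day_annotation"))
  meal_sums <- summarize_meals(day)
  items <- food_items(day)
  nutrient_totals <- if (nrow(items) == 0) {
    tibble::tibble(
      nutrient = character(0), total = numeric(0), unit = character(0),
      n_missing_items = integer(0)
    )
  } else {
    tidyr::unnest(
      dplyr::select(items, "item_id", "aeep_id", "nutrients"),
      "nutrients"
    ) |>
      dplyr::group_by(.data$nutrient, .data$unit) |>
      dplyr::summarise(
        total = sum(.data$value, na.rm = TRUE),
        n_missing_items = sum(is.na(.data$value)),
        .groups = "drop"
      ) |>
      dplyr::select("nutrient", "total", "unit", "n_missing_items")
  }
  out <- tibble::tibble(
    participant_id = day$project$participant_id,
    day_id = day$project$day_id,
    n_aeep = nrow(meal_sums),
    n_foods = sum(meal_sums$n_foods),
    weight_g = sum(meal_sums$weight_g),
    energy_kcal = sum(meal_sums$energy_kcal)
  )
  attr(out, "nutrient_totals") <- nutrient_totals
  attr(out, "db_usage") <- db_usage(day)
  out
}

#' Database usage over annotated items
#'
#' How often each food-composition database supplied the matched record,
#' as a count and as a percentage of all annotated items.
#'
#' @param days a [day_annotation()] or a list of them.
#' @return a tibble: `source_db`, `n_items`, `pct` (sums to 100 over
#'   annotated items); zero rows when nothing is annotated.
#' @export
db_usage <- function(days) {
  if (inherits(days, "day_annotation")) days <- list(days)
  items <- purrr::map_dfr(days, food_items)
  if (nrow(items) == 0) {
    return(tibble::tibble(
      source_db = character(0), n_items = integer(0), pct = numeric(0)
    ))
  }
  dplyr::count(items, .data$source_db, name = "n_items") |>
    dplyr::mutate(pct = 100 * .data$n_items / sum(.data$n_items)) |>
    dplyr::arrange(dplyr::desc(.data$n_items), .data$source_db)
}

#' @describeIn summarize_day `glance()` on a `day_annotation` returns the
#'   daily summary row extended with sensor-episode tallies and the
#'   annotation duration.
#' @param x a `day_annotation`.
#' @param ... unused.
#' @export
glance.day_annotation <- function(x, ...) {
  s <- summarize_day(x)
  counts <- episode_status_counts(x$episodes)
  dplyr::bind_cols(s, counts,
    tibble::tibble(annotation_duration_s = annotation_duration(x))
  )
}

#' @describeIn summarize_day `tidy()` on a `day_annotation` returns the
#'   item-level tibble ([food_items()]).
#' @export
tidy.day_annotation <- function(x, ...) food_items(x)
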