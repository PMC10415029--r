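#' Export the day's nutrition analysis as tabular files
#'
#' Writes the full output set for one annotated day to a directory as CSV
#' (RFC 4180): `items.csv` with one row per annotated food item (episode
#' context, source database, food id, form, group, description, initial /
#' leftover / consumed amount and portion, consumed grams, energy and one
#' column per nutrient), `aeep_summary.csv` with one row per annotated
#' episode, `daily_summary.csv` with the one-row daily totals, and
#' `day_meta.csv` with the sensor-episode true/false tallies and the
#' annotation duration rendered hh:mm:ss. Gram and kcal cells are rendered
#' to 2 decimal places; re-parsing a file reproduces the in-memory values to
#' within 0.005.
#'
#' @param day a [day_annotation()].
#' @param dir output directory (created if needed).
#' @param format only `"csv"` is supported; CSV is the canonical,
#'   dependency-light, diffable export format.
#' @param nutrients optional character vector pinning the nutrient column
#'   set and order of `items.csv`; defaults to the nutrients of the first
#'   item's source record, in declaration order.
#' @return invisibly, a named list of the written file paths.
#' @export
export_report <- function(day, dir, format = c("csv"), nutrients = NULL) {
  stopifnot(inherits(day, "day_annotation"))
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }

  items <- food_items(day)
  if (is.null(nutrients)) {
    nutrients <- if (nrow(items) > 0) {
      setdiff(items$nutrients[[1]]$nutrient, "energy")
    } else {
      character(0)
    }
  }

  item_rows <- if (nrow(items) == 0) {
    base <- tibble::tibble(
      participant_id = character(0), day_id = character(0),
      aeep_id = integer(0), meal_label = character(0),
      source_db = character(0), food_id = character(0),
      form = character(0), group = character(0), description = character(0),
      initial_amount = character(0), initial_portion = character(0),
      leftover_amount = character(0), leftover_portion = character(0),
      consumed_amount = character(0),
      consumed_grams = numeric(0), energy_kcal = numeric(0)
    )
    for (n in nutrients) base[[n]] <- numeric(0)
    base
  } else {
    nut_wide <- purrr::map_dfr(items$nutrients, function(nt) {
      vals <- stats::setNames(nt$value, nt$nutrient)[nutrients]
      tibble::as_tibble_row(stats::setNames(
        as.list(round2(unname(vals))), nutrients
      ))
    })
    dplyr::bind_cols(
      tibble::tibble(
        participant_id = day$project$participant_id,
        day_id = format(day$project$day_id)
      )[rep(1, nrow(items)), ],
      dplyr::select(
        items, "aeep_id", "meal_label", "source_db", "food_id", "form",
        "group", "description", "initial_amount", "initial_portion",
        "leftover_amount", "leftover_portion", "consumed_amount"
      ),
      tibble::tibble(
        consumed_grams = round2(items$consumed_grams),
        energy_kcal = round2(items$energy_kcal)
      ),
      nut_wide
    )
  }

  meal_sums <- summarize_meals(day)
  meal_out <- dplyr::mutate(meal_sums,
    start = format_instant(.data$start),
    end = format_instant(.data$end),
    weight_g = round2(.data$weight_g),
    energy_kcal = round2(.data$energy_kcal)
  )

  daily <- summarize_day(day)
  totals <- attr(daily, "nutrient_totals")
  daily_out <- dplyr::mutate(daily,
    day_id = format(.data$day_id),
    weight_g = round2(.data$weight_g),
    energy_kcal = round2(.data$energy_kcal)
  )
  for (i in seq_len(nrow(totals))) {
    if (totals$nutrient[i] == "energy") next
    daily_out[[paste0(totals$nutrient[i], "_total")]] <- round2(totals$total[i])
  }

  counts <- episode_status_counts(day$episodes)
  meta <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = day$project$participant_id,
      day_id = format(day$project$day_id)
    ),
    counts,
    tibble::tibble(
      annotation_duration = format_hms(annotation_duration(day))
    )
  )

  paths <- list(
    items = file.path(dir, "items.csv"),
    aeep_summary = file.path(dir, "aeep_summary.csv"),
    daily_summary = file.path(dir, "daily_summary.csv"),
    day_meta = file.path(dir, "day_meta.csv")
  )
  readr::write_csv(item_rows, paths$items, na = "")
  readr::write_csv(meal_out, paths$aeep_summary, na = "")
  readr::write_csv(daily_out, paths$daily_summary, na = "")
  readr::write_csv(meta, paths$day_meta, na = "")
  invisible(paths)
}

round2 <- function(x) round(x, 2)

#' Format seconds as hh:mm:ss
#'
#' @param seconds non-negative duration in seconds (fractions truncated).
#' @return "hh:mm:ss" string, `NA` in, `NA` out.
#' @examples
#' format_hms(1093) # "00:18:13"
#' @export
format_hms <- function(seconds) {
  ifelse(is.na(seconds), NA_character_, {
    s <- floor(as.numeric(seconds))
    sprintf("%02d:%02d:%02d", s %/% 3600, (s %% 3600) %/% 60, s %% 60)
  })
}

#' Database-usage frequency report
#'
#' Tabulates, over one or more annotated days, how many annotated food items
#' each registered food-composition database supplied, with the share
#' expressed as a percentage of all annotated items.
#'
#' @param days a [day_annotation()] or list of them, with at least one
#'   annotated item overall.
#' @return a tibble: `source_db`, `n_items`, `pct`.
#' @export
db_usage_report <- function(days) {
  usage <- db_usage(days)
  if (nrow(usage) == 0) {
    stop("no annotated food items to report on", call. = FALSE)
  }
  usage
}

#' Bar chart of database usage
#'
#' @param usage a [db_usage_report()] tibble.
#' @return a ggplot.
#' @export
plot_db_usage <- function(usage) {
  ggplot2::ggplot(
    usage,
    ggplot2::aes(
      x = stats::reorder(.data$source_db, -.data$pct),
      y = .data$pct
    )
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "Food database",
      y = "Annotated items (%)",
      title = "Food-composition database usage"
    ) +
    ggplot2::theme_minimal()
}
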