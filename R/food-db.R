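#' Supported food-composition CSV dialects
#'
#' Food-composition tables are published as CSV in house styles that differ
#' in column naming, energy units and how the portion-weight table is
#' encoded. Four dialects are supported out of the box, modelled on the
#' USDA Standard Reference legacy export (`"sr"`), the Food and Nutrient
#' Database for Dietary Studies (`"fndds"`), the USDA Branded Food Products
#' export (`"branded"`) and FAO-style national food-composition tables
#' (`"fao"`, energy in kJ). The mapping from source columns to the unified
#' record model is declarative: a YAML file shipped with the package (or
#' supplied by the user) lists, per dialect, the id/description/group
#' columns, the energy column and unit, the nutrient columns with units, and
#' the portion-table encoding.
#'
#' @param config path to a dialect-map YAML file; defaults to the maps
#'   shipped with the package.
#' @return a named list of dialect column maps (invisibly for the loader's
#'   use); `food_dialects()` returns the dialect names.
#' @export
food_dialects <- function(config = NULL) {
  names(load_dialect_maps(config))
}

load_dialect_maps <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "dialects.yaml", package = "nutricam")
  }
  if (!file.exists(config)) {
    stop("dialect config not found: ", config, call. = FALSE)
  }
  yaml::read_yaml(config)
}

#' Load a food-composition database from CSV
#'
#' Reads a food-composition table in one of the supported [food_dialects()]
#' and unifies it into a tibble of food records: one row per food, with the
#' source-native food id, a description, a food group, per-100 g nutrient
#' values (energy standardized to kcal at load; kJ sources are divided by
#' 4.184) and a portion-weight table. A `"gram"` portion of exactly 1 g is
#' synthesized for every food whose source table lacks one, so every food can
#' always be annotated directly in grams.
#'
#' Rows missing the food id or the description are skipped and counted (the
#' count is available through [glance()] and the `skipped` attribute);
#' nutrient cells that do not parse as numbers (including thousands
#' separators and simple fractions) are stored as missing, never as zero.
#' Missing nutrients propagate to downstream summaries as completeness
#' flags rather than biasing totals toward zero.
#'
#' @param path path to the CSV file (RFC 4180, UTF-8, header row).
#' @param dialect dialect name, one of [food_dialects()].
#' @param name database name used as `source_db` on every record and as the
#'   registry key.
#' @param config optional path to a dialect-map YAML overriding the shipped
#'   maps.
#' @return a `food_db` object: a list with `name`, `dialect`, and `records`,
#'   a tibble with columns `food_id`, `source_db`, `description`, `group`,
#'   `energy_kcal`, and list-columns `nutrients` (tibble of
#'   `nutrient`/`value`/`unit` per 100 g) and `portions` (tibble of
#'   `label`/`gram_weight`).
#' @examples
#' csv <- make_toy_database("sr", n_foods = 5, seed = 1,
#'                          path = tempfile(fileext = ".csv"))
#' db <- load_food_db(csv$path, dialect = "sr", name = "toy-sr")
#' db$records
#' @export
load_food_db <- function(path, dialect, name, config = NULL) {
  maps <- load_dialect_maps(config)
  if (!dialect %in% names(maps)) {
    stop("unknown dialect '", dialect, "'; supported: ",
      paste(names(maps), collapse = ", "),
      call. = FALSE
    )
  }
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  map <- maps[[dialect]]
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  need <- c(map$id, map$description, map$energy$column)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0) {
    stop("file does not match dialect '", dialect, "': missing column(s) ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }

  id <- stringr::str_trim(raw[[map$id]])
  desc <- stringr::str_trim(raw[[map$description]])
  ok <- !is.na(id) & id != "" & !is.na(desc) & desc != ""
  skipped <- sum(!ok)
  raw <- raw[ok, , drop = FALSE]
  if (nrow(raw) == 0) {
    stop("no valid rows in ", path, " (", skipped, " skipped)", call. = FALSE)
  }

  energy <- parse_nutrient_cell(raw[[map$energy$column]])
  if (identical(map$energy$unit, "kJ")) energy <- energy / 4.184

  nut_names <- vapply(map$nutrients, `[[`, character(1), "name")
  nut_units <- vapply(map$nutrients, `[[`, character(1), "unit")
  nut_cols <- vapply(map$nutrients, `[[`, character(1), "column")
  nut_vals <- lapply(nut_cols, function(col) {
    if (col %in% names(raw)) parse_nutrient_cell(raw[[col]]) else rep(NA_real_, nrow(raw))
  })

  nutrients <- lapply(seq_len(nrow(raw)), function(i) {
    tibble::tibble(
      nutrient = c("energy", nut_names),
      value = c(energy[i], vapply(nut_vals, `[[`, numeric(1), i)),
      unit = c("kcal", nut_units)
    )
  })

  portions <- extract_portions(raw, map$portions)

  group <- if (!is.null(map$group) && map$group %in% names(raw)) {
    dplyr::coalesce(stringr::str_trim(raw[[map$group]]), "")
  } else {
    rep("", nrow(raw))
  }

  records <- tibble::tibble(
    food_id = stringr::str_trim(raw[[map$id]]),
    source_db = name,
    description = stringr::str_trim(raw[[map$description]]),
    group = group,
    energy_kcal = energy,
    nutrients = nutrients,
    portions = portions
  )
  if (anyDuplicated(records$food_id) > 0) {
    stop("duplicate food ids in ", path, call. = FALSE)
  }

  structure(
    list(name = name, dialect = dialect, records = records, skipped = skipped),
    class = "food_db"
  )
}

# numbers with thousands separators and simple fractions; anything else -> NA
parse_nutrient_cell <- function(x) {
  x <- stringr::str_trim(x)
  x[x == ""] <- NA_character_
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    v <- tryCatch(as.numeric(parse_amount(x[i])), error = function(e) NA_real_)
    if (!is.na(v) && is.finite(v) && v >= 0) out[i] <- v
  }
  out
}

extract_portions <- function(raw, spec) {
  n <- nrow(raw)
  base <- switch(spec$style,
    pairs = lapply(seq_len(n), function(i) {
      labs <- character(0)
      wts <- numeric(0)
      for (pair in spec$pairs) {
        if (!all(pair %in% names(raw))) next
        lab <- stringr::str_trim(raw[[pair[[1]]]][i])
        wt <- suppressWarnings(as.numeric(gsub(",", "", raw[[pair[[2]]]][i])))
        if (!is.na(lab) && lab != "" && !is.na(wt) && wt > 0) {
          labs <- c(labs, lab)
          wts <- c(wts, wt)
        }
      }
      tibble::tibble(label = labs, gram_weight = wts)
    }),
    serving = lapply(seq_len(n), function(i) {
      lab <- if (spec$label %in% names(raw)) stringr::str_trim(raw[[spec$label]][i]) else NA_character_
      wt <- if (spec$weight %in% names(raw)) {
        suppressWarnings(as.numeric(gsub(",", "", raw[[spec$weight]][i])))
      } else {
        NA_real_
      }
      if (!is.na(lab) && lab != "" && !is.na(wt) && wt > 0) {
        tibble::tibble(label = lab, gram_weight = wt)
      } else {
        tibble::tibble(label = character(0), gram_weight = numeric(0))
      }
    }),
    inline = lapply(seq_len(n), function(i) {
      parse_inline_portions(raw[[spec$column]][i])
    }),
    stop("unknown portion style '", spec$style, "'", call. = FALSE)
  )
  lapply(base, ensure_gram_option)
}

# "cup=240; tablespoon=15" -> tibble(label, gram_weight)
parse_inline_portions <- function(s) {
  if (is.na(s) || stringr::str_trim(s) == "") {
    return(tibble::tibble(label = character(0), gram_weight = numeric(0)))
  }
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  labs <- character(0)
  wts <- numeric(0)
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) next
    lab <- stringr::str_trim(kv[1])
    wt <- suppressWarnings(as.numeric(stringr::str_trim(kv[2])))
    if (lab != "" && !is.na(wt) && wt > 0) {
      labs <- c(labs, lab)
      wts <- c(wts, wt)
    }
  }
  tibble::tibble(label = labs, gram_weight = wts)
}

ensure_gram_option <- function(portions) {
  if (!"gram" %in% portions$label) {
    portions <- dplyr::bind_rows(
      portions,
      tibble::tibble(label = "gram", gram_weight = 1)
    )
  }
  portions
}

#' @export
print.food_db <- function(x, ...) {
  cat(
    "<food_db> ", x$name, " (dialect: ", x$dialect, "): ",
    nrow(x$records), " foods",
    if (x$skipped > 0) paste0(", ", x$skipped, " rows skipped") else "",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn load_food_db `tidy()` returns the unified records tibble.
#' @param x a `food_db` object.
#' @param ... unused.
#' @export
tidy.food_db <- function(x, ...) x$records

#' @describeIn load_food_db `glance()` returns a one-row tibble with
#'   `name`, `dialect`, `record_count` and `rows_skipped`.
#' @export
glance.food_db <- function(x, ...) {
  tibble::tibble(
    name = x$name,
    dialect = x$dialect,
    record_count = nrow(x$records),
    rows_skipped = x$skipped
  )
}
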