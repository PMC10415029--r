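#' Multi-database food registry
#'
#' Annotation may draw food items from any combination of food-composition
#' databases (a national reference table, a dietary-survey table, a branded
#' products table, regional FAO tables, ...). A registry holds any number of
#' loaded databases under unique names with an explicit priority that decides
#' cross-database ordering of search results. No nutrient standardization is
#' performed across databases: each record's values are reported exactly as
#' its source table states them.
#'
#' @return an empty `food_registry`.
#' @examples
#' reg <- food_registry()
#' @export
food_registry <- function() {
  structure(list(dbs = list(), priority = numeric(0)), class = "food_registry")
}

#' Register a loaded database
#'
#' @param registry a [food_registry()].
#' @param db a `food_db` from [load_food_db()].
#' @param priority lower numbers rank earlier in cross-database search
#'   results; defaults to registration order.
#' @return the registry with the database added.
#' @export
register_db <- function(registry, db, priority = NULL) {
  stopifnot(inherits(registry, "food_registry"), inherits(db, "food_db"))
  if (db$name %in% names(registry$dbs)) {
    stop("database '", db$name, "' is already registered", call. = FALSE)
  }
  if (is.null(priority)) {
    priority <- if (length(registry$priority) == 0) 1 else max(registry$priority) + 1
  }
  registry$dbs[[db$name]] <- db
  registry$priority <- c(registry$priority, stats::setNames(priority, db$name))
  registry
}

#' List registered databases in priority order
#'
#' @param registry a [food_registry()].
#' @return a tibble with `name`, `dialect`, `priority`, `record_count`.
#' @export
list_databases <- function(registry) {
  stopifnot(inherits(registry, "food_registry"))
  tibble::tibble(
    name = names(registry$dbs),
    dialect = vapply(registry$dbs, `[[`, character(1), "dialect"),
    priority = unname(registry$priority[names(registry$dbs)]),
    record_count = vapply(registry$dbs, function(d) nrow(d$records), integer(1))
  ) |>
    dplyr::arrange(.data$priority, .data$name)
}

#' Search registered databases by food name
#'
#' Case-insensitive search over food descriptions with a fixed rank-tier
#' scheme: exact description match first, then descriptions starting with the
#' query, then descriptions containing every whitespace-separated query token,
#' then plain substring matches. Ties within a tier are broken by database
#' priority, then by food id (numerically where the ids are numeric). The
#' same query on the same registry always returns the same ordering.
#'
#' @param registry a [food_registry()] with at least one database.
#' @param query food name text; must be non-empty after trimming.
#' @param databases optional character vector restricting the search to a
#'   subset of registered database names.
#' @return a tibble of matching records: `source_db`, `food_id`,
#'   `description`, `group`, `energy_kcal`, `match_tier` (1 = exact, 2 =
#'   prefix, 3 = all tokens, 4 = substring) plus the `nutrients` and
#'   `portions` list-columns. Zero rows when nothing matches.
#' @export
search_foods <- function(registry, query, databases = NULL) {
  stopifnot(inherits(registry, "food_registry"))
  if (length(registry$dbs) == 0) {
    stop("no databases registered", call. = FALSE)
  }
  query <- stringr::str_trim(query)
  if (length(query) != 1 || is.na(query) || query == "") {
    stop("query must be a single non-empty string", call. = FALSE)
  }
  dbs <- names(registry$dbs)
  if (!is.null(databases)) {
    unknown <- setdiff(databases, dbs)
    if (length(unknown) > 0) {
      stop("unknown database(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    dbs <- databases
  }

  q <- stringr::str_to_lower(query)
  tokens <- strsplit(q, "\\s+")[[1]]

  pooled <- purrr::map_dfr(dbs, function(nm) {
    recs <- registry$dbs[[nm]]$records
    recs$priority <- unname(registry$priority[nm])
    recs
  })

  d <- stringr::str_to_lower(pooled$description)
  substr_hit <- stringr::str_detect(d, stringr::fixed(q))
  token_hit <- purrr::map_lgl(d, function(x) {
    all(stringr::str_detect(x, stringr::fixed(tokens)))
  })
  tier <- dplyr::case_when(
    d == q ~ 1L,
    stringr::str_starts(d, stringr::fixed(q)) ~ 2L,
    token_hit ~ 3L,
    substr_hit ~ 4L,
    .default = NA_integer_
  )
  pooled$match_tier <- tier
  hits <- pooled[!is.na(tier), , drop = FALSE]

  id_num <- suppressWarnings(as.numeric(hits$food_id))
  id_key <- if (nrow(hits) > 0 && !anyNA(id_num)) id_num else hits$food_id
  hits <- hits[order(hits$match_tier, hits$priority, id_key), , drop = FALSE]

  dplyr::select(
    hits, "source_db", "food_id", "description", "group",
    "match_tier", "energy_kcal", "nutrients", "portions"
  ) |> tibble::as_tibble()
}

#' Look up one record by database name and food id
#'
#' @param registry a [food_registry()].
#' @param source_db registered database name.
#' @param food_id source-native food id.
#' @return a one-row records tibble.
#' @export
get_food <- function(registry, source_db, food_id) {
  stopifnot(inherits(registry, "food_registry"))
  if (!source_db %in% names(registry$dbs)) {
    stop("database '", source_db, "' is not registered", call. = FALSE)
  }
  recs <- registry$dbs[[source_db]]$records
  hit <- recs[recs$food_id == as.character(food_id), , drop = FALSE]
  if (nrow(hit) == 0) {
    stop(
      "food id '", food_id, "' not found in database '", source_db, "'",
      call. = FALSE
    )
  }
  hit
}

#' Portion-size options for a food record
#'
#' Returns the food's portion-weight table: household measures mapped to the
#' gram weight of one unit. Every record carries a `"gram"` option with
#' weight exactly 1, synthesized at load time where the source lacks it, so
#' amounts can always be entered in grams. The result is a pure function of
#' the record: repeated calls return identical tables.
#'
#' @param record a one-row records tibble (e.g. from [search_foods()] or
#'   [get_food()]).
#' @return a tibble with `label` and `gram_weight` (> 0).
#' @export
portion_options <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1, "portions" %in% names(record))
  ensure_gram_option(record$portions[[1]])
}

#' @export
print.food_registry <- function(x, ...) {
  cat("<food_registry> ", length(x$dbs), " database(s)\n", sep = "")
  if (length(x$dbs) > 0) print(list_databases(x))
  invisible(x)
}

#' @describeIn food_registry `tidy()` lists the registered databases.
#' @param x a `food_registry`.
#' @param ... unused.
#' @export
tidy.food_registry <- function(x, ...) list_databases(x)
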