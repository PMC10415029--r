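#' A day's annotation session
#'
#' Holds everything the annotator produces for one participant-day: the
#' review verdicts on sensor-detected episodes, the annotator-created eating
#' episodes (meals/snacks) with their linked images, and the food items
#' attached to each episode. The project itself is referenced read-only;
#' deleting or editing annotations never mutates the project.
#'
#' @param project a [camera_project()].
#' @param episodes optional [detect_episodes()] tibble; detected with
#'   defaults when omitted.
#' @param started,finished optional annotation session timestamps; their
#'   difference is the reported annotation duration.
#' @return a `day_annotation` object.
#' @examples
#' prj <- simulate_day(seed = 3)$project
#' day <- day_annotation(prj)
#' @export
day_annotation <- function(project, episodes = NULL, started = NULL,
                           finished = NULL) {
  stopifnot(inherits(project, "camera_project"))
  if (is.null(episodes)) episodes <- detect_episodes(project)
  structure(
    list(
      project = project,
      episodes = episodes,
      meals = list(),
      started = started,
      finished = finished,
      schema_version = 1L
    ),
    class = "day_annotation"
  )
}

#' Create an annotated eating episode (meal record)
#'
#' Adds an annotator-created eating episode. The label is typically one of
#' breakfast/lunch/dinner/snack but any free text is accepted. Start and end
#' may be given explicitly or left unset, in which case they auto-populate
#' from the timestamps of subsequently linked images.
#'
#' @param day a [day_annotation()].
#' @param meal_label episode label.
#' @param start,end optional instants (POSIXct or ISO 8601 strings);
#'   `start <= end` required when both are given.
#' @return the updated `day_annotation`; the new episode gets the next
#'   sequential id (see [meals()]).
#' @export
add_meal <- function(day, meal_label, start = NULL, end = NULL) {
  stopifnot(inherits(day, "day_annotation"))
  if (is.character(start)) start <- parse_instant(start)
  if (is.character(end)) end <- parse_instant(end)
  if (!is.null(start) && !is.null(end) && start > end) {
    stop("meal start must not be after its end", call. = FALSE)
  }
  id <- length(day$meals) + 1L
  day$meals[[id]] <- list(
    aeep_id = id,
    meal_label = as.character(meal_label),
    start = start,
    end = end,
    times_explicit = !is.null(start) || !is.null(end),
    image_ids = character(0),
    items = empty_items()
  )
  day
}

empty_items <- function() {
  tibble::tibble(
    item_id = integer(0),
    source_db = character(0),
    food_id = character(0),
    description = character(0),
    group = character(0),
    form = character(0),
    initial_amount = character(0),
    initial_portion = character(0),
    leftover_amount = character(0),
    leftover_portion = character(0),
    consumed_amount = character(0),
    consumed_grams = numeric(0),
    energy_kcal = numeric(0),
    nutrients = list(),
    missing_nutrients = list()
  )
}

#' Link a project image to a meal
#'
#' Associates an image with an annotated episode (set semantics: linking the
#' same image twice keeps one entry). For meals created without explicit
#' times, start/end auto-populate as the earliest linked-image timestamp and
#' the latest linked-image timestamp plus one capture interval; re-linking
#' the same image set always yields the same times. An image may be linked
#' to more than one meal (e.g. a drink spanning a meal); doing so raises a
#' warning, not an error.
#'
#' @param day a [day_annotation()].
#' @param aeep_id meal id from [meals()].
#' @param image_id a project image id.
#' @return the updated `day_annotation`.
#' @export
link_image <- function(day, aeep_id, image_id) {
  stopifnot(inherits(day, "day_annotation"))
  m <- get_meal(day, aeep_id)
  image_id <- as.character(image_id)
  imgs <- day$project$images
  if (!image_id %in% imgs$image_id) {
    stop("image '", image_id, "' does not belong to this project",
      call. = FALSE
    )
  }
  linked_elsewhere <- purrr::map_lgl(day$meals, function(other) {
    other$aeep_id != aeep_id && image_id %in% other$image_ids
  })
  if (any(linked_elsewhere)) {
    warning("image '", image_id, "' is already linked to another meal",
      call. = FALSE
    )
  }
  m$image_ids <- union(m$image_ids, image_id)
  if (!m$times_explicit) {
    ts <- imgs$timestamp[imgs$image_id %in% m$image_ids]
    m$start <- min(ts)
    m$end <- max(ts) + day$project$capture_interval
  }
  day$meals[[which_meal(day, aeep_id)]] <- m
  day
}

which_meal <- function(day, aeep_id) {
  i <- which(purrr::map_int(day$meals, "aeep_id") == aeep_id)
  if (length(i) != 1) stop("no meal with id ", aeep_id, call. = FALSE)
  i
}

get_meal <- function(day, aeep_id) day$meals[[which_meal(day, aeep_id)]]

#' Meals of a day as a tibble
#'
#' @param day a [day_annotation()].
#' @return a tibble with one row per annotated episode: `aeep_id`,
#'   `meal_label`, `start`, `end`, `n_images` (linked), `n_items`.
#' @export
meals <- function(day) {
  stopifnot(inherits(day, "day_annotation"))
  purrr::map_dfr(day$meals, function(m) {
    tibble::tibble(
      aeep_id = m$aeep_id,
      meal_label = m$meal_label,
      start = m$start %||% lubridate::as_datetime(NA),
      end = m$end %||% lubridate::as_datetime(NA),
      n_images = length(m$image_ids),
      n_items = nrow(m$items)
    )
  })
}

#' Annotated food items of a day as a tibble
#'
#' @param day a [day_annotation()].
#' @return one row per food item across all meals, with meal context columns
#'   prepended to the item fields (see [add_food_item()]).
#' @export
food_items <- function(day) {
  stopifnot(inherits(day, "day_annotation"))
  empty <- dplyr::bind_cols(
    tibble::tibble(aeep_id = integer(0), meal_label = character(0)),
    empty_items()
  )
  rows <- purrr::map_dfr(day$meals, function(m) {
    if (nrow(m$items) == 0) {
      return(NULL)
    }
    dplyr::bind_cols(
      tibble::tibble(
        aeep_id = m$aeep_id,
        meal_label = m$meal_label
      )[rep(1, nrow(m$items)), ],
      m$items
    )
  })
  if (nrow(rows) == 0) empty else rows
}

#' Time-based lookup across panels
#'
#' The time link between the image stream, the sensor-detected episodes and
#' the annotated episodes: given an instant, returns the image captured at or
#' most recently before it, the sensor-detected episode containing it (if
#' any), and the annotated episodes whose span contains it (possibly
#' several, possibly none).
#'
#' @param day a [day_annotation()].
#' @param t an instant (POSIXct or ISO 8601 string) within the day's
#'   recording span (first image to last image + capture interval).
#' @return a list with elements `image` (one-row tibble or zero rows),
#'   `episode` (sensor-detected, zero or one row), `meals` (tibble).
#' @export
lookup_time <- function(day, t) {
  stopifnot(inherits(day, "day_annotation"))
  if (is.character(t)) t <- parse_instant(t)
  imgs <- day$project$images
  span_lo <- min(imgs$timestamp)
  span_hi <- max(imgs$timestamp) + day$project$capture_interval
  if (t < span_lo || t > span_hi) {
    stop("instant lies outside the recording span", call. = FALSE)
  }
  img <- dplyr::slice_tail(dplyr::filter(imgs, .data$timestamp <= t), n = 1)
  ep <- dplyr::filter(day$episodes, .data$start <= t, t < .data$end)
  ml <- meals(day)
  ml <- if (nrow(ml) > 0) {
    dplyr::filter(ml, !is.na(.data$start), .data$start <= t, t <= .data$end)
  } else {
    ml
  }
  list(image = img, episode = ep, meals = ml)
}

#' Attach a food item to a meal
#'
#' Records one annotated food: the database record it was matched to, its
#' food form (solid / liquid / semi-solid), and the initial and leftover
#' portions. Consumed amount, grams, energy and nutrients are derived
#' immediately via the nutrition rules ([consumed_amount()],
#' [amount_to_grams()], [nutrient_intake()]) and stored on the item row.
#' Amounts accept decimals and simple fractions ("1/3"); the leftover
#' defaults to zero. A leftover exceeding the initial amount (compared in
#' grams) is rejected.
#'
#' @param day a [day_annotation()].
#' @param aeep_id meal id.
#' @param record one-row food records tibble ([get_food()] /
#'   [search_foods()]).
#' @param form `"solid"`, `"liquid"` or `"semi-solid"`.
#' @param initial_amount,leftover_amount numbers or fraction strings.
#' @param initial_portion,leftover_portion portion labels; must exist in the
#'   record's [portion_options()]. The leftover portion defaults to the
#'   initial one.
#' @return the updated `day_annotation`.
#' @export
add_food_item <- function(day, aeep_id, record, form, initial_amount,
                          initial_portion, leftover_amount = 0,
                          leftover_portion = initial_portion) {
  stopifnot(inherits(day, "day_annotation"))
  form <- match.arg(form, c("solid", "liquid", "semi-solid"))
  m <- get_meal(day, aeep_id)
  opts <- portion_options(record)
  for (p in c(initial_portion, leftover_portion)) {
    if (!p %in% opts$label) {
      stop("portion '", p, "' is not offered for this food (available: ",
        paste(opts$label, collapse = ", "), ")",
        call. = FALSE
      )
    }
  }
  initial <- parse_amount(initial_amount)
  leftover <- parse_amount(leftover_amount)
  if (as.numeric(initial) <= 0) {
    stop("initial amount must be > 0", call. = FALSE)
  }
  if (as.numeric(leftover) < 0) {
    stop("leftover amount must be >= 0", call. = FALSE)
  }
  consumed <- consumed_amount(initial, leftover,
    initial_portion = initial_portion,
    leftover_portion = leftover_portion, portions = opts
  )
  grams <- amount_to_grams(consumed, initial_portion, opts)
  intake <- nutrient_intake(grams, record)

  item <- tibble::tibble(
    item_id = nrow(m$items) + 1L,
    source_db = record$source_db,
    food_id = record$food_id,
    description = record$description,
    group = record$group,
    form = form,
    initial_amount = format(initial),
    initial_portion = initial_portion,
    leftover_amount = format(leftover),
    leftover_portion = leftover_portion,
    consumed_amount = format(consumed),
    consumed_grams = grams,
    energy_kcal = intake$energy_kcal,
    nutrients = list(intake$nutrients),
    missing_nutrients = list(intake$missing_nutrients)
  )
  m$items <- dplyr::bind_rows(m$items, item)
  day$meals[[which_meal(day, aeep_id)]] <- m
  day
}

#' Record the sensor-episode verdict inside an annotation session
#'
#' @param day a [day_annotation()].
#' @param episode_id sensor-detected episode id.
#' @param verdict `"true"`, `"false"` or `"unreviewed"`.
#' @return the updated `day_annotation`.
#' @export
review_episode <- function(day, episode_id, verdict) {
  stopifnot(inherits(day, "day_annotation"))
  day$episodes <- mark_episode(day$episodes, episode_id, verdict)
  day
}

#' Save / load an annotation session
#'
#' Annotations persist as a versioned JSON document embedding the project,
#' the sensor-episode verdicts, the meals with their image links, and the
#' food items with recorded portions. `read_annotation(write_annotation(x))`
#' is field-equal to `x`; derived item quantities are recomputed from the
#' recorded portions at load against the supplied registry.
#'
#' @param day a [day_annotation()].
#' @param path JSON file path.
#' @param registry the [food_registry()] used to resolve item records when
#'   loading (required only when items are present).
#' @return `read_annotation()` returns a `day_annotation`.
#' @export
write_annotation <- function(day, path) {
  stopifnot(inherits(day, "day_annotation"))
  doc <- list(
    schema_version = day$schema_version,
    started = if (!is.null(day$started)) format_instant(day$started),
    finished = if (!is.null(day$finished)) format_instant(day$finished),
    project = list(
      participant_id = day$project$participant_id,
      day_id = format(day$project$day_id),
      capture_interval_s = day$project$capture_interval,
      images = data.frame(
        image_id = day$project$images$image_id,
        timestamp = format_instant(day$project$images$timestamp),
        label = day$project$images$label,
        path = day$project$images$path
      )
    ),
    episodes = data.frame(
      episode_id = day$episodes$episode_id,
      start = format_instant(day$episodes$start),
      end = format_instant(day$episodes$end),
      n_images = day$episodes$n_images,
      status = day$episodes$status
    ),
    meals = purrr::map(day$meals, function(m) {
      list(
        aeep_id = m$aeep_id,
        meal_label = m$meal_label,
        start = if (!is.null(m$start)) format_instant(m$start),
        end = if (!is.null(m$end)) format_instant(m$end),
        times_explicit = m$times_explicit,
        image_ids = as.list(m$image_ids),
        items = purrr::map(seq_len(nrow(m$items)), function(i) {
          it <- m$items[i, ]
          list(
            source_db = it$source_db, food_id = it$food_id,
            form = it$form,
            initial_amount = it$initial_amount,
            initial_portion = it$initial_portion,
            leftover_amount = it$leftover_amount,
            leftover_portion = it$leftover_portion
          )
        })
      )
    })
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path, registry = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse annotation file: ",
        conditionMessage(e),
        call. = FALSE
      )
  )
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported annotation schema version: ",
      doc$schema_version %||% "<absent>",
      call. = FALSE
    )
  }
  pj <- doc$project
  project <- camera_project(
    pj$participant_id, pj$day_id, pj$capture_interval_s,
    purrr::map_dfr(pj$images, function(im) {
      tibble::tibble(
        image_id = im$image_id, timestamp = im$timestamp,
        label = im$label, path = im$path %||% NA_character_
      )
    })
  )
  episodes <- purrr::map_dfr(doc$episodes, function(e) {
    tibble::tibble(
      episode_id = as.integer(e$episode_id),
      start = parse_instant(e$start),
      end = parse_instant(e$end),
      n_images = as.integer(e$n_images),
      status = e$status
    )
  })
  if (nrow(episodes) == 0) episodes <- detect_episodes(project)[0, ]
  day <- day_annotation(project, episodes,
    started = if (!is.null(doc$started)) parse_instant(doc$started),
    finished = if (!is.null(doc$finished)) parse_instant(doc$finished)
  )
  for (m in doc$meals) {
    day <- add_meal(day, m$meal_label,
      start = if (isTRUE(m$times_explicit) && !is.null(m$start)) m$start,
      end = if (isTRUE(m$times_explicit) && !is.null(m$end)) m$end
    )
    id <- m$aeep_id
    for (img in m$image_ids) day <- link_image(day, id, img)
    for (it in m$items) {
      if (is.null(registry)) {
        stop("annotation has food items; a registry is required to load it",
          call. = FALSE
        )
      }
      rec <- get_food(registry, it$source_db, it$food_id)
      day <- add_food_item(day, id, rec, it$form,
        initial_amount = it$initial_amount,
        initial_portion = it$initial_portion,
        leftover_amount = it$leftover_amount,
        leftover_portion = it$leftover_portion
      )
    }
  }
  day
}

#' Annotation duration in seconds
#'
#' @param day a [day_annotation()].
#' @return numeric seconds, or `NA` when the session timestamps are unset.
#' @export
annotation_duration <- function(day) {
  stopifnot(inherits(day, "day_annotation"))
  if (is.null(day$started) || is.null(day$finished)) {
    return(NA_real_)
  }
  as.numeric(difftime(day$finished, day$started, units = "secs"))
}

#' @export
print.day_annotation <- function(x, ...) {
  cat(
    "<day_annotation> participant ", x$project$participant_id, ", ",
    format(x$project$day_id), ": ", nrow(x$episodes),
    " sensor episode(s), ", length(x$meals), " meal(s), ",
    nrow(food_items(x)), " item(s)\n",
    sep = ""
  )
  invisible(x)
}
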