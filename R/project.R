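#' A participant-day camera project
#'
#' One wearable-camera recording day: an ordered image index (one row per
#' captured image, at a fixed capture interval of typically 10 or 15 s) where
#' each image carries a binary food-intake label produced upstream by the
#' sensor-based intake classifier (1 = intake, 0 = no intake). The project is
#' the unit all downstream work operates on: episode segmentation, review
#' metrics and annotation.
#'
#' @param participant_id participant identifier.
#' @param day_id recording date (`Date` or "YYYY-MM-DD").
#' @param capture_interval seconds between consecutive images; any positive
#'   value is accepted.
#' @param images a data frame with columns `image_id`, `timestamp`
#'   (POSIXct or ISO 8601 strings), `label` (0/1) and optionally `path`.
#' @return a `camera_project`: list with the fields above and `images` as a
#'   validated tibble sorted by timestamp.
#' @examples
#' prj <- camera_project(
#'   "p01", "2024-05-01", 15,
#'   data.frame(
#'     image_id = sprintf("img%03d", 1:4),
#'     timestamp = as.POSIXct("2024-05-01 12:00:00", tz = "UTC") + 15 * (0:3),
#'     label = c(0, 1, 1, 0)
#'   )
#' )
#' @export
camera_project <- function(participant_id, day_id, capture_interval, images) {
  if (!is.numeric(capture_interval) || length(capture_interval) != 1 ||
    capture_interval <= 0) {
    stop("capture_interval must be a single positive number of seconds",
      call. = FALSE
    )
  }
  images <- tibble::as_tibble(images)
  required <- c("image_id", "timestamp", "label")
  missing_cols <- setdiff(required, names(images))
  if (length(missing_cols) > 0) {
    stop("images lack column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(images) == 0) stop("a project needs at least one image", call. = FALSE)
  if (is.character(images$timestamp)) {
    images$timestamp <- parse_instant(images$timestamp)
  }
  if (!lubridate::is.POSIXct(images$timestamp) || anyNA(images$timestamp)) {
    stop("timestamps must parse as instants (ISO 8601)", call. = FALSE)
  }
  if (!all(images$label %in% c(0, 1))) {
    stop("intake labels must be 0 or 1", call. = FALSE)
  }
  images$label <- as.integer(images$label)
  images$image_id <- as.character(images$image_id)
  if (!"path" %in% names(images)) images$path <- NA_character_
  images <- dplyr::arrange(images, .data$timestamp)
  if (any(duplicated(images$timestamp))) {
    stop("image timestamps must be strictly increasing (duplicates found)",
      call. = FALSE
    )
  }
  if (any(duplicated(images$image_id))) {
    stop("image ids must be unique", call. = FALSE)
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      day_id = as.Date(day_id),
      capture_interval = as.numeric(capture_interval),
      images = images[, c("image_id", "timestamp", "label", "path")]
    ),
    class = "camera_project"
  )
}

parse_instant <- function(x) {
  out <- lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE)
  if (anyNA(out)) {
    stop("timestamps must parse as instants (ISO 8601)", call. = FALSE)
  }
  out
}

#' Read / write a project file
#'
#' The project file is a JSON document holding the image-folder index and the
#' per-image intake labels for one participant-day:
#' `{participant_id, day_id, capture_interval_s, images: [{image_id,
#' timestamp, label, path?}]}`. `write_project()` followed by
#' `read_project()` reproduces the project field-by-field.
#'
#' @param path JSON file path.
#' @return `read_project()` returns a [camera_project()].
#' @export
read_project <- function(path) {
  if (!file.exists(path)) stop("project file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("participant_id", "day_id", "capture_interval_s", "images")
  missing_f <- setdiff(required, names(doc))
  if (length(missing_f) > 0) {
    stop("project file lacks field(s): ", paste(missing_f, collapse = ", "),
      call. = FALSE
    )
  }
  camera_project(
    doc$participant_id, doc$day_id, doc$capture_interval_s,
    tibble::as_tibble(doc$images)
  )
}

#' @rdname read_project
#' @param project a [camera_project()].
#' @export
write_project <- function(project, path) {
  stopifnot(inherits(project, "camera_project"))
  doc <- list(
    participant_id = project$participant_id,
    day_id = format(project$day_id),
    capture_interval_s = project$capture_interval,
    images = data.frame(
      image_id = project$images$image_id,
      timestamp = format_instant(project$images$timestamp),
      label = project$images$label,
      path = project$images$path
    )
  )
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

format_instant <- function(t) {
  lubridate::format_ISO8601(lubridate::with_tz(t, "UTC"), usetz = TRUE)
}

#' @export
print.camera_project <- function(x, ...) {
  cat(
    "<camera_project> participant ", x$participant_id, ", ",
    format(x$day_id), ": ", nrow(x$images), " images @ ",
    x$capture_interval, " s, ", sum(x$images$label), " labeled intake\n",
    sep = ""
  )
  invisible(x)
}

#' @describeIn camera_project `tidy()` returns the image tibble.
#' @param x a `camera_project`.
#' @param ... unused.
#' @export
tidy.camera_project <- function(x, ...) x$images

#' @describeIn camera_project `glance()` returns a one-row overview:
#'   image counts, labeled count, recording span.
#' @export
glance.camera_project <- function(x, ...) {
  tibble::tibble(
    participant_id = x$participant_id,
    day_id = x$day_id,
    capture_interval_s = x$capture_interval,
    n_images = nrow(x$images),
    n_intake_labeled = sum(x$images$label),
    first_image = min(x$images$timestamp),
    last_image = max(x$images$timestamp)
  )
}
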