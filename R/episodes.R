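#' Sensor-detected eating episodes from intake labels
#'
#' Converts the per-image binary intake labels of a project into
#' sensor-detected eating-episode (SDEEp) boundaries. Maximal runs of
#' intake-labeled images form candidate episodes; two consecutive runs are
#' merged when the non-intake time between them (from the end of the earlier
#' run, i.e. its last intake image plus one capture interval, to the first
#' intake image of the later run) is at most `merge_gap` seconds. Merged runs
#' containing fewer than `min_images` intake-labeled images are dropped; the
#' ids of intake images lost that way are reported in the `dropped_images`
#' attribute rather than disappearing silently.
#'
#' An episode starts at the timestamp of its first intake image and ends at
#' the timestamp of its last intake image plus one capture interval, so a
#' single intake image yields an episode of one capture interval. Episodes
#' are non-overlapping, sorted by start time, and initially `unreviewed`.
#'
#' @param project a [camera_project()].
#' @param merge_gap maximum non-intake seconds bridged between runs
#'   (default 60, tolerating short within-meal pauses at a 15 s capture
#'   interval).
#' @param min_images minimum number of intake-labeled images an episode must
#'   contain (default 1).
#' @return a tibble with one row per episode: `episode_id`, `start`, `end`,
#'   `n_images` (intake-labeled images inside), `status`
#'   (`"unreviewed"`/`"true"`/`"false"`). All labels 0 gives zero rows.
#' @examples
#' prj <- simulate_day(seed = 7)$project
#' detect_episodes(prj)
#' @export
detect_episodes <- function(project, merge_gap = 60, min_images = 1) {
  stopifnot(inherits(project, "camera_project"))
  if (merge_gap < 0) stop("merge_gap must be >= 0", call. = FALSE)
  if (min_images < 1) stop("min_images must be >= 1", call. = FALSE)

  imgs <- project$images
  on_idx <- which(imgs$label == 1L)
  empty <- tibble::tibble(
    episode_id = integer(0),
    start = imgs$timestamp[0],
    end = imgs$timestamp[0],
    n_images = integer(0),
    status = character(0)
  )
  if (length(on_idx) == 0) {
    return(structure(empty, dropped_images = character(0)))
  }

  t_on <- as.numeric(imgs$timestamp[on_idx])
  interval <- project$capture_interval
  # non-intake time between consecutive intake images; <= merge_gap keeps
  # them in the same episode (0 for images one interval apart)
  gap <- diff(t_on) - interval
  new_run <- c(TRUE, gap > merge_gap)
  run_id <- cumsum(new_run)

  starts <- as.numeric(tapply(t_on, run_id, min))
  ends <- as.numeric(tapply(t_on, run_id, max)) + interval
  counts <- as.integer(table(run_id))

  keep <- counts >= min_images
  dropped <- imgs$image_id[on_idx[!keep[run_id]]]

  out <- tibble::tibble(
    episode_id = seq_len(sum(keep)),
    start = lubridate::as_datetime(starts[keep], tz = "UTC"),
    end = lubridate::as_datetime(ends[keep], tz = "UTC"),
    n_images = counts[keep],
    status = "unreviewed"
  )
  structure(out, dropped_images = as.character(dropped))
}

#' Images belonging to an episode
#'
#' All project images whose timestamp lies in `[start, end)` of the episode,
#' in time order — the set an annotator reviews for that episode.
#'
#' @param project a [camera_project()].
#' @param episode one row of a [detect_episodes()] tibble.
#' @return a tibble of image records.
#' @export
episode_images <- function(project, episode) {
  stopifnot(inherits(project, "camera_project"))
  episode <- tibble::as_tibble(episode)
  if (nrow(episode) != 1) stop("episode must be a single row", call. = FALSE)
  span <- range(project$images$timestamp)
  if (episode$start > span[2] + project$capture_interval ||
    episode$end < span[1]) {
    stop("episode does not belong to this project", call. = FALSE)
  }
  dplyr::filter(
    project$images,
    .data$timestamp >= episode$start, .data$timestamp < episode$end
  )
}

#' Review-burden metrics across projects
#'
#' Quantifies how much human review the sensor guidance saves: of all images
#' captured across the given projects, what share falls inside detected
#' eating episodes (and must be reviewed), and what share can be ignored.
#' The two shares sum to exactly 100 before display rounding; displayed
#' percentages are rounded half away from zero to whole percents.
#'
#' @param projects a [camera_project()] or list of them.
#' @param episodes a [detect_episodes()] tibble or list of them, parallel to
#'   `projects`.
#' @return a one-row tibble: `n_projects`, `total_images`,
#'   `detected_images` (in-episode), `labeled_images` (individually labeled
#'   intake), `pct_reviewed`, `pct_reduction` (full precision) and
#'   `pct_reviewed_display`, `pct_reduction_display` (whole percents).
#' @examples
#' prj <- simulate_day(seed = 1)$project
#' review_metrics(prj, detect_episodes(prj))
#' @export
review_metrics <- function(projects, episodes) {
  if (inherits(projects, "camera_project")) projects <- list(projects)
  if (is.data.frame(episodes)) episodes <- list(episodes)
  if (length(projects) == 0) stop("at least one project required", call. = FALSE)
  if (length(projects) != length(episodes)) {
    stop("projects and episodes must have the same length", call. = FALSE)
  }
  total <- sum(vapply(projects, function(p) nrow(p$images), integer(1)))
  if (total == 0) stop("no images in any project", call. = FALSE)
  detected <- sum(unlist(purrr::map2(projects, episodes, function(p, e) {
    if (nrow(e) == 0) {
      return(0L)
    }
    sum(vapply(seq_len(nrow(e)), function(i) {
      nrow(episode_images(p, e[i, ]))
    }, integer(1)))
  })))
  labeled <- sum(vapply(projects, function(p) sum(p$images$label), integer(1)))
  pct <- 100 * detected / total
  tibble::tibble(
    n_projects = length(projects),
    total_images = total,
    detected_images = detected,
    labeled_images = labeled,
    pct_reviewed = pct,
    pct_reduction = 100 - pct,
    pct_reviewed_display = round_half_away(pct),
    pct_reduction_display = round_half_away(100 - pct)
  )
}

# round to integer, halves away from zero (base round() goes to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Review-burden arithmetic from printed counts
#'
#' The same arithmetic as [review_metrics()] but applied directly to image
#' counts (e.g. study-level totals from a published table) rather than to
#' project objects.
#'
#' @param total_images total images captured.
#' @param detected_images images inside sensor-detected episodes.
#' @return the same one-row tibble as [review_metrics()] minus the
#'   project-derived columns.
#' @examples
#' review_metrics_from_counts(180520, 12267)
#' @export
review_metrics_from_counts <- function(total_images, detected_images) {
  if (total_images <= 0) stop("total_images must be positive", call. = FALSE)
  if (detected_images < 0 || detected_images > total_images) {
    stop("detected_images must lie in [0, total_images]", call. = FALSE)
  }
  pct <- 100 * detected_images / total_images
  tibble::tibble(
    total_images = total_images,
    detected_images = detected_images,
    pct_reviewed = pct,
    pct_reduction = 100 - pct,
    pct_reviewed_display = round_half_away(pct),
    pct_reduction_display = round_half_away(100 - pct)
  )
}

#' Mark an episode as a true or false detection
#'
#' After reviewing an episode's images the annotator marks the
#' sensor-detected episode as a true eating episode (food visible) or a false
#' one (no food). Re-review is allowed: the last verdict wins.
#'
#' @param episodes a [detect_episodes()] tibble.
#' @param episode_id id of the episode to mark.
#' @param verdict `"true"` or `"false"` (or `"unreviewed"` to reset).
#' @return the episodes tibble with the status updated.
#' @export
mark_episode <- function(episodes, episode_id, verdict) {
  verdict <- match.arg(as.character(verdict), c("true", "false", "unreviewed"))
  i <- which(episodes$episode_id == episode_id)
  if (length(i) != 1) {
    stop("no episode with id ", episode_id, call. = FALSE)
  }
  episodes$status[i] <- verdict
  episodes
}

#' Tally of episode review statuses
#'
#' @param episodes a [detect_episodes()] tibble.
#' @return a one-row tibble with `n_true`, `n_false`, `n_unreviewed`,
#'   `n_episodes` (the three statuses always sum to `n_episodes`).
#' @export
episode_status_counts <- function(episodes) {
  tibble::tibble(
    n_true = sum(episodes$status == "true"),
    n_false = sum(episodes$status == "false"),
    n_unreviewed = sum(episodes$status == "unreviewed"),
    n_episodes = nrow(episodes)
  )
}
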