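test_that("project construction validates labels, timestamps and ordering", {
  expect_error(label_project(c(0, 1, 2)), "0 or 1")
  expect_error(
    camera_project("p", "2024-05-01", 0, tibble::tibble(
      image_id = "a", timestamp = Sys.time(), label = 1
    )),
    "positive"
  )
  expect_error(
    camera_project("p", "2024-05-01", 15, tibble::tibble(
      image_id = c("a", "b"),
      timestamp = rep(as.POSIXct("2024-05-01 08:00:00", tz = "UTC"), 2),
      label = c(0, 1)
    )),
    "duplicates"
  )
  # images supplied out of order come back sorted
  ts <- as.POSIXct("2024-05-01 08:00:00", tz = "UTC") + c(30, 0, 15)
  prj <- camera_project("p", "2024-05-01", 15, tibble::tibble(
    image_id = c("c", "a", "b"), timestamp = ts, label = c(1, 0, 0)
  ))
  expect_equal(prj$images$image_id, c("a", "b", "c"))
})

test_that("project files round-trip field-by-field", {
  sim <- simulate_day(seed = 21, fp_rate = 0.05, fn_rate = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_project(sim$project, path)
  back <- read_project(path)
  expect_equal(back$participant_id, sim$project$participant_id)
  expect_equal(back$day_id, sim$project$day_id)
  expect_equal(back$capture_interval, sim$project$capture_interval)
  expect_equal(back$images$image_id, sim$project$images$image_id)
  expect_equal(back$images$label, sim$project$images$label)
  expect_true(all(back$images$timestamp == sim$project$images$timestamp))
  expect_error(read_project("no-such-file.json"), "not found")
})

test_that("episode boundaries follow the run/merge/min-images rules", {
  # all labels zero: no episodes
  expect_equal(nrow(detect_episodes(label_project(rep(0, 20)))), 0)

  # one contiguous run: one episode spanning first-1 to last-1 + interval
  labels <- c(rep(0, 5), rep(1, 4), rep(0, 6))
  prj <- label_project(labels, interval = 15)
  eps <- detect_episodes(prj)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$start, prj$images$timestamp[6])
  expect_equal(eps$end, prj$images$timestamp[9] + 15)
  expect_equal(eps$n_images, 4L)

  # two runs separated by 3 non-intake images (45 s gap): merged at the
  # default 60 s merge gap, split with merge_gap = 30
  labels2 <- c(1, 1, 0, 0, 0, 1, 1)
  prj2 <- label_project(labels2, interval = 15)
  expect_equal(nrow(detect_episodes(prj2, merge_gap = 60)), 1)
  expect_equal(nrow(detect_episodes(prj2, merge_gap = 30)), 2)

  # min_images drops small runs and reports the dropped intake images
  labels3 <- c(1, 0, 0, 0, 0, 0, 0, 1, 1, 1)
  prj3 <- label_project(labels3, interval = 15)
  eps3 <- detect_episodes(prj3, merge_gap = 30, min_images = 2)
  expect_equal(nrow(eps3), 1)
  expect_equal(attr(eps3, "dropped_images"), prj3$images$image_id[1])
})

test_that("segmentation matches the brute-force merge oracle on random labels", {
  set.seed(404)
  for (rep in 1:60) {
    n <- sample(10:400, 1)
    labels <- rbinom(n, 1, runif(1, 0.05, 0.6))
    interval <- sample(c(10, 15), 1)
    merge_gap <- sample(c(0, 15, 30, 60, 120), 1)
    min_images <- sample(1:3, 1)
    prj <- label_project(labels, interval = interval)
    got <- detect_episodes(prj, merge_gap, min_images)
    want <- oracle_episodes(
      prj$images$timestamp, labels, interval, merge_gap, min_images
    )
    expect_equal(nrow(got), nrow(want))
    expect_equal(as.numeric(got$start), want$start)
    expect_equal(as.numeric(got$end), want$end)
    expect_equal(got$n_images, want$n)
  }
})

test_that("episode images partition the intake images", {
  set.seed(99)
  for (rep in 1:20) {
    labels <- rbinom(sample(30:200, 1), 1, 0.3)
    prj <- label_project(labels)
    eps <- detect_episodes(prj, merge_gap = sample(c(0, 30, 60), 1))
    seen <- character(0)
    for (i in seq_len(nrow(eps))) {
      ids <- episode_images(prj, eps[i, ])$image_id
      # disjointness: no image in two episodes
      expect_length(intersect(seen, ids), 0)
      seen <- c(seen, ids)
    }
    # coverage: every intake image falls inside some episode (min_images = 1)
    intake <- prj$images$image_id[prj$images$label == 1]
    expect_true(all(intake %in% seen))
  }
})

test_that("review metrics sum to 100 and round half away from zero", {
  # published study-level counts
  us <- review_metrics_from_counts(180520, 12267)
  expect_equal(us$pct_reviewed, 100 * 12267 / 180520)
  expect_equal(us$pct_reviewed_display, 7)
  expect_equal(us$pct_reviewed + us$pct_reduction, 100)

  ghana <- review_metrics_from_counts(138076, 20005)
  expect_lte(ghana$pct_reviewed_display, 15)
  expect_gte(ghana$pct_reduction_display, 85)

  # degenerate corners
  all_in <- review_metrics_from_counts(50, 50)
  expect_equal(all_in$pct_reviewed, 100)
  expect_equal(all_in$pct_reduction, 0)
  none <- review_metrics_from_counts(50, 0)
  expect_equal(none$pct_reviewed, 0)
  expect_equal(none$pct_reduction, 100)
  expect_error(review_metrics_from_counts(0, 0), "positive")

  # project-derived metrics agree with count-derived ones
  sim <- simulate_day(seed = 31)
  eps <- detect_episodes(sim$project)
  m <- review_metrics(sim$project, eps)
  expect_equal(m$pct_reviewed + m$pct_reduction, 100)
  expect_equal(
    m$pct_reviewed,
    review_metrics_from_counts(m$total_images, m$detected_images)$pct_reviewed
  )
  # display rounding: half away from zero (e.g. 6.5 -> 7, not banker's 6)
  expect_equal(review_metrics_from_counts(200, 13)$pct_reviewed_display, 7)
})

test_that("episode verdicts persist with last-verdict-wins and conserve counts", {
  prj <- label_project(c(1, 1, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 0, 1))
  eps <- detect_episodes(prj, merge_gap = 30)
  expect_equal(nrow(eps), 3)
  expect_true(all(eps$status == "unreviewed"))
  eps <- mark_episode(eps, 1, "true")
  eps <- mark_episode(eps, 2, "false")
  eps <- mark_episode(eps, 2, "true") # re-review: last verdict wins
  counts <- episode_status_counts(eps)
  expect_equal(counts$n_true, 2)
  expect_equal(counts$n_false, 0)
  expect_equal(counts$n_unreviewed, 1)
  expect_equal(counts$n_true + counts$n_false + counts$n_unreviewed, counts$n_episodes)
  expect_error(mark_episode(eps, 9, "true"), "no episode")
})
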