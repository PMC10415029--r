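make_day <- function(labels = c(0, 1, 1, 1, 0, 0, 0, 0, 1, 1, 0),
                     interval = 15) {
  prj <- label_project(labels, interval = interval)
  day_annotation(prj, detect_episodes(prj, merge_gap = 30))
}

test_that("meals get sequential ids and validated explicit times", {
  day <- make_day()
  day <- add_meal(day, "lunch",
    start = "2024-05-01 12:00:00", end = "2024-05-01 12:30:00"
  )
  day <- add_meal(day, "afternoon tea") # free-text label allowed
  ml <- meals(day)
  expect_equal(ml$aeep_id, 1:2)
  expect_equal(ml$meal_label, c("lunch", "afternoon tea"))
  expect_equal(ml$start[1], as.POSIXct("2024-05-01 12:00:00", tz = "UTC"))
  expect_true(is.na(ml$start[2]))
  expect_error(
    add_meal(day, "x", start = "2024-05-01 13:00:00", end = "2024-05-01 12:00:00"),
    "start must not be after"
  )
})

test_that("image links auto-populate meal times from linked timestamps", {
  prj <- camera_project(
    "p", "2024-05-01", 15,
    tibble::tibble(
      image_id = c("a", "b", "c"),
      timestamp = as.POSIXct(
        c("2024-05-01 12:00:00", "2024-05-01 12:02:00", "2024-05-01 12:05:00"),
        tz = "UTC"
      ),
      label = c(1, 1, 1)
    )
  )
  day <- day_annotation(prj)
  day <- add_meal(day, "lunch")
  day <- link_image(day, 1, "a")
  day <- link_image(day, 1, "c")
  ml <- meals(day)
  # min/max of linked images; end extended by one capture interval
  expect_equal(ml$start, as.POSIXct("2024-05-01 12:00:00", tz = "UTC"))
  expect_equal(ml$end, as.POSIXct("2024-05-01 12:05:15", tz = "UTC"))

  # single image: start = image time, end = start + interval
  day2 <- add_meal(day_annotation(prj), "snack")
  day2 <- link_image(day2, 1, "b")
  ml2 <- meals(day2)
  expect_equal(ml2$start, as.POSIXct("2024-05-01 12:02:00", tz = "UTC"))
  expect_equal(as.numeric(ml2$end - ml2$start, units = "secs"), 15)

  # set semantics and idempotent auto-population
  day3 <- link_image(day, 1, "a")
  expect_equal(meals(day3)$n_images, 2)
  expect_equal(meals(day3)$start, ml$start)
  expect_equal(meals(day3)$end, ml$end)

  # foreign image rejected; double-linking across meals warns
  expect_error(link_image(day, 1, "zz"), "does not belong")
  day4 <- add_meal(day, "drink")
  expect_warning(link_image(day4, 2, "a"), "already linked")
})

test_that("time lookup ties images, sensor episodes and meals together", {
  day <- make_day()
  prj <- day$project
  day <- add_meal(day, "snack")
  day <- link_image(day, 1, prj$images$image_id[2])
  day <- link_image(day, 1, prj$images$image_id[4])

  hit <- lookup_time(day, prj$images$timestamp[3])
  expect_equal(hit$image$image_id, prj$images$image_id[3])
  expect_equal(nrow(hit$episode), 1)
  expect_equal(hit$meals$aeep_id, 1)

  # an instant in the non-intake stretch hits no sensor episode
  gap_hit <- lookup_time(day, prj$images$timestamp[7])
  expect_equal(nrow(gap_hit$episode), 0)

  # out-of-day instants are rejected
  expect_error(lookup_time(day, "2024-05-02 08:00:00"), "outside")

  # property: looking up any image timestamp returns that image
  for (i in seq_len(nrow(prj$images))) {
    expect_equal(
      lookup_time(day, prj$images$timestamp[i])$image$image_id,
      prj$images$image_id[i]
    )
  }
})

test_that("food items validate portions and amounts and derive consumption", {
  db <- hand_db()
  rice <- db$records[1, ] # cup = 240 g, 52 kcal / 100 g
  day <- make_day()
  day <- add_meal(day, "lunch")
  day <- add_food_item(day, 1, rice, "solid", "1", "cup", "1/3", "cup")
  it <- food_items(day)
  expect_equal(it$consumed_amount, "2/3")
  expect_equal(it$consumed_grams, 160)
  expect_equal(it$energy_kcal, 160 * 52 / 100)

  # leftover omitted means zero
  day2 <- add_food_item(make_day() |> add_meal("x"), 1, rice, "solid", "2", "cup")
  expect_equal(food_items(day2)$consumed_amount, "2")

  # leftover exceeding the initial amount is rejected
  expect_error(
    add_food_item(day, 1, rice, "solid", "1", "cup", "2", "cup"),
    "exceeds"
  )
  # unknown portion label is rejected
  expect_error(
    add_food_item(day, 1, rice, "solid", "1", "bowl"),
    "not offered"
  )
  # mixed units: leftover in tablespoons against a cup initial
  day3 <- add_food_item(make_day() |> add_meal("x"), 1, rice,
    "solid", "1", "cup", "4", "tablespoon"
  )
  expect_equal(food_items(day3)$consumed_grams, 240 - 60)
  expect_equal(food_items(day3)$consumed_amount, "3/4")
})

test_that("annotation sessions round-trip through JSON", {
  reg <- register_db(food_registry(), hand_db())
  rice <- get_food(reg, "hand", "10001")
  brown <- get_food(reg, "hand", "10002")

  day <- make_day()
  day$started <- as.POSIXct("2024-05-02 09:00:00", tz = "UTC")
  day$finished <- day$started + 1093
  day <- review_episode(day, 1, "true")
  day <- review_episode(day, 2, "false")
  day <- add_meal(day, "lunch")
  day <- link_image(day, 1, day$project$images$image_id[2])
  day <- add_food_item(day, 1, rice, "solid", "1", "cup", "1/3", "cup")
  day <- add_meal(day, "snack", start = "2024-05-01 08:02:00", end = "2024-05-01 08:03:00")
  day <- add_food_item(day, 2, brown, "semi-solid", "1/2", "cup")

  path <- withr::local_tempfile(fileext = ".json")
  write_annotation(day, path)
  back <- read_annotation(path, reg)

  expect_equal(back$episodes$status, day$episodes$status)
  expect_equal(meals(back), meals(day))
  expect_equal(food_items(back), food_items(day))
  expect_equal(annotation_duration(back), 1093)
  expect_equal(
    summarize_day(back)$energy_kcal,
    summarize_day(day)$energy_kcal
  )

  # truncated file is a format error, not a crash
  txt <- readLines(path)
  writeLines(txt[1:(length(txt) %/% 2)], path)
  expect_error(read_annotation(path, reg), "cannot parse|schema")
})

test_that("round-trip holds for arbitrary generated annotation sessions", {
  reg <- toy_registry(dialects = c("sr", "fao"), n_foods = 12, seed = 42)
  for (s in 1:5) {
    sim <- simulate_day(seed = s, fp_rate = 0.01, fn_rate = 0.1)
    day <- simulate_annotations(sim$project, reg, seed = s * 7)
    path <- withr::local_tempfile(fileext = ".json")
    write_annotation(day, path)
    back <- read_annotation(path, reg)
    expect_equal(meals(back), meals(day))
    expect_equal(food_items(back), food_items(day))
    expect_equal(back$episodes$status, day$episodes$status)
    expect_equal(summarize_day(back), summarize_day(day), ignore_attr = TRUE)
  }
})
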