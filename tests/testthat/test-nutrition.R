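test_that("consumed amount subtracts leftover exactly", {
  # the canonical worked example: 1 cup served, 1/3 cup left -> 2/3 cup
  expect_identical(format(consumed_amount(1, "1/3")), "2/3")
  # identity when nothing is left over
  for (x in c("1", "3/4", "2 1/2", "0.6")) {
    expect_identical(format(consumed_amount(x, 0)), format(parse_amount(x)))
  }
  expect_error(consumed_amount("1", "3/2"), "exceeds")
  expect_error(consumed_amount("1", "-1"), ">= 0")
})

test_that("mixed portion units resolve through grams", {
  opts <- tibble::tibble(
    label = c("cup", "tablespoon", "gram"),
    gram_weight = c(240, 15, 1)
  )
  got <- consumed_amount("1", "4",
    initial_portion = "cup", leftover_portion = "tablespoon", portions = opts
  )
  expect_equal(as.numeric(got), 0.75) # 240 g - 60 g = 180 g = 3/4 cup
  expect_error(
    consumed_amount("1", "20",
      initial_portion = "cup", leftover_portion = "tablespoon", portions = opts
    ),
    "exceeds"
  )
  expect_error(
    consumed_amount("1", "1",
      initial_portion = "cup", leftover_portion = "tablespoon"
    ),
    "portions table required"
  )
})

test_that("gram conversion is linear in the portion weight", {
  opts <- tibble::tibble(label = c("cup", "gram"), gram_weight = c(240, 1))
  expect_equal(amount_to_grams(1, "cup", opts), 240)
  expect_equal(amount_to_grams("2/3", "cup", opts), 160)
  expect_equal(amount_to_grams(0, "cup", opts), 0)
  expect_equal(amount_to_grams(37, "gram", opts), 37)
  expect_error(amount_to_grams(1, "bowl", opts), "unknown portion")
  expect_error(amount_to_grams(-1, "cup", opts), ">= 0")
})

test_that("nutrient intake scales per-100 g values linearly and flags gaps", {
  db <- hand_db()
  rice <- db$records[1, ] # 52 kcal, fiber missing
  at100 <- nutrient_intake(100, rice)
  expect_equal(at100$energy_kcal, 52)
  at150 <- nutrient_intake(150, rice)
  expect_equal(at150$energy_kcal, 78)
  # linearity: energy(alpha * g) = alpha * energy(g)
  expect_equal(nutrient_intake(75, rice)$energy_kcal, 0.75 * at100$energy_kcal)
  # zero grams: all-zero vector, nothing newly missing
  at0 <- nutrient_intake(0, rice)
  expect_true(all(at0$nutrients$value == 0 | is.na(at0$nutrients$value)))
  expect_equal(at0$energy_kcal, 0)
  # missing source nutrients stay missing and are flagged
  expect_true("fiber" %in% at150$missing_nutrients)
  expect_true(is.na(at150$nutrients$value[at150$nutrients$nutrient == "fiber"]))
  prot <- at150$nutrients$value[at150$nutrients$nutrient == "protein"]
  expect_equal(prot, 1.1 * 1.5)
})

test_that("monotonicity: larger leftovers never increase consumption", {
  db <- hand_db()
  rice <- db$records[1, ]
  opts <- portion_options(rice)
  leftovers <- c("0", "1/4", "1/3", "1/2", "3/4", "1")
  grams <- vapply(leftovers, function(l) {
    amount_to_grams(consumed_amount("1", l), "cup", opts)
  }, numeric(1))
  expect_true(all(diff(grams) <= 0))
  energies <- vapply(grams, function(g) nutrient_intake(g, rice)$energy_kcal,
    numeric(1)
  )
  expect_true(all(diff(energies) <= 0))
})

test_that("item, episode and daily totals are conserved", {
  db <- hand_db()
  reg <- register_db(food_registry(), db)
  rice <- db$records[1, ]
  brown <- db$records[2, ]
  prj <- label_project(c(1, 1, 1, 0, 0, 0, 0, 0, 1, 1))
  day <- day_annotation(prj, detect_episodes(prj, merge_gap = 30))
  day <- add_meal(day, "lunch")
  day <- add_food_item(day, 1, rice, "solid", "1", "cup", "1/3", "cup") # 160 g, 83.2 kcal
  day <- add_food_item(day, 1, brown, "solid", "1", "cup") # 195 g, 234 kcal
  day <- add_meal(day, "snack")
  day <- add_food_item(day, 2, rice, "solid", "100", "gram") # 100 g, 52 kcal

  ms <- summarize_meals(day)
  expect_equal(ms$n_foods, c(2, 1))
  expect_equal(ms$energy_kcal, c(160 * 0.52 + 234, 52))
  expect_equal(ms$weight_g, c(355, 100))

  daily <- summarize_day(day)
  expect_equal(daily$n_aeep, 2)
  expect_equal(daily$n_foods, 3)
  expect_identical(daily$energy_kcal, sum(ms$energy_kcal))
  expect_identical(daily$weight_g, sum(ms$weight_g))

  # per-nutrient totals skip missing values but count them
  totals <- attr(daily, "nutrient_totals")
  calcium <- totals[totals$nutrient == "calcium", ]
  expect_equal(calcium$n_missing_items, 1) # brown rice lacks calcium
  expect_equal(calcium$total, (160 + 100) * 3 / 100)

  # permuting item insertion order leaves the summaries unchanged
  day_perm <- day_annotation(prj, detect_episodes(prj, merge_gap = 30))
  day_perm <- add_meal(day_perm, "lunch")
  day_perm <- add_food_item(day_perm, 1, brown, "solid", "1", "cup")
  day_perm <- add_food_item(day_perm, 1, rice, "solid", "1", "cup", "1/3", "cup")
  day_perm <- add_meal(day_perm, "snack")
  day_perm <- add_food_item(day_perm, 2, rice, "solid", "100", "gram")
  expect_equal(summarize_meals(day_perm)$energy_kcal, ms$energy_kcal)
  expect_equal(summarize_day(day_perm)$energy_kcal, daily$energy_kcal)

  # an empty day sums to zero everywhere
  empty <- summarize_day(day_annotation(prj))
  expect_equal(empty$n_aeep, 0)
  expect_equal(empty$energy_kcal, 0)
  expect_equal(empty$weight_g, 0)
})

test_that("database usage splits items by source with percentages over 100", {
  reg <- toy_registry(dialects = c("sr", "fndds", "fao"), n_foods = 6, seed = 3)
  prj <- label_project(c(1, 1, 1))
  day <- day_annotation(prj)
  day <- add_meal(day, "lunch")
  picks <- c("db_sr", "db_sr", "db_fndds", "db_fao") # 2/1/1 split
  for (db in picks) {
    rec <- reg$dbs[[db]]$records[1, ]
    day <- add_food_item(day, 1, rec, "solid", "50", "gram")
  }
  usage <- db_usage(day)
  expect_equal(sum(usage$n_items), 4)
  expect_equal(
    usage$pct[match(c("db_sr", "db_fndds", "db_fao"), usage$source_db)],
    c(50, 25, 25)
  )
  expect_equal(sum(usage$pct), 100)
  expect_equal(nrow(db_usage(day_annotation(prj))), 0)
})
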