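# Shared fixture builders. Everything is generated in code at test time.

# a minimal project from a label vector, images every `interval` seconds
label_project <- function(labels, interval = 15,
                          participant = "p01", day = "2024-05-01",
                          start = "2024-05-01 08:00:00") {
  n <- length(labels)
  camera_project(
    participant, day, interval,
    tibble::tibble(
      image_id = sprintf("img%05d", seq_len(n)),
      timestamp = as.POSIXct(start, tz = "UTC") + interval * (seq_len(n) - 1),
      label = labels
    )
  )
}

# a registry of toy databases, one per requested dialect, shared seed
toy_registry <- function(dialects = c("sr", "fndds"), n_foods = 20, seed = 101) {
  reg <- food_registry()
  for (i in seq_along(dialects)) {
    csv <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
    make_toy_database(dialects[i], n_foods, seed = seed + i, path = csv)
    reg <- register_db(reg, load_food_db(csv, dialects[i], paste0("db_", dialects[i])))
  }
  reg
}

# a hand-built two-food database for arithmetic tests: values chosen so
# energy/nutrient scaling can be checked by hand
hand_db <- function(name = "hand") {
  csv <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(
    tibble::tibble(
      NDB_No = c("10001", "10002"),
      Shrt_Desc = c("Rice, white, cooked", "Brown rice"),
      FdGrp_Desc = c("Cereals", "Cereals"),
      Energ_Kcal = c("52", "120"),
      `Protein_(g)` = c("1.1", "2.5"),
      `Lipid_Tot_(g)` = c("0.2", "1"),
      `Carbohydrt_(g)` = c("11", "25"),
      `Fiber_TD_(g)` = c("", "1.8"),
      `Calcium_(mg)` = c("3", ""),
      `Iron_(mg)` = c("0.2", "0.5"),
      GmWt_Desc1 = c("cup", "cup"),
      GmWt_1 = c("240", "195"),
      GmWt_Desc2 = c("tablespoon", ""),
      GmWt_2 = c("15", "")
    ),
    csv, na = ""
  )
  load_food_db(csv, "sr", name)
}
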