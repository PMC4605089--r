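test_that("constructors reject single-field corruptions of valid records", {
  expect_s3_class(product_slate(40, 15, 5, 8, 0.4, 6), "product_slate")
  expect_error(product_slate(40, 15, 5, -1, 0.4, 6), "solids_mass_g")
  expect_error(product_slate(0, 15, 5, 8, 0.4, 6), "feed_dry_mass_g")
  expect_error(product_slate(40, 30, 20, 8, 0.4, 6), "105")

  expect_error(fraction_properties(101, 10, 2, 12, 0.1, 36), "carbon_pct")
  expect_error(fraction_properties(77, 10, 2, 12, 0.1, -1), "hhv")

  expect_error(acp_profile(0.1, 659, 1220, 1254, 4281, 15, 16.28), "ph")
  expect_error(acp_profile(-0.1, 659, 1220, 1254, 4281, 3.7, 16.28),
               "no3_no2")

  expect_error(htl_condition(temperature_c = 400), "temperature_c")
  expect_error(htl_condition(300, catalyst_loading_frac = 0.5),
               "catalyst_loading_frac")

  expect_error(gas_profile(c(0.9, 0.1)), "named")
  expect_error(gas_profile(c(CO2 = -0.1, CO = 0.2)), "non-negative")
})

test_that("feedstock proximate closure is enforced, with a tolerance knob", {
  expect_error(
    feedstock_composition(54.92, 8.73, 2.40, 33.85, 3.54, 90.14, 2.50, 7.82,
                          32.77, 16.00, 19.40, 24.88),
    "proximate")
  fs <- yeast_feedstock()   # relaxed tolerance for the printed 103.99 sum
  expect_s3_class(fs, "feedstock_composition")
  expect_equal(fs$hhv_mj_per_kg, 24.88)
  expect_error(
    feedstock_composition(54.92, 8.73, 2.40, 33.85, 3.54, 90.14, 2.50, 7.82,
                          32.77, 16.00, 19.40, 24.88,
                          fatty_acid_profile = c(C16 = 0.5, C18 = 0.4),
                          proximate_tol = 5),
    "fatty_acid_profile")
})

test_that("reference-table transcription round-trips through raw masses", {
  runs <- htl_reference_runs(feed_dry_mass_g = 40)
  expect_length(runs, 4)
  acc <- account_experiments(runs)
  expect_equal(acc$biocrude_yield_pct, c(49.11, 52.61, 56.38, 57.94))
  # b1 + b2 on 40 g feed for the first condition
  expect_equal(runs[[1]]$slate$biocrude1_mass_g +
                 runs[[1]]$slate$biocrude2_mass_g, 19.644)
})

test_that("experiment CSV reader/writer round-trips randomized records", {
  set.seed(42)
  path <- withr::local_tempfile(fileext = ".csv")
  for (rep in 1:5) {
    records <- lapply(1:200, function(i)
      random_run(i, with_acp = runif(1) < 0.7, with_gas = runif(1) < 0.7))
    write_experiment_table(records, path)
    back <- read_experiment_table(path)
    expect_length(back, length(records))
    for (i in seq_along(records)) expect_run_equal(records[[i]], back[[i]])
  }
})

test_that("reader handles empty tables, missing columns and bad cells", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_experiment_table(list(), path)
  expect_identical(read_experiment_table(path), list())

  runs <- htl_reference_runs()
  write_experiment_table(runs, path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)

  bad <- df; bad$feed_dry_mass_g <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_experiment_table(p2), "feed_dry_mass_g")

  bad <- df; bad$solids_g[2] <- "oops"
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_experiment_table(p2), "row 2.*solids_g")

  bad <- df; bad$solids_g[3] <- "-1"
  utils::write.csv(bad, p2, row.names = FALSE)
  expect_error(read_experiment_table(p2), "row 3")
})

test_that("absent optional blocks survive the round trip as absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  records <- list(random_run(1, with_acp = FALSE, with_gas = FALSE),
                  random_run(2, with_acp = TRUE, with_gas = FALSE),
                  random_run(3, with_acp = FALSE, with_gas = TRUE))
  write_experiment_table(records, path)
  back <- read_experiment_table(path)
  expect_null(back[[1]]$acp); expect_null(back[[1]]$gas)
  expect_null(back[[2]]$gas); expect_s3_class(back[[2]]$acp, "acp_profile")
  expect_null(back[[3]]$acp); expect_s3_class(back[[3]]$gas, "gas_profile")
})

test_that("feedstock configs load from JSON and YAML", {
  fs <- yeast_feedstock()
  cfg <- unclass(fs)[c("carbon_pct", "hydrogen_pct", "nitrogen_pct",
                       "oxygen_pct", "moisture_pct", "volatiles_pct",
                       "fixed_carbon_pct", "ash_pct", "lipid_pct",
                       "protein_pct", "carbohydrate_pct", "hhv_mj_per_kg")]
  pj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, pj, auto_unbox = TRUE, digits = NA)
  py <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, py)
  for (p in c(pj, py)) {
    got <- read_feedstock_config(p, proximate_tol = 5)
    expect_equal(got$carbon_pct, 54.92)
    expect_equal(got$hhv_mj_per_kg, 24.88)
  }
})
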