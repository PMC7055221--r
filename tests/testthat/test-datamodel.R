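test_that("protocol invariants and infusate flow", {
  p <- infusion_protocol()
  expect_equal(infusate_flow(p), 1.2)
  expect_error(infusion_protocol(pi_infusion_rate = 0),
               class = "phoskin_error_invalid_protocol")
  expect_error(infusion_protocol(collection_interval = -1),
               class = "phoskin_error_invalid_protocol")
})

test_that("metabolic weight is body_weight^0.75 exactly", {
  expect_identical(metabolic_weight(1), 1)
  expect_identical(metabolic_weight(16), 8)
  expect_equal(metabolic_weight(3.28), 3.28^0.75)
})

test_that("dataset validation rejects malformed records with named errors", {
  animals <- data.frame(animal_id = "A", body_weight_kg = 3)
  plasma <- data.frame(animal_id = "A", time_min = 7.5,
                       plasma_pi_mmol_l = 2.2)
  urine <- data.frame(animal_id = "A", t_start_min = 0, t_end_min = 15,
                      urine_volume_ml = 5, urine_pi_mmol_l = 10)
  expect_s3_class(pi_experiment(infusion_protocol(), animals, plasma, urine),
                  "pi_experiment")
  bad <- urine; bad$t_end_min <- 0
  expect_error(pi_experiment(infusion_protocol(), animals, plasma, bad),
               class = "phoskin_error_collection_order")
  expect_error(
    pi_experiment(infusion_protocol(), animals,
                  transform(plasma, animal_id = "ghost"), urine),
    class = "phoskin_error_unknown_animal")
  overlapping <- rbind(urine,
                       data.frame(animal_id = "A", t_start_min = 10,
                                  t_end_min = 25, urine_volume_ml = 5,
                                  urine_pi_mmol_l = 10))
  expect_error(pi_experiment(infusion_protocol(), animals, plasma,
                             overlapping),
               class = "phoskin_error_overlapping_collections")
  expect_error(pi_experiment(infusion_protocol(), animals, plasma,
                             urine[, -3]),
               class = "phoskin_error_missing_column")
  expect_error(pi_experiment(infusion_protocol(), animals, plasma, urine,
                             ultrafilterable_fraction = 1.2),
               class = "phoskin_error_invalid_value")
})

test_that("plasma sample off any collection midpoint warns but is retained", {
  animals <- data.frame(animal_id = "A", body_weight_kg = 3)
  plasma <- data.frame(animal_id = "A", time_min = 3,
                       plasma_pi_mmol_l = 2.2)
  urine <- data.frame(animal_id = "A", t_start_min = 0, t_end_min = 15,
                      urine_volume_ml = 5, urine_pi_mmol_l = 10)
  expect_warning(
    d <- pi_experiment(infusion_protocol(), animals, plasma, urine),
    class = "phoskin_warning_unmatched_plasma")
  expect_equal(nrow(d$plasma), 1)
})

test_that("write then read reproduces a simulated cohort field-for-field", {
  sim <- simulate_cohort(simulation_config(n_animals = 3, rng_seed = 11))
  dir <- withr::local_tempdir()
  write_experiment(sim$dataset, dir)
  back <- read_experiment(dir)
  expect_equal(back$animals$body_weight_kg, sim$dataset$animals$body_weight_kg)
  expect_equal(back$plasma, sim$dataset$plasma)
  expect_equal(back$urine, sim$dataset$urine)
  expect_identical(unclass(back$protocol), unclass(sim$dataset$protocol))
  expect_identical(back$ultrafilterable_fraction,
                   sim$dataset$ultrafilterable_fraction)
  # re-analysis of the round-tripped data gives the identical table
  t1 <- build_kinetics_table(sim$dataset, gfr = 16.3)
  t2 <- build_kinetics_table(back, gfr = 16.3)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("empty urine table round-trips as a header-only file", {
  animals <- data.frame(animal_id = "A", body_weight_kg = 3)
  plasma <- data.frame(animal_id = "A", time_min = -7.5,
                       plasma_pi_mmol_l = 2.2)
  urine <- data.frame(animal_id = character(), t_start_min = numeric(),
                      t_end_min = numeric(), urine_volume_ml = numeric(),
                      urine_pi_mmol_l = numeric())
  d <- pi_experiment(infusion_protocol(), animals, plasma, urine)
  dir <- withr::local_tempdir()
  paths <- write_experiment(d, dir)
  expect_length(readLines(paths[["urine"]]), 1L)
  expect_equal(nrow(read_experiment(dir)$urine), 0L)
})

test_that("reader flags unparseable numbers and missing files", {
  dir <- withr::local_tempdir()
  sim <- simulate_cohort(simulation_config(n_animals = 1, rng_seed = 2))
  write_experiment(sim$dataset, dir)
  an <- read.csv(file.path(dir, "animals.csv"))
  an$body_weight_kg <- "three"
  write.csv(an, file.path(dir, "animals.csv"), row.names = FALSE)
  expect_error(read_experiment(dir), class = "phoskin_error_bad_number")
  unlink(file.path(dir, "plasma.csv"))
  expect_error(read_experiment(dir), class = "phoskin_error_missing_file")
})
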