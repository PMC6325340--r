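test_that("zero altitude noise gives exactly the nominal footprint", {
  sv <- survey_spec(units_per_area = 2, replicates_per_area = 1,
                    altitude_sd = 1e-12)
  sim <- simulate_survey(areas = default_area_polygons()["Flat"],
                         survey = sv, populate = FALSE, seed = 1)
  expect_equal(sim$images$footprint, rep(1.71, nrow(sim$images)),
               tolerance = 1e-6)
})

test_that("the requested number of units is surveyed in every area", {
  sv <- survey_spec(units_per_area = 40, replicates_per_area = 4)
  sim <- simulate_survey(survey = sv, populate = FALSE, seed = 2)
  expect_equal(as.vector(table(unique(sim$images[, c("area", "unit")])$area)),
               rep(40L, 3))
})

test_that("footprint follows the altitude-squared law exactly", {
  sim <- simulate_survey(
    areas = default_area_polygons()["Flat"],
    survey = survey_spec(units_per_area = 2, replicates_per_area = 1),
    populate = FALSE, seed = 3)
  expect_equal(sim$images$footprint,
               1.71 * (sim$images$altitude / 3)^2, tolerance = 1e-12)
})

test_that("survey output is byte-identical across runs with the same seed", {
  args <- list(survey = survey_spec(units_per_area = 3,
                                    replicates_per_area = 2),
               community = generate_community(seed = 40),
               nodule_fields = nodule_field_spec(mean_cover = 5),
               seed = 41)
  s1 <- do.call(simulate_survey, args)
  s2 <- do.call(simulate_survey, args)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$specimens, s2$specimens)
  expect_identical(s1$nodules, s2$nodules)
})

test_that("every-second-image discard and subsampling hit the 1321-1324 m2 window", {
  # constructed unit: 1546 usable images at exactly 1.71 m2
  n <- 1546
  img <- data.frame(
    area = "Flat", unit = "Flat-01", seq = seq_len(n),
    x = seq_len(n), y = 0, altitude = 3, footprint = 1.71,
    junction = FALSE, image_id = paste0("Flat-01-", seq_len(n)),
    stringsAsFactors = FALSE)
  sim <- structure(list(images = img, specimens = benthosurvey:::empty_specimens(),
                        nodules = data.frame(image_id = character(),
                                             area_cm2 = numeric()),
                        survey = survey_spec(units_per_area = 1,
                                             replicates_per_area = 1),
                        areas = NULL, community = NULL,
                        nodule_fields = NULL, populated = FALSE),
                   class = "survey_sim")
  std <- standardize_units(sim, seed = 5)
  expect_equal(std$unit_table$n_images, 773)        # ceil(1546 / 2)
  expect_equal(std$unit_table$area_m2, 773 * 1.71, tolerance = 1e-9)
  expect_true(std$unit_table$area_m2 >= 1321 && std$unit_table$area_m2 <= 1324)
})

test_that("units flying outside the altitude window are excluded with a warning", {
  n <- 200
  img <- data.frame(
    area = "Flat", unit = "Flat-01", seq = seq_len(n),
    x = seq_len(n), y = 0, altitude = 5,
    footprint = 1.71 * (5 / 3)^2, junction = FALSE,
    image_id = paste0("Flat-01-", seq_len(n)), stringsAsFactors = FALSE)
  sim <- structure(list(images = img, specimens = benthosurvey:::empty_specimens(),
                        nodules = data.frame(image_id = character(),
                                             area_cm2 = numeric()),
                        survey = survey_spec(units_per_area = 1,
                                             replicates_per_area = 1),
                        areas = NULL, community = NULL, nodule_fields = NULL,
                        populated = FALSE),
                   class = "survey_sim")
  expect_warning(
    expect_error(standardize_units(sim, seed = 6), "standardized"),
    "cannot be standardized")
})

test_that("standardized units land in the window with typical image counts", {
  std <- small_survey()
  expect_true(all(std$unit_table$area_m2 >= 1321 &
                    std$unit_table$area_m2 <= 1324))
  expect_true(all(std$unit_table$n_images >= 555 - 100 &
                    std$unit_table$n_images <= 781 + 100))
  expect_equal(as.vector(table(std$unit_table$area)), rep(2L, 3))
})

test_that("area too small for the requested track is rejected", {
  sv <- survey_spec(units_per_area = 40)
  expect_error(
    simulate_survey(areas = list(Flat = c(0, 1000, 0, 1000)), survey = sv,
                    populate = FALSE, seed = 7),
    "too small")
})
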