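test_that("animal categories combine species and purpose, camel meat excluded", {
  expect_identical(animal_category("cattle", "dairy"), "cattle_dairy")
  expect_identical(animal_category("shoats", "meat"), "shoats_meat")
  expect_error(animal_category("camel", "meat"), "camel meat")
  expect_error(animal_category("sheep", "dairy"))
  cats <- animal_categories()
  expect_equal(nrow(cats), 5)
  expect_false("camel_meat" %in% cats$category)
  expect_true("shoats_dairy" %in% cats$category)  # sheep+goats never split
})

test_that("systems, scenarios and feed classes are closed enumerations", {
  expect_setequal(production_systems(), c("arid", "semi_arid", "humid"))
  expect_setequal(scenario_ids(), c("BAU", "SDP", "V2030"))
  expect_length(feed_classes(), 4)
  expect_identical(land_class_of("pasture"), "grazing")
  expect_identical(land_class_of(c("planted_forage", "crop_residue",
                                   "concentrate")),
                   rep("cropland", 3))
  expect_error(land_class_of("silage"), "unknown feed class")
})

test_that("structural zeros are dairy shoats and camels in the humid system", {
  expect_true(is_structural_zero("shoats_dairy", "humid"))
  expect_true(is_structural_zero("camel_dairy", "humid"))
  expect_false(is_structural_zero("cattle_dairy", "humid"))
  expect_false(is_structural_zero("camel_dairy", "arid"))
  expect_equal(nrow(valid_cells()), 13)
})

test_that("a well-formed bundle validates", {
  b <- tiny_bundle()
  expect_s3_class(b, "parameter_bundle")
  # spec-shaped basket: fractions summing to one are accepted
  bk <- data.frame(category = "cattle_dairy", system = "humid",
                   feed_type = feed_classes(),
                   fraction = c(0.5, 0.3, 0.15, 0.05))
  expect_silent(allocate_feed(1, setNames(bk$fraction, bk$feed_type)))
})

test_that("bundle validation rejects each invariant violation", {
  b <- tiny_bundle()
  # basket not summing to 1, error names the offending cell
  bad <- b$basket
  bad$fraction[bad$category == "cattle_dairy" & bad$system == "humid" &
                 bad$feed_type == "pasture"] <- 0.65
  expect_error(parameter_bundle(b$fcr, bad, b$feed_params, b$animal_water,
                                b$system_shares),
               "cattle_dairy-humid")
  # basket fraction outside [0,1]
  bad <- b$basket
  bad$fraction[1] <- 1.2
  expect_error(parameter_bundle(b$fcr, bad, b$feed_params, b$animal_water,
                                b$system_shares),
               "\\[0, 1\\]")
  # negative FCR is a domain error
  bad <- b$fcr
  bad$fcr[1] <- -1
  expect_error(parameter_bundle(bad, b$basket, b$feed_params, b$animal_water,
                                b$system_shares),
               "domain error")
  # nonpositive feed yield
  bad <- b$feed_params
  bad$feed_yield[1] <- 0
  expect_error(parameter_bundle(b$fcr, b$basket, bad, b$animal_water,
                                b$system_shares),
               "feed_yield")
  # negative water footprint
  bad <- b$feed_params
  bad$wf_blue[1] <- -5
  expect_error(parameter_bundle(b$fcr, b$basket, bad, b$animal_water,
                                b$system_shares),
               ">= 0")
  # negative drinking water
  bad <- b$animal_water
  bad$drink_water[1] <- -1
  expect_error(parameter_bundle(b$fcr, b$basket, b$feed_params, bad,
                                b$system_shares),
               "animal_water")
  # shares not summing to 1
  bad <- b$system_shares
  bad$share[bad$category == "cattle_meat" & bad$scenario == "BAU" &
              bad$system == "arid"] <- 0.1
  expect_error(parameter_bundle(b$fcr, b$basket, b$feed_params,
                                b$animal_water, bad),
               "sum to 1")
  # positive share on a structural-zero cell
  bad <- b$system_shares
  bad$share[bad$category == "camel_dairy" & bad$system == "humid"] <- 0.1
  bad$share[bad$category == "camel_dairy" & bad$system == "arid"] <-
    bad$share[bad$category == "camel_dairy" & bad$system == "arid"] - 0.1
  expect_error(parameter_bundle(b$fcr, b$basket, b$feed_params,
                                b$animal_water, bad),
               "structural-zero")
  # feed type mapped to two classes
  bad <- b$feed_params
  bad$feed_class[bad$feed_type == "pasture" & bad$system == "arid"] <-
    "concentrate"
  expect_error(parameter_bundle(b$fcr, b$basket, bad, b$animal_water,
                                b$system_shares),
               "more than one feed class")
  # unknown enum level
  bad <- b$fcr
  bad$system[1] <- "alpine"
  expect_error(parameter_bundle(bad, b$basket, b$feed_params, b$animal_water,
                                b$system_shares),
               "invalid production system")
  # duplicated key
  bad <- rbind(b$fcr, b$fcr[1, ])
  expect_error(parameter_bundle(bad, b$basket, b$feed_params, b$animal_water,
                                b$system_shares),
               "duplicate")
})

test_that("missing required columns raise schema errors naming the column", {
  b <- tiny_bundle()
  expect_error(parameter_bundle(b$fcr[setdiff(names(b$fcr), "fcr")],
                                b$basket, b$feed_params),
               "missing column fcr")
  expect_error(parameter_bundle(b$fcr, b$basket,
                                b$feed_params[setdiff(names(b$feed_params),
                                                      "wf_green")]),
               "missing column wf_green")
})

test_that("parameter bundles round-trip through a CSV directory", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_parameter_bundle(b, dir)
  b2 <- read_parameter_bundle(dir)
  expect_equal(b2$fcr$fcr, b$fcr$fcr)
  expect_equal(b2$basket$fraction, b$basket$fraction)
  expect_equal(b2$feed_params, b$feed_params)
  expect_equal(b2$animal_water, b$animal_water)
  expect_equal(b2$system_shares$share, b$system_shares$share)
})

test_that("a missing animal_water table defaults to zero with a warning", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_parameter_bundle(b, dir)
  file.remove(file.path(dir, "animal_water.csv"))
  expect_warning(b2 <- read_parameter_bundle(dir), "animal_water")
  expect_true(all(b2$animal_water$drink_water == 0))
  expect_true(all(b2$animal_water$service_water == 0))
})

test_that("result tables round-trip losslessly and reject incomplete data", {
  set.seed(42)
  tab <- data.frame(category = "cattle_dairy", system = "arid",
                    scenario = "BAU", year = 2005:2014,
                    metric = "wf_total", value = exp(runif(10, -8, 8)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(tab, path)
  back <- read_results(path)
  expect_identical(back$value, tab$value)  # bitwise, not approximate
  # empty table: header-only CSV, no error
  write_results(tab[0, ], path)
  expect_equal(nrow(read_results(path)), 0)
  expect_equal(names(read_results(path)), names(tab))
  # NaN is rejected: results must be complete
  tab$value[3] <- NaN
  expect_error(write_results(tab, path), "complete")
})
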