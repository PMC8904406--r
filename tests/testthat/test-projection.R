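test_that("compound growth is evaluated in closed form", {
  years <- 2005:2040
  r <- 4^(1 / 35) - 1  # quadruples over the horizon
  traj <- project_trajectory(100, r, years)
  expect_lt(abs(traj[["2040"]] - 400) / 400, 1e-6)
  expect_equal(unname(project_trajectory(50, 0, years)), rep(50, 36))
  expect_equal(unname(project_trajectory(0, 0.05, years)), rep(0, 36))
  # one-year step is exactly base*(1+rate)
  expect_identical(unname(project_trajectory(123, 0.04, 2005:2006)[2]),
                   123 * 1.04)
  expect_error(project_trajectory(10, -1, years), "domain error")
  expect_error(project_trajectory(-5, 0.1, years), "domain error")
})

test_that("disaggregation preserves the national total", {
  out <- disaggregate_national(1000, c(arid = 0.3, semi_arid = 0.3,
                                       humid = 0.4))
  expect_equal(unname(out), c(300, 300, 400))
  expect_equal(unname(disaggregate_national(77, c(arid = 1))), 77)
  set.seed(19)
  for (i in 1:50) {
    w <- runif(3)
    shares <- setNames(w / sum(w), production_systems())
    national <- runif(1, 0, 1e7)
    out <- disaggregate_national(national, shares)
    expect_true(abs(sum(out) - national) <= 1e-9 * max(national, 1))
  }
  expect_error(disaggregate_national(100, c(arid = 0.5, humid = 0.4)),
               "sum to")
  # positive share on a structural-zero system
  expect_error(
    disaggregate_national(100, c(arid = 0.5, semi_arid = 0.3, humid = 0.2),
                          category = "camel_dairy"),
    "structural-zero")
  # zero share on the structural-zero system is fine and yields exactly 0
  out <- disaggregate_national(100, c(arid = 0.6, semi_arid = 0.4,
                                      humid = 0),
                               category = "shoats_dairy")
  expect_identical(unname(out[["humid"]]), 0)
})

test_that("projection bundles enforce grid and structural-zero invariants", {
  grid <- merge(merge(valid_cells(), data.frame(scenario = "BAU")),
                data.frame(year = 2005:2010))
  grid$herd <- 100
  grid$output <- 500
  expect_s3_class(projection_bundle(grid), "projection_bundle")
  # non-contiguous years
  bad <- grid[grid$year != 2007, ]
  expect_error(projection_bundle(bad), "contiguous")
  # structural-zero cell with animals
  bad <- rbind(grid, data.frame(category = "camel_dairy", system = "humid",
                                scenario = "BAU", year = 2005:2010,
                                herd = 5, output = 300))
  expect_error(projection_bundle(bad), "structural-zero")
  # negative herd
  bad <- grid
  bad$herd[1] <- -2
  expect_error(projection_bundle(bad), ">= 0")
  # herd lookup: absent structural-zero cells read as zero
  pb <- projection_bundle(grid)
  expect_identical(herd_count(pb, "camel_dairy", "humid", "BAU", 2005), 0)
  expect_equal(herd_count(pb, "cattle_dairy", "arid", "BAU", 2005), 100)
  expect_error(herd_count(pb, "cattle_dairy", "arid", "SDP", 2005),
               "coverage error")
})

test_that("projection building compounds growth and splits by shares", {
  shares <- data.frame(category = rep(c("cattle_dairy", "cattle_meat"),
                                      each = 3),
                       system = rep(production_systems(), 2),
                       share = c(0.2, 0.3, 0.5, 0.4, 0.4, 0.2))
  base_herd <- data.frame(category = c("cattle_dairy", "cattle_meat"),
                          herd = c(1000, 600))
  base_yield <- data.frame(category = rep(c("cattle_dairy", "cattle_meat"),
                                          each = 3),
                           system = rep(production_systems(), 2),
                           output = c(300, 500, 1500, 100, 120, 140))
  mk <- function(scn, gh, gy) {
    scenario_config(scn,
                    herd_growth = c(cattle_dairy = gh, cattle_meat = gh),
                    yield_growth = c(cattle_dairy = gy, cattle_meat = gy),
                    system_shares = shares)
  }
  # zero growth: 2040 equals 2005 everywhere
  cfgs <- lapply(scenario_ids(), mk, gh = 0, gy = 0)
  pb <- build_projection(cfgs, base_herd, base_yield)
  t05 <- pb$table[pb$table$year == 2005, ]
  t40 <- pb$table[pb$table$year == 2040, ]
  expect_equal(t40$herd, t05$herd)
  expect_equal(t40$output, t05$output)
  # disaggregation: systems sum back to the compounded national herd
  cfgs <- lapply(scenario_ids(), mk, gh = 0.02, gy = 0.01)
  pb <- build_projection(cfgs, base_herd, base_yield)
  tab <- pb$table[pb$table$scenario == "BAU" &
                    pb$table$category == "cattle_dairy", ]
  nat <- as.numeric(tapply(tab$herd, tab$year, sum))
  expect_equal(nat, unname(1000 * 1.02^(0:35)))
  # identical configs produce identical bundles
  pb2 <- build_projection(lapply(scenario_ids(), mk, gh = 0.02, gy = 0.01),
                          base_herd, base_yield)
  expect_identical(pb, pb2)
  # missing base cell is a coverage error
  expect_error(build_projection(cfgs, base_herd[1, , drop = FALSE],
                                base_yield),
               "coverage error")
  expect_error(build_projection(cfgs, base_herd, base_yield[-1, ]),
               "coverage error")
})

test_that("scenario configs validate rates and shares and round-trip JSON", {
  shares <- data.frame(category = "cattle_dairy",
                       system = production_systems(),
                       share = c(0.2, 0.3, 0.5))
  cfg <- scenario_config("V2030", c(cattle_dairy = 0.0404),
                         c(cattle_dairy = 0.012), shares)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_config(cfg, path)
  cfg2 <- read_scenario_config(path)
  expect_equal(cfg2$herd_growth, cfg$herd_growth)
  expect_equal(cfg2$yield_growth, cfg$yield_growth)
  expect_equal(cfg2$system_shares$share, cfg$system_shares$share)
  expect_identical(cfg2$base_year, 2005L)
  expect_error(scenario_config("V2030", c(cattle_dairy = 1.2),
                               c(cattle_dairy = 0), shares),
               "\\(-1, 1\\)")
  expect_error(scenario_config("V2030", c(cattle_dairy = 0.04),
                               c(cattle_dairy = 0), shares,
                               base_year = 2040, end_year = 2005),
               "precede")
  bad <- shares
  bad$share[1] <- 0.4
  expect_error(scenario_config("V2030", c(cattle_dairy = 0.04),
                               c(cattle_dairy = 0), bad),
               "sum to 1")
})
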