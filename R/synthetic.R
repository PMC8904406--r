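#' Synthetic input generator
#'
#' The accounting consumes two kinds of inputs that are not shipped with the
#' package: parameter tables (feed conversion ratios, diet baskets, feed water
#' footprints and yields, drinking/service water, system shares) sourced in
#' the original study from external publications and field surveys, and
#' herd/yield trajectories produced by a global economic model. The generator
#' emulates both so that the whole pipeline runs and is testable end to end.
#'
#' Two calibrations are provided. `"paperlike"` is a fixed, deterministic
#' calibration whose qualitative structure matches the study system: pasture
#' dominates arid and semi-arid diets, concentrate shares peak in humid dairy
#' diets, pasture consumes only green water, shoat-meat feed conversion is
#' set to 1/3.5 of cattle-meat feed conversion so shoat meat is 3-4 times as
#' water-productive as beef, camel dairy herds quadruple 2005-2040 under
#' V2030, and total milk production quadruples under V2030 while doubling
#' under BAU and SDP. `"random"` jitters every positive parameter around the
#' paperlike values with a lognormal factor (coefficient of variation
#' `noise_cv`) and renormalizes baskets and shares; it is meant for
#' property-based stress tests, not for resembling the study.
#'
#' @param seed integer seed; the single source of randomness. Table-specific
#'   streams are derived from it by fixed offsets.
#' @param calibration `"paperlike"` or `"random"`.
#' @param noise_cv coefficient of variation of the lognormal parameter jitter
#'   used by the random calibration (default 0.1).
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, calibration = c("paperlike", "random"),
                           noise_cv = 0.1) {
  calibration <- match.arg(calibration)
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("domain error: noise_cv must be >= 0", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), calibration = calibration,
                 noise_cv = noise_cv),
            class = "synthetic_spec")
}

# run code under a seeded RNG without disturbing the caller's RNG state
.with_seed <- function(seed, fn) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed %% .Machine$integer.max, kind = "Mersenne-Twister")
  fn()
}

# lognormal jitter with unit mean; returns x unchanged (but consumes no
# draws) when the spec is paperlike
.jitter <- function(spec, offset, x) {
  if (spec$calibration != "random" || spec$noise_cv == 0) return(x)
  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  .with_seed(spec$seed + offset, function() {
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  })
}

# fixed paperlike calibration constants ----------------------------------

.syn_feed_params <- function() {
  sys <- production_systems()
  data.frame(
    feed_type = rep(feed_classes(), each = 3),
    feed_class = rep(feed_classes(), each = 3),
    system = rep(sys, times = 4),
    wf_green = c(1200, 900, 700,    # pasture: rain-fed only
                 400, 350, 300,     # planted forage
                 300, 260, 220,     # crop residue (allocated share)
                 1000, 1000, 1000), # concentrate
    wf_blue = c(0, 0, 0,
                60, 50, 40,
                0, 0, 0,
                200, 200, 200),
    feed_yield = c(0.8, 1.5, 3.0,
                   4, 7, 12,
                   1.5, 2.5, 4,
                   2, 3, 4),
    stringsAsFactors = FALSE
  )
}

.syn_baskets <- function() {
  row <- function(cat, sys, fr) {
    data.frame(category = cat, system = sys, feed_type = feed_classes(),
               fraction = fr, stringsAsFactors = FALSE)
  }
  rbind(
    row("cattle_dairy", "arid", c(0.80, 0.02, 0.13, 0.05)),
    row("cattle_dairy", "semi_arid", c(0.60, 0.10, 0.20, 0.10)),
    row("cattle_dairy", "humid", c(0.35, 0.30, 0.20, 0.15)),
    row("shoats_dairy", "arid", c(0.80, 0.02, 0.13, 0.05)),
    row("shoats_dairy", "semi_arid", c(0.60, 0.10, 0.20, 0.10)),
    row("camel_dairy", "arid", c(0.85, 0.00, 0.10, 0.05)),
    row("camel_dairy", "semi_arid", c(0.85, 0.00, 0.10, 0.05)),
    row("cattle_meat", "arid", c(0.85, 0.00, 0.12, 0.03)),
    row("cattle_meat", "semi_arid", c(0.70, 0.05, 0.20, 0.05)),
    row("cattle_meat", "humid", c(0.50, 0.15, 0.25, 0.10)),
    row("shoats_meat", "arid", c(0.85, 0.00, 0.12, 0.03)),
    row("shoats_meat", "semi_arid", c(0.70, 0.05, 0.20, 0.05)),
    row("shoats_meat", "humid", c(0.50, 0.15, 0.25, 0.10))
  )
}

# shoat-meat FCR is cattle-meat FCR / 3.5 with identical baskets, which
# pins the shoat/cattle meat water-productivity ratio near 3.5 in every
# system (drinking/service water moves it only slightly).
.syn_fcr_base <- function() {
  rbind(
    data.frame(category = "cattle_dairy", system = production_systems(),
               fcr = c(3.0, 2.4, 1.8), stringsAsFactors = FALSE),
    data.frame(category = "shoats_dairy", system = c("arid", "semi_arid"),
               fcr = c(3.6, 3.2), stringsAsFactors = FALSE),
    data.frame(category = "camel_dairy", system = c("arid", "semi_arid"),
               fcr = c(1.8, 1.6), stringsAsFactors = FALSE),
    data.frame(category = "cattle_meat", system = production_systems(),
               fcr = c(70, 60, 45), stringsAsFactors = FALSE),
    data.frame(category = "shoats_meat", system = production_systems(),
               fcr = c(70, 60, 45) / 3.5, stringsAsFactors = FALSE)
  )
}

# scenario FCR multipliers: SDP improves feeding efficiency only marginally
# over BAU; V2030 assumes markedly better breeds, feeding and range
# management.
.syn_fcr_scenario_mult <- c(BAU = 1.00, SDP = 0.97, V2030 = 0.85)

# drinking and service water, m3 per animal per accounting period.
# Order-of-magnitude placeholders (synthetic): the study does not publish
# these values.
.syn_animal_water <- function() {
  aw <- data.frame(
    category = c("cattle_dairy", "shoats_dairy", "camel_dairy",
                 "cattle_meat", "shoats_meat"),
    drink_water = c(9, 1.5, 5.5, 12, 1.5),
    service_water = c(2.5, 0.4, 0.5, 3, 0.4),
    stringsAsFactors = FALSE
  )
  cells <- valid_cells()
  idx <- match(cells$category, aw$category)
  data.frame(cells, drink_water = aw$drink_water[idx],
             service_water = aw$service_water[idx], stringsAsFactors = FALSE)
}

# national herd shares by production system (per category); shared across
# scenarios in the paperlike calibration
.syn_system_shares_base <- function() {
  rbind(
    data.frame(category = "cattle_dairy", system = production_systems(),
               share = c(0.10, 0.30, 0.60), stringsAsFactors = FALSE),
    data.frame(category = "shoats_dairy", system = production_systems(),
               share = c(0.45, 0.55, 0.00), stringsAsFactors = FALSE),
    data.frame(category = "camel_dairy", system = production_systems(),
               share = c(0.70, 0.30, 0.00), stringsAsFactors = FALSE),
    data.frame(category = "cattle_meat", system = production_systems(),
               share = c(0.35, 0.40, 0.25), stringsAsFactors = FALSE),
    data.frame(category = "shoats_meat", system = production_systems(),
               share = c(0.45, 0.40, 0.15), stringsAsFactors = FALSE)
  )
}

# (category, scenario, system) shares as actually used for a spec; jittered
# and renormalized under the random calibration, with structural zeros kept
.syn_shares_used <- function(spec) {
  shares <- do.call(rbind, lapply(scenario_ids(), function(scn) {
    s <- .syn_system_shares_base()
    data.frame(category = s$category, scenario = scn, system = s$system,
               share = s$share, stringsAsFactors = FALSE)
  }))
  shares$share <- .jitter(spec, 15L, shares$share)
  key <- paste(shares$category, shares$scenario)
  shares$share <- shares$share / stats::ave(shares$share, key, FUN = sum)
  shares
}

# base-year (2005) national herds and per-animal outputs
.syn_base_herd <- function(spec) {
  bh <- data.frame(
    category = c("cattle_dairy", "shoats_dairy", "camel_dairy",
                 "cattle_meat", "shoats_meat"),
    herd = c(3.5e6, 1.2e6, 0.4e6, 1.0e6, 3.0e6),
    stringsAsFactors = FALSE
  )
  bh$herd <- .jitter(spec, 21L, bh$herd)
  bh
}

.syn_base_yield <- function(spec) {
  by <- rbind(
    data.frame(category = "cattle_dairy", system = production_systems(),
               output = c(250, 450, 1800), stringsAsFactors = FALSE),
    data.frame(category = "shoats_dairy", system = c("arid", "semi_arid"),
               output = c(40, 60), stringsAsFactors = FALSE),
    data.frame(category = "camel_dairy", system = c("arid", "semi_arid"),
               output = c(350, 450), stringsAsFactors = FALSE),
    data.frame(category = "cattle_meat", system = production_systems(),
               output = c(110, 130, 150), stringsAsFactors = FALSE),
    data.frame(category = "shoats_meat", system = production_systems(),
               output = c(11, 12, 13), stringsAsFactors = FALSE)
  )
  by$output <- .jitter(spec, 22L, by$output)
  by
}

# 2005->2040 multipliers defining the paperlike scenarios. Total-production
# multiples (milk x4 under V2030, x2 under BAU/SDP; meat more than doubling
# under BAU/SDP and quadrupling under V2030) are hit exactly by solving the
# cattle production multiple in closed form given the other categories'
# fixed multiples. Camel yields never improve (no interventions for camel
# milk in any scenario); the V2030 camel herd quadruples exactly. Fast-
# growing categories are the feed-efficient ones, so production-weighted
# per-tonne footprints fall over time in every scenario.
.syn_targets <- function() {
  list(
    milk_total = c(BAU = 2.00, SDP = 2.04, V2030 = 4.00),
    meat_total = c(BAU = 2.30, SDP = 2.37, V2030 = 4.00),
    camel_prod = c(BAU = 1.90, SDP = 1.95, V2030 = 4.00),
    camel_herd = c(BAU = 1.90, SDP = 1.95, V2030 = 4.00),
    shoats_dairy_prod = c(BAU = 1.30, SDP = 1.32, V2030 = 1.40),
    shoats_dairy_herd = c(BAU = 0.95, SDP = 0.94, V2030 = 0.93),
    cattle_dairy_herd = c(BAU = 1.12, SDP = 1.15, V2030 = 1.19),
    shoats_meat_prod = c(BAU = 2.60, SDP = 2.70, V2030 = 4.30),
    shoats_meat_herd = c(BAU = 1.45, SDP = 1.50, V2030 = 1.45),
    cattle_meat_herd = c(BAU = 1.35, SDP = 1.40, V2030 = 1.35)
  )
}

#' Generate a synthetic parameter bundle
#'
#' @param spec a [synthetic_spec()].
#' @return a validated [parameter_bundle()]. The paperlike calibration is
#'   deterministic; the random calibration jitters every positive parameter
#'   by a lognormal factor seeded by `spec$seed` and renormalizes baskets
#'   and shares.
#' @export
generate_parameters <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fcr_base <- .syn_fcr_base()
  mult <- .syn_fcr_scenario_mult
  fcr <- do.call(rbind, lapply(scenario_ids(), function(scn) {
    data.frame(category = fcr_base$category, system = fcr_base$system,
               scenario = scn, fcr = fcr_base$fcr * mult[[scn]],
               stringsAsFactors = FALSE)
  }))
  fcr$fcr <- .jitter(spec, 11L, fcr$fcr)

  feed_params <- .syn_feed_params()
  feed_params$wf_green <- .jitter(spec, 12L, feed_params$wf_green)
  feed_params$wf_blue <- .jitter(spec, 13L, feed_params$wf_blue)
  feed_params$feed_yield <- .jitter(spec, 14L, feed_params$feed_yield)

  animal_water <- .syn_animal_water()
  animal_water$drink_water <- .jitter(spec, 16L, animal_water$drink_water)
  animal_water$service_water <- .jitter(spec, 17L, animal_water$service_water)

  basket <- .syn_baskets()
  basket$fraction <- .jitter(spec, 18L, basket$fraction)
  bkey <- paste(basket$category, basket$system)
  basket$fraction <- basket$fraction /
    stats::ave(basket$fraction, bkey, FUN = sum)

  parameter_bundle(fcr = fcr, basket = basket, feed_params = feed_params,
                   animal_water = animal_water,
                   system_shares = .syn_shares_used(spec))
}

# closed-form growth multiples per category for one scenario, given that
# scenario's base production by category
.syn_growth_multiples <- function(prod0, scn) {
  tg <- .syn_targets()
  milk_tot0 <- prod0[["cattle_dairy"]] + prod0[["camel_dairy"]] +
    prod0[["shoats_dairy"]]
  cattle_dairy_prod <- (tg$milk_total[[scn]] * milk_tot0 -
                          prod0[["camel_dairy"]] * tg$camel_prod[[scn]] -
                          prod0[["shoats_dairy"]] *
                          tg$shoats_dairy_prod[[scn]]) /
    prod0[["cattle_dairy"]]
  meat_tot0 <- prod0[["cattle_meat"]] + prod0[["shoats_meat"]]
  cattle_meat_prod <- (tg$meat_total[[scn]] * meat_tot0 -
                         prod0[["shoats_meat"]] *
                         tg$shoats_meat_prod[[scn]]) /
    prod0[["cattle_meat"]]
  herd <- c(cattle_dairy = tg$cattle_dairy_herd[[scn]],
            shoats_dairy = tg$shoats_dairy_herd[[scn]],
            camel_dairy = tg$camel_herd[[scn]],
            cattle_meat = tg$cattle_meat_herd[[scn]],
            shoats_meat = tg$shoats_meat_herd[[scn]])
  prod <- c(cattle_dairy = cattle_dairy_prod,
            shoats_dairy = tg$shoats_dairy_prod[[scn]],
            camel_dairy = tg$camel_prod[[scn]],
            cattle_meat = cattle_meat_prod,
            shoats_meat = tg$shoats_meat_prod[[scn]])
  list(herd = herd, yield = prod / herd)
}

#' Generate synthetic herd and yield trajectories
#'
#' Builds one [scenario_config()] per scenario from the calibration's
#' 2005-2040 growth multiples (converted to compound annual rates) and
#' compounds them into a [projection_bundle()] via [build_projection()].
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `projection` (a `projection_bundle`) and
#'   `configs` (named list of `scenario_config`).
#' @export
generate_projection <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  base_herd <- .syn_base_herd(spec)
  base_yield <- .syn_base_yield(spec)
  shares <- .syn_shares_used(spec)

  horizon <- 2040 - 2005
  configs <- lapply(scenario_ids(), function(scn) {
    sh <- shares[shares$scenario == scn,
                 c("category", "system", "share"), drop = FALSE]
    idx <- match(paste(base_yield$category, base_yield$system),
                 paste(sh$category, sh$system))
    prod0_cell <- base_herd$herd[match(base_yield$category,
                                       base_herd$category)] *
      sh$share[idx] * base_yield$output
    prod0 <- tapply(prod0_cell, base_yield$category, sum)
    m <- .syn_growth_multiples(prod0, scn)
    m$herd <- .jitter(spec, 23L + match(scn, scenario_ids()), m$herd)
    m$yield <- .jitter(spec, 26L + match(scn, scenario_ids()), m$yield)
    scenario_config(
      scenario = scn,
      herd_growth = m$herd^(1 / horizon) - 1,
      yield_growth = m$yield^(1 / horizon) - 1,
      system_shares = sh,
      base_year = 2005L, end_year = 2040L
    )
  })
  names(configs) <- scenario_ids()
  projection <- build_projection(configs, base_herd, base_yield)
  list(projection = projection, configs = configs)
}

#' Write a complete synthetic input directory
#'
#' Writes the parameter CSV tables, base-year herd and yield tables and one
#' scenario-configuration JSON per scenario into `out`, so that the directory
#' alone suffices to rerun the pipeline
#' (`read_parameter_bundle()` + `read_scenario_config()` +
#' [build_projection()]).
#'
#' @param seed integer seed.
#' @param calibration `"paperlike"` or `"random"`.
#' @param out output directory (created if absent).
#' @param noise_cv jitter coefficient of variation for the random
#'   calibration.
#' @return `out`, invisibly.
#' @export
generate_inputs <- function(seed = 1L, calibration = "paperlike", out,
                            noise_cv = 0.1) {
  spec <- synthetic_spec(seed = seed, calibration = calibration,
                         noise_cv = noise_cv)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  params <- generate_parameters(spec)
  write_parameter_bundle(params, out)
  proj <- generate_projection(spec)
  for (scn in names(proj$configs)) {
    write_scenario_config(proj$configs[[scn]],
                          file.path(out, paste0("scenario_",
                                                tolower(scn), ".json")))
  }
  .write_csv(.syn_base_herd(spec), file.path(out, "base_herd.csv"))
  .write_csv(.syn_base_yield(spec), file.path(out, "base_yield.csv"))
  invisible(out)
}
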