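#' Scenario configuration
#'
#' A scenario is parameterized by compound annual growth rates for national
#' herd sizes and per-animal product yields, one rate per animal category,
#' over a fixed 2005-2040 horizon, together with the shares that split the
#' national herd across the three production systems. The BAU, SDP and V2030
#' scenarios differ only through these numbers.
#'
#' @param scenario one of `"BAU"`, `"SDP"`, `"V2030"`.
#' @param herd_growth named numeric, annual herd growth rate (fraction/yr) by
#'   animal category; each in (-1, 1).
#' @param yield_growth named numeric, annual per-animal yield growth rate by
#'   category; each in (-1, 1).
#' @param system_shares data.frame(category, system, share); shares sum to 1
#'   per category, structural-zero cells have zero share.
#' @param base_year,end_year horizon (defaults 2005 and 2040).
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario, herd_growth, yield_growth,
                            system_shares, base_year = 2005L,
                            end_year = 2040L) {
  .check_levels(scenario, scenario_ids(), "scenario")
  if (base_year >= end_year) {
    stop("base_year must precede end_year", call. = FALSE)
  }
  cats <- animal_categories()$category
  .check_levels(names(herd_growth), cats, "animal category")
  .check_levels(names(yield_growth), cats, "animal category")
  rates <- c(herd_growth, yield_growth)
  if (any(!is.finite(rates)) || any(rates <= -1) || any(rates >= 1)) {
    stop("domain error: growth rates must lie in (-1, 1)", call. = FALSE)
  }
  .require_columns(system_shares, c("category", "system", "share"),
                   "system_shares")
  .check_levels(system_shares$category, cats, "animal category")
  .check_levels(system_shares$system, production_systems(),
                "production system")
  sums <- tapply(system_shares$share, system_shares$category, sum)
  off <- names(sums)[!.rel_close(as.numeric(sums), 1)]
  if (length(off) > 0) {
    stop("validation error: system shares do not sum to 1 for ", off[1],
         call. = FALSE)
  }
  zero <- is_structural_zero(system_shares$category, system_shares$system)
  if (any(zero & system_shares$share > 0)) {
    stop("validation error: structural-zero cell has positive share",
         call. = FALSE)
  }
  structure(list(scenario = scenario, herd_growth = herd_growth,
                 yield_growth = yield_growth, system_shares = system_shares,
                 base_year = as.integer(base_year),
                 end_year = as.integer(end_year)),
            class = "scenario_config")
}

#' Compound-growth trajectory
#'
#' Evaluates \eqn{x_t = x_0 (1+r)^{t-t_0}} on a year grid in closed form
#' (no iterative accumulation, hence no drift).
#'
#' @param base value at the first year of `years`; >= 0.
#' @param rate annual growth rate (fraction/yr); > -1.
#' @param years integer vector of years; the first element is the base year.
#' @return named numeric series over `years`.
#' @export
project_trajectory <- function(base, rate, years) {
  if (!is.finite(base) || base < 0) {
    stop("domain error: base must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(rate) || rate <= -1) {
    stop("domain error: rate must be > -1", call. = FALSE)
  }
  stats::setNames(base * (1 + rate)^(years - years[1]), years)
}

#' Disaggregate a national total into production systems
#'
#' Splits a national quantity across the arid, semi-arid and humid systems by
#' fixed shares. The per-system values sum back to the national total;
#' structural-zero systems receive exactly 0 (and must carry zero share).
#'
#' @param national national quantity; >= 0.
#' @param shares named numeric by production system, summing to 1.
#' @param category optional animal-category id; when given, a positive share
#'   on a structural-zero system for that category is a validation error.
#' @return named numeric by production system.
#' @export
disaggregate_national <- function(national, shares, category = NULL) {
  .check_levels(names(shares), production_systems(), "production system")
  if (any(shares < 0 | shares > 1)) {
    stop("domain error: shares must lie in [0, 1]", call. = FALSE)
  }
  if (!.rel_close(sum(shares), 1)) {
    stop("validation error: shares sum to ",
         format(sum(shares), digits = 12), ", not 1", call. = FALSE)
  }
  if (!is.null(category)) {
    zero <- is_structural_zero(rep(category, length(shares)), names(shares))
    if (any(zero & shares > 0)) {
      stop("validation error: positive share on structural-zero system (",
           category, ", ", names(shares)[zero & shares > 0][1], ")",
           call. = FALSE)
    }
    shares[zero] <- 0
  }
  national * shares
}

#' Projection bundle: herd and yield trajectories
#'
#' Holds head counts and per-animal product output for every (category,
#' system, scenario, year) cell on a contiguous annual grid. Structural-zero
#' cells (dairy shoats/camels in the humid system) carry zero herd.
#'
#' @param table data.frame with columns `category`, `system`, `scenario`,
#'   `year`, `herd` (head, >= 0) and `output` (kg product per animal per
#'   accounting period, > 0).
#' @return object of class `projection_bundle`.
#' @export
projection_bundle <- function(table) {
  .require_columns(table, c("category", "system", "scenario", "year", "herd",
                            "output"), "projection")
  .check_levels(table$category, animal_categories()$category,
                "animal category")
  .check_levels(table$system, production_systems(), "production system")
  .check_levels(table$scenario, scenario_ids(), "scenario")
  .check_no_duplicates(table, c("category", "system", "scenario", "year"),
                       "projection")
  if (any(!is.finite(table$herd)) || any(table$herd < 0)) {
    stop("domain error: herd counts must be >= 0", call. = FALSE)
  }
  if (any(!is.finite(table$output)) || any(table$output <= 0)) {
    stop("domain error: per-animal output must be > 0", call. = FALSE)
  }
  yrs <- sort(unique(table$year))
  if (!identical(as.integer(yrs), as.integer(seq(min(yrs), max(yrs))))) {
    stop("validation error: years must form a contiguous annual grid",
         call. = FALSE)
  }
  zero <- is_structural_zero(table$category, table$system)
  if (any(table$herd[zero] > 0)) {
    i <- which(zero & table$herd > 0)[1]
    stop("validation error: structural-zero cell (", table$category[i], ", ",
         table$system[i], ") has nonzero herd", call. = FALSE)
  }
  table <- table[order(table$scenario, table$category, table$system,
                       table$year), , drop = FALSE]
  rownames(table) <- NULL
  structure(list(table = table, years = as.integer(yrs)),
            class = "projection_bundle")
}

#' Look up a herd count in a projection bundle
#'
#' Structural-zero cells absent from the table read as 0.
#'
#' @param bundle a `projection_bundle`.
#' @param category,system,scenario,year cell coordinates.
#' @return head count.
#' @export
herd_count <- function(bundle, category, system, scenario, year) {
  stopifnot(inherits(bundle, "projection_bundle"))
  tab <- bundle$table
  idx <- match(.param_key(category, system, scenario, year),
               .param_key(tab$category, tab$system, tab$scenario, tab$year))
  out <- tab$herd[idx]
  zero <- is_structural_zero(category, system)
  out[is.na(out) & zero] <- 0
  if (anyNA(out)) {
    stop("coverage error: no herd entry for (", category, ", ", system, ", ",
         scenario, ", ", year, ")", call. = FALSE)
  }
  out
}

#' Build a projection bundle from scenario configurations
#'
#' Compounds national herd and per-animal yield growth from base-year values
#' and disaggregates the national herd into production systems by the
#' scenario's shares. The stand-in for the economic-model layer whose
#' outputs the footprint accounting consumes.
#'
#' @param configs list of [scenario_config()] objects, one per scenario.
#' @param base_herd data.frame(category, herd): national head counts in the
#'   base year.
#' @param base_yield data.frame(category, system, output): per-animal output
#'   (kg/period) in the base year, for every non-structural-zero cell.
#' @return a `projection_bundle` on the annual grid base_year..end_year.
#' @export
build_projection <- function(configs, base_herd, base_yield) {
  stopifnot(length(configs) > 0,
            all(vapply(configs, inherits, logical(1), "scenario_config")))
  .require_columns(base_herd, c("category", "herd"), "base_herd")
  .require_columns(base_yield, c("category", "system", "output"), "base_yield")
  rows <- list()
  for (cfg in configs) {
    years <- seq(cfg$base_year, cfg$end_year)
    for (cat in sort(unique(cfg$system_shares$category))) {
      hb <- base_herd$herd[base_herd$category == cat]
      if (length(hb) != 1) {
        stop("coverage error: no base herd for category ", cat, call. = FALSE)
      }
      if (is.null(cfg$herd_growth[[cat]]) || is.null(cfg$yield_growth[[cat]])) {
        stop("coverage error: no growth rates for category ", cat,
             call. = FALSE)
      }
      national <- project_trajectory(hb, cfg$herd_growth[[cat]], years)
      sh <- cfg$system_shares[cfg$system_shares$category == cat, ]
      shares <- stats::setNames(sh$share, sh$system)
      for (sys in names(shares)) {
        if (is_structural_zero(cat, sys)) next
        yb <- base_yield$output[base_yield$category == cat &
                                  base_yield$system == sys]
        if (length(yb) != 1) {
          stop("coverage error: no base yield for (", cat, ", ", sys, ")",
               call. = FALSE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          category = cat, system = sys, scenario = cfg$scenario,
          year = years,
          herd = as.numeric(national * shares[[sys]]),
          output = as.numeric(project_trajectory(yb, cfg$yield_growth[[cat]],
                                                 years)),
          stringsAsFactors = FALSE)
      }
    }
  }
  projection_bundle(do.call(rbind, rows))
}

#' Read/write scenario configurations as JSON
#'
#' @param config a `scenario_config`.
#' @param path JSON file path.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  obj <- list(scenario = config$scenario,
              base_year = config$base_year, end_year = config$end_year,
              herd_growth = as.list(config$herd_growth),
              yield_growth = as.list(config$yield_growth),
              system_shares = config$system_shares)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_config(scenario = obj$scenario,
                  herd_growth = unlist(obj$herd_growth),
                  yield_growth = unlist(obj$yield_growth),
                  system_shares = as.data.frame(obj$system_shares),
                  base_year = obj$base_year, end_year = obj$end_year)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario", x$scenario, "(", x$base_year, "-", x$end_year, ")\n")
  cat("  herd growth (%/yr): ",
      paste(sprintf("%s %.2f", names(x$herd_growth), 100 * x$herd_growth),
            collapse = ", "), "\n")
  cat("  yield growth (%/yr):",
      paste(sprintf("%s %.2f", names(x$yield_growth), 100 * x$yield_growth),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.projection_bundle <- function(x, ...) {
  cat("Projection bundle:", nrow(x$table), "cells,",
      length(x$years), "years (", min(x$years), "-", max(x$years), "),",
      length(unique(x$table$scenario)), "scenarios\n")
  invisible(x)
}
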