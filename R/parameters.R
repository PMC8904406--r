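#' Parameter bundle: all exogenous tables of the accounting
#'
#' A `parameter_bundle` collects every exogenous parameter table the footprint
#' accounting needs:
#'
#' * `fcr` — feed conversion ratio, kg feed dry matter per kg product, by
#'   (category, system, scenario). Scenario-specific values encode the
#'   management improvements assumed by the development scenarios.
#' * `basket` — diet composition: the fraction of each feed type in the diet,
#'   by (category, system). Fractions sum to 1 per cell.
#' * `feed_params` — per feed type and system: green and blue water footprint
#'   of producing the feed (m3 per tonne dry matter) and the feed yield
#'   (tonne dry matter per ha). The feed class determines whether the feed
#'   occupies grazing land (pasture) or cropland (all other classes).
#' * `animal_water` — drinking and service water, m3 per animal per
#'   accounting period, by (category, system).
#' * `system_shares` — fraction of the national herd of each category kept in
#'   each production system, by (category, scenario). Shares sum to 1;
#'   structural-zero cells (dairy shoats/camels in the humid system) must have
#'   zero share.
#'
#' Units are fixed globally: mass in kg (1 tonne = 1000 kg), water in m3,
#' land in ha, feed as dry-matter tonnes. The accounting period is one
#' calendar year for dairy animals and lifetime-to-slaughter for meat
#' animals, counted in the slaughter year.
#'
#' @param fcr data.frame(category, system, scenario, fcr).
#' @param basket data.frame(category, system, feed_type, fraction).
#' @param feed_params data.frame(feed_type, feed_class, system, wf_green,
#'   wf_blue, feed_yield).
#' @param animal_water data.frame(category, system, drink_water,
#'   service_water), or `NULL` for all-zero allowances.
#' @param system_shares data.frame(category, scenario, system, share).
#' @return a validated object of class `parameter_bundle`.
#' @export
parameter_bundle <- function(fcr, basket, feed_params, animal_water = NULL,
                             system_shares = NULL) {
  .require_columns(fcr, c("category", "system", "scenario", "fcr"), "fcr")
  .require_columns(basket, c("category", "system", "feed_type", "fraction"),
                   "basket")
  .require_columns(feed_params,
                   c("feed_type", "feed_class", "system", "wf_green",
                     "wf_blue", "feed_yield"), "feed_params")
  if (is.null(animal_water)) {
    cells <- valid_cells()
    animal_water <- data.frame(cells, drink_water = 0, service_water = 0,
                               stringsAsFactors = FALSE)
  }
  .require_columns(animal_water,
                   c("category", "system", "drink_water", "service_water"),
                   "animal_water")
  if (!is.null(system_shares)) {
    .require_columns(system_shares,
                     c("category", "scenario", "system", "share"),
                     "system_shares")
  }
  x <- structure(list(fcr = fcr, basket = basket, feed_params = feed_params,
                      animal_water = animal_water,
                      system_shares = system_shares),
                 class = "parameter_bundle")
  validate_parameter_bundle(x)
}

.check_no_duplicates <- function(df, keys, table) {
  key <- do.call(paste, c(df[keys], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate keys in ", table, ": ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a parameter bundle
#'
#' Enforces every invariant of the bundle: positive FCRs and feed yields,
#' nonnegative water parameters, basket fractions in \[0, 1\] summing to 1 per
#' (category, system) within relative tolerance 1e-9, system shares summing to
#' 1 per (category, scenario), zero shares for structural-zero cells, and a
#' consistent feed-type registry (each feed type has exactly one feed class;
#' pasture maps to grazing land, everything else to cropland).
#'
#' @param x a `parameter_bundle`.
#' @return `x`, invisibly classed, if valid; otherwise an error naming the
#'   offending table and key.
#' @export
validate_parameter_bundle <- function(x) {
  stopifnot(inherits(x, "parameter_bundle"))
  fcr <- x$fcr; basket <- x$basket; fp <- x$feed_params; aw <- x$animal_water
  cats <- animal_categories()$category

  .check_levels(fcr$category, cats, "animal category")
  .check_levels(fcr$system, production_systems(), "production system")
  .check_levels(fcr$scenario, scenario_ids(), "scenario")
  .check_no_duplicates(fcr, c("category", "system", "scenario"), "fcr")
  if (any(!is.finite(fcr$fcr)) || any(fcr$fcr <= 0)) {
    bad <- fcr[!is.finite(fcr$fcr) | fcr$fcr <= 0, ]
    stop("domain error in fcr: feed conversion ratio must be > 0 for (",
         paste(bad$category[1], bad$system[1], bad$scenario[1], sep = ", "),
         ")", call. = FALSE)
  }

  .check_levels(basket$category, cats, "animal category")
  .check_levels(basket$system, production_systems(), "production system")
  .check_no_duplicates(basket, c("category", "system", "feed_type"), "basket")
  if (any(basket$fraction < 0 | basket$fraction > 1)) {
    stop("domain error in basket: fractions must lie in [0, 1]", call. = FALSE)
  }
  key <- paste(basket$category, basket$system, sep = "-")
  sums <- tapply(basket$fraction, key, sum)
  off <- names(sums)[!.rel_close(as.numeric(sums), 1)]
  if (length(off) > 0) {
    stop("validation error in basket: fractions do not sum to 1 for (",
         off[1], "), sum = ", format(sums[[off[1]]], digits = 12),
         call. = FALSE)
  }

  .check_levels(fp$system, production_systems(), "production system")
  .check_levels(fp$feed_class, feed_classes(), "feed class")
  .check_no_duplicates(fp, c("feed_type", "system"), "feed_params")
  cls <- tapply(fp$feed_class, fp$feed_type, function(v) length(unique(v)))
  if (any(cls > 1)) {
    stop("validation error in feed_params: feed type ",
         names(cls)[cls > 1][1], " mapped to more than one feed class",
         call. = FALSE)
  }
  if (any(!is.finite(fp$feed_yield)) || any(fp$feed_yield <= 0)) {
    stop("domain error in feed_params: feed_yield must be > 0", call. = FALSE)
  }
  if (any(fp$wf_green < 0) || any(fp$wf_blue < 0)) {
    stop("domain error in feed_params: water footprints must be >= 0",
         call. = FALSE)
  }

  .check_levels(aw$category, cats, "animal category")
  .check_levels(aw$system, production_systems(), "production system")
  .check_no_duplicates(aw, c("category", "system"), "animal_water")
  if (any(aw$drink_water < 0) || any(aw$service_water < 0)) {
    stop("domain error in animal_water: allowances must be >= 0",
         call. = FALSE)
  }

  ss <- x$system_shares
  if (!is.null(ss)) {
    .check_levels(ss$category, cats, "animal category")
    .check_levels(ss$scenario, scenario_ids(), "scenario")
    .check_levels(ss$system, production_systems(), "production system")
    .check_no_duplicates(ss, c("category", "scenario", "system"),
                         "system_shares")
    if (any(ss$share < 0 | ss$share > 1)) {
      stop("domain error in system_shares: shares must lie in [0, 1]",
           call. = FALSE)
    }
    key <- paste(ss$category, ss$scenario, sep = "-")
    sums <- tapply(ss$share, key, sum)
    off <- names(sums)[!.rel_close(as.numeric(sums), 1)]
    if (length(off) > 0) {
      stop("validation error in system_shares: shares do not sum to 1 for (",
           off[1], ")", call. = FALSE)
    }
    zero <- is_structural_zero(ss$category, ss$system)
    if (any(zero & ss$share > 0)) {
      bad <- ss[zero & ss$share > 0, ][1, ]
      stop("validation error in system_shares: structural-zero cell (",
           bad$category, ", ", bad$system,
           ") must have zero share", call. = FALSE)
    }
  }
  invisible(x)
}

# scalar lookup helpers -------------------------------------------------

.param_key <- function(...) do.call(paste, c(list(...), sep = "\r"))

.lookup <- function(df, keycols, valcol, keys, what) {
  tab_key <- do.call(.param_key, df[keycols])
  idx <- match(keys, tab_key)
  if (anyNA(idx)) {
    miss <- keys[is.na(idx)][1]
    stop("lookup error: no ", what, " entry for (",
         gsub("\r", ", ", miss), ")", call. = FALSE)
  }
  df[[valcol]][idx]
}

#' Read a parameter bundle from a directory of CSV tables
#'
#' Expects `fcr.csv`, `basket.csv`, `feed_params.csv`, `system_shares.csv`
#' and optionally `animal_water.csv` in `path`, with the column schemas
#' documented in [parameter_bundle()]. A missing `animal_water.csv` defaults
#' drinking and service water to zero with a warning. All bundle invariants
#' are enforced on read.
#'
#' @param path directory containing the CSV tables.
#' @return a validated `parameter_bundle`.
#' @export
read_parameter_bundle <- function(path) {
  if (!dir.exists(path)) stop("parameter directory not found: ", path,
                              call. = FALSE)
  fcr <- .read_csv(file.path(path, "fcr.csv"))
  basket <- .read_csv(file.path(path, "basket.csv"))
  feed_params <- .read_csv(file.path(path, "feed_params.csv"))
  shares_path <- file.path(path, "system_shares.csv")
  system_shares <- if (file.exists(shares_path)) .read_csv(shares_path) else NULL
  aw_path <- file.path(path, "animal_water.csv")
  if (file.exists(aw_path)) {
    animal_water <- .read_csv(aw_path)
  } else {
    warning("animal_water.csv not found in ", path,
            "; drinking and service water default to zero", call. = FALSE)
    animal_water <- NULL
  }
  parameter_bundle(fcr, basket, feed_params, animal_water, system_shares)
}

#' Write a parameter bundle to a directory of CSV tables
#'
#' Inverse of [read_parameter_bundle()]; the written directory re-reads to a
#' bundle with identical values.
#'
#' @param bundle a `parameter_bundle`.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_parameter_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "parameter_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  .write_csv(bundle$fcr, file.path(path, "fcr.csv"))
  .write_csv(bundle$basket, file.path(path, "basket.csv"))
  .write_csv(bundle$feed_params, file.path(path, "feed_params.csv"))
  .write_csv(bundle$animal_water, file.path(path, "animal_water.csv"))
  if (!is.null(bundle$system_shares)) {
    .write_csv(bundle$system_shares, file.path(path, "system_shares.csv"))
  }
  invisible(path)
}

#' @export
print.parameter_bundle <- function(x, ...) {
  cat("Livestock footprint parameter bundle\n")
  cat("  FCR entries:        ", nrow(x$fcr), "\n")
  cat("  basket cells:       ", length(unique(paste(x$basket$category,
                                                    x$basket$system))), "\n")
  cat("  feed types:         ",
      paste(unique(x$feed_params$feed_type), collapse = ", "), "\n")
  cat("  scenarios:          ",
      paste(sort(unique(x$fcr$scenario)), collapse = ", "), "\n")
  invisible(x)
}
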