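#' Per-animal footprint result
#'
#' Holds the per-animal water footprint split into green (soil-moisture
#' consumption by feed) and blue (irrigation, drinking and service water)
#' components, and the land footprint split into grazing land and cropland.
#' Totals are the component sums by construction.
#'
#' @param wf_green,wf_blue water footprint components, m3 per animal per
#'   accounting period; >= 0.
#' @param lf_grazing,lf_cropland land footprint components, ha per animal per
#'   accounting period; >= 0.
#' @return object of class `footprint_result` with fields `wf_green`,
#'   `wf_blue`, `wf_total`, `lf_grazing`, `lf_cropland`, `lf_total`.
#' @export
footprint_result <- function(wf_green, wf_blue, lf_grazing, lf_cropland) {
  vals <- c(wf_green, wf_blue, lf_grazing, lf_cropland)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("domain error: footprint components must be finite and >= 0",
         call. = FALSE)
  }
  structure(list(wf_green = wf_green, wf_blue = wf_blue,
                 wf_total = wf_green + wf_blue,
                 lf_grazing = lf_grazing, lf_cropland = lf_cropland,
                 lf_total = lf_grazing + lf_cropland),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("Water footprint: %s m3/animal (green %s, blue %s)\n",
              format(x$wf_total, digits = 6), format(x$wf_green, digits = 6),
              format(x$wf_blue, digits = 6)))
  cat(sprintf("Land footprint:  %s ha/animal (grazing %s, cropland %s)\n",
              format(x$lf_total, digits = 6), format(x$lf_grazing, digits = 6),
              format(x$lf_cropland, digits = 6)))
  invisible(x)
}

.match_feed_param <- function(by_type, param, what, system = NULL) {
  types <- names(by_type)
  if (length(types) == 0) return(numeric(0))
  idx <- match(types, names(param))
  if (anyNA(idx)) {
    miss <- types[is.na(idx)][1]
    where <- if (is.null(system)) miss else paste(miss, system, sep = ", ")
    stop("lookup error: no ", what, " entry for (", where, ")",
         call. = FALSE)
  }
  param[idx]
}

#' Water footprint of the feed ration
#'
#' The water embedded in producing an animal's feed is the demand-weighted sum
#' of the per-tonne water footprints of each feed type:
#' \deqn{WF_{feed} = \sum_p Feed_p \cdot wf_p}
#' evaluated separately for green and blue water.
#'
#' @param demand a [feed_demand()] object (tonnes DM per feed type).
#' @param wf_green,wf_blue named numeric vectors of water footprints by feed
#'   type (m3 per tonne DM), for the animal's production system.
#' @param system optional system label, used only in lookup error messages.
#' @return named numeric `c(green = , blue = )` in m3 per animal.
#' @export
feed_water_footprint <- function(demand, wf_green, wf_blue, system = NULL) {
  stopifnot(inherits(demand, "feed_demand"))
  g <- .match_feed_param(demand$by_type, wf_green, "green water footprint",
                         system)
  b <- .match_feed_param(demand$by_type, wf_blue, "blue water footprint",
                         system)
  if (any(g < 0) || any(b < 0)) {
    stop("domain error: feed water footprints must be >= 0", call. = FALSE)
  }
  c(green = sum(demand$by_type * g), blue = sum(demand$by_type * b))
}

#' Total per-animal water footprint
#'
#' Sums the feed, drinking and service water footprints. Drinking and service
#' water are abstractions of ground/surface water and are therefore assigned
#' entirely to the blue component; the green component is feed-only.
#'
#' @param feed_wf named numeric `c(green=, blue=)` from
#'   [feed_water_footprint()].
#' @param drink,service m3 per animal per accounting period; >= 0.
#' @return `footprint_result` with the water fields populated (land fields 0).
#' @export
animal_water_footprint <- function(feed_wf, drink, service) {
  if (drink < 0 || service < 0 || any(feed_wf < 0)) {
    stop("domain error: water footprint terms must be >= 0", call. = FALSE)
  }
  footprint_result(wf_green = unname(feed_wf[["green"]]),
                   wf_blue = unname(feed_wf[["blue"]]) + drink + service,
                   lf_grazing = 0, lf_cropland = 0)
}

#' Land footprint of the feed ration
#'
#' Land required to grow an animal's feed: each feed type contributes its
#' demand divided by the feed yield, \eqn{\sum_p Feed_p / Y_p}, accumulated
#' into grazing land (pasture) or cropland (planted forage, crop residues,
#' concentrates) according to the feed type's land class.
#'
#' @param demand a [feed_demand()] object.
#' @param feed_yield named numeric vector, tonne DM per ha by feed type; > 0.
#' @param land_class named character vector mapping feed types to
#'   `"grazing"`/`"cropland"`. Defaults to [land_class_of()] applied to the
#'   feed-type names (valid when feed types are named after their class).
#' @param system optional system label for lookup error messages.
#' @return named numeric `c(grazing = , cropland = )` in ha per animal.
#' @export
feed_land_footprint <- function(demand, feed_yield, land_class = NULL,
                                system = NULL) {
  stopifnot(inherits(demand, "feed_demand"))
  y <- .match_feed_param(demand$by_type, feed_yield, "feed yield", system)
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop("domain error: feed yield must be finite and > 0", call. = FALSE)
  }
  if (is.null(land_class)) {
    land_class <- stats::setNames(land_class_of(names(demand$by_type)),
                                  names(demand$by_type))
  }
  lc <- .match_feed_param(demand$by_type, land_class, "land class", system)
  area <- demand$by_type / y
  c(grazing = sum(area[lc == "grazing"]),
    cropland = sum(area[lc == "cropland"]))
}

#' Total per-animal land footprint
#'
#' The animal's land footprint equals its feed land footprint; land for
#' housing or feed storage is not accounted.
#'
#' @param feed_lf named numeric `c(grazing=, cropland=)` from
#'   [feed_land_footprint()].
#' @return `footprint_result` with the land fields populated (water fields 0).
#' @export
animal_land_footprint <- function(feed_lf) {
  footprint_result(wf_green = 0, wf_blue = 0,
                   lf_grazing = unname(feed_lf[["grazing"]]),
                   lf_cropland = unname(feed_lf[["cropland"]]))
}

# vectorized engine ------------------------------------------------------

# Per-cell footprints for every (category, system, scenario, year) row of a
# projection with herd > 0 (plus all rows with positive per-animal output).
# Vectorized across cells via demand/parameter matrices; the testthat suite
# checks it against a scalar per-term loop oracle.
.compute_cell_footprints <- function(params, cells) {
  stopifnot(inherits(params, "parameter_bundle"))
  n <- nrow(cells)
  ft <- sort(unique(params$basket$feed_type))

  # basket matrix: one row per projection cell, one column per feed type
  bk <- params$basket
  bkey <- .param_key(bk$category, bk$system, bk$feed_type)
  B <- matrix(0, nrow = n, ncol = length(ft), dimnames = list(NULL, ft))
  for (j in seq_along(ft)) {
    idx <- match(.param_key(cells$category, cells$system, ft[j]), bkey)
    B[, j] <- ifelse(is.na(idx), 0, bk$fraction[idx])
  }
  miss_basket <- !.rel_close(rowSums(B), 1)
  if (any(miss_basket)) {
    i <- which(miss_basket)[1]
    stop("lookup error: no complete diet basket for (", cells$category[i],
         ", ", cells$system[i], ")", call. = FALSE)
  }

  fcr <- .lookup(params$fcr, c("category", "system", "scenario"), "fcr",
                 .param_key(cells$category, cells$system, cells$scenario),
                 "feed conversion ratio")
  total_dm <- total_feed_intake(fcr, cells$output)  # tonnes DM per animal
  D <- total_dm * B

  # per-cell feed parameters aligned with the demand matrix
  fp <- params$feed_params
  fkey <- .param_key(fp$feed_type, fp$system)
  WG <- WB <- Y <- matrix(NA_real_, nrow = n, ncol = length(ft),
                          dimnames = list(NULL, ft))
  LC <- matrix(NA_character_, nrow = n, ncol = length(ft))
  for (j in seq_along(ft)) {
    idx <- match(.param_key(ft[j], cells$system), fkey)
    WG[, j] <- fp$wf_green[idx]
    WB[, j] <- fp$wf_blue[idx]
    Y[, j] <- fp$feed_yield[idx]
    LC[, j] <- land_class_of(fp$feed_class)[idx]
  }
  need <- D > 0
  if (any(need & is.na(WG))) {
    i <- which(need & is.na(WG), arr.ind = TRUE)[1, ]
    stop("lookup error: no feed parameters for (", ft[i[["col"]]], ", ",
         cells$system[i[["row"]]], ")", call. = FALSE)
  }
  WG[!need & is.na(WG)] <- 0
  WB[!need & is.na(WB)] <- 0
  Y[!need & is.na(Y)] <- 1
  LC[is.na(LC)] <- "cropland"

  feed_green <- rowSums(D * WG)
  feed_blue <- rowSums(D * WB)
  area <- D / Y
  lf_grazing <- rowSums(area * (LC == "grazing"))
  lf_cropland <- rowSums(area * (LC == "cropland"))

  drink <- .lookup(params$animal_water, c("category", "system"),
                   "drink_water", .param_key(cells$category, cells$system),
                   "drinking water")
  service <- .lookup(params$animal_water, c("category", "system"),
                     "service_water", .param_key(cells$category, cells$system),
                     "service water")

  data.frame(cells,
             feed_dm = total_dm,
             wf_green = feed_green,
             wf_blue = feed_blue + drink + service,
             wf_total = feed_green + feed_blue + drink + service,
             lf_grazing = lf_grazing,
             lf_cropland = lf_cropland,
             lf_total = lf_grazing + lf_cropland,
             stringsAsFactors = FALSE)
}
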