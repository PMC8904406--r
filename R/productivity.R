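#' Water productivity
#'
#' Product output per unit of water consumed, \eqn{WP = PO / WF}, in kg
#' product per m3. The inverse of the water footprint per kg of product.
#'
#' @param output kg product per animal per accounting period; > 0.
#' @param wf water footprint, m3 per animal per accounting period; > 0.
#' @return kg per m3. Vectorized.
#' @export
water_productivity <- function(output, wf) {
  if (any(!is.finite(output)) || any(output <= 0)) {
    stop("domain error: output must be > 0", call. = FALSE)
  }
  if (any(!is.finite(wf)) || any(wf <= 0)) {
    stop("domain error: water footprint must be > 0 (productivity undefined)",
         call. = FALSE)
  }
  output / wf
}

#' Land productivity
#'
#' Product output per unit of land used, \eqn{LP = PO / LF}, in kg product
#' per ha.
#'
#' @param output kg product per animal per accounting period; > 0.
#' @param lf land footprint, ha per animal per accounting period; > 0.
#' @return kg per ha. Vectorized.
#' @export
land_productivity <- function(output, lf) {
  if (any(!is.finite(output)) || any(output <= 0)) {
    stop("domain error: output must be > 0", call. = FALSE)
  }
  if (any(!is.finite(lf)) || any(lf <= 0)) {
    stop("domain error: land footprint must be > 0 (productivity undefined)",
         call. = FALSE)
  }
  output / lf
}

#' Footprint per tonne of product
#'
#' Converts a per-animal footprint to a per-tonne-of-product footprint by
#' dividing each component by the per-animal output in tonnes. The green/blue
#' and grazing/cropland decompositions are preserved. The per-tonne water
#' footprint is the inverse of water productivity on the kg/tonne scale:
#' `wf_total` per tonne times `water_productivity()` equals 1000.
#'
#' @param fr a [footprint_result()] (per animal).
#' @param output kg product per animal per accounting period; > 0.
#' @return named numeric with components `wf_green`, `wf_blue`, `wf_total`
#'   (m3 per tonne) and `lf_grazing`, `lf_cropland`, `lf_total` (ha per
#'   tonne).
#' @export
per_tonne_footprint <- function(fr, output) {
  stopifnot(inherits(fr, "footprint_result"))
  if (!is.finite(output) || output <= 0) {
    stop("domain error: output must be > 0", call. = FALSE)
  }
  tonnes <- output / 1000
  c(wf_green = fr$wf_green, wf_blue = fr$wf_blue, wf_total = fr$wf_total,
    lf_grazing = fr$lf_grazing, lf_cropland = fr$lf_cropland,
    lf_total = fr$lf_total) / tonnes
}

#' Percent change between two quantities
#'
#' `100 * (b - a) / a`; e.g. a quadrupling is +300%.
#'
#' @param a baseline quantity; > 0.
#' @param b comparison quantity.
#' @return percent change. Vectorized.
#' @export
percent_change <- function(a, b) {
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("domain error: baseline must be > 0", call. = FALSE)
  }
  100 * (b - a) / a
}

#' Herd-level totals of production, water and land use
#'
#' Scales per-animal output and footprints by head counts and sums over
#' categories and systems: total production (tonnes), total water use (m3,
#' split green/blue) and total land use (ha, split grazing/cropland), per
#' scenario, year and commodity (milk from dairy categories, meat from meat
#' categories). Structural-zero cells (zero herd) contribute nothing.
#'
#' @param projection a `projection_bundle` (see [projection_bundle()]).
#' @param footprints per-animal footprint table as produced by the engine:
#'   one row per (category, system, scenario, year) with columns `wf_green`,
#'   `wf_blue`, `wf_total`, `lf_grazing`, `lf_cropland`, `lf_total`.
#' @param year,scenario optional filters; default all.
#' @return data.frame with one row per (scenario, year, product) and columns
#'   `total_production` (tonnes), `total_wf_green`, `total_wf_blue`,
#'   `total_wf` (m3), `total_lf_grazing`, `total_lf_cropland`, `total_lf`
#'   (ha).
#' @export
aggregate_totals <- function(projection, footprints, year = NULL,
                             scenario = NULL) {
  proj <- if (inherits(projection, "projection_bundle")) {
    projection$table
  } else {
    projection
  }
  .require_columns(proj, c("category", "system", "scenario", "year", "herd",
                           "output"), "projection")
  .require_columns(footprints,
                   c("category", "system", "scenario", "year", "wf_green",
                     "wf_blue", "wf_total", "lf_grazing", "lf_cropland",
                     "lf_total"), "footprints")
  if (!is.null(year)) proj <- proj[proj$year %in% year, , drop = FALSE]
  if (!is.null(scenario)) {
    proj <- proj[proj$scenario %in% scenario, , drop = FALSE]
  }
  key <- .param_key(proj$category, proj$system, proj$scenario, proj$year)
  fkey <- .param_key(footprints$category, footprints$system,
                     footprints$scenario, footprints$year)
  idx <- match(key, fkey)
  uncovered <- is.na(idx) & proj$herd > 0
  if (any(uncovered)) {
    i <- which(uncovered)[1]
    stop("coverage error: no per-animal footprint for nonzero herd cell (",
         proj$category[i], ", ", proj$system[i], ", ", proj$scenario[i],
         ", ", proj$year[i], ")", call. = FALSE)
  }
  keep <- !is.na(idx)
  proj <- proj[keep, , drop = FALSE]
  fp <- footprints[idx[keep], , drop = FALSE]

  product <- ifelse(grepl("_dairy$", proj$category), "milk", "meat")
  gkey <- paste(proj$scenario, proj$year, product, sep = "\r")
  groups <- sort(unique(gkey))  # tapply groups come back in this order
  parts <- do.call(rbind, strsplit(groups, "\r", fixed = TRUE))
  h <- proj$herd
  out <- data.frame(
    scenario = parts[, 1],
    year = as.integer(parts[, 2]),
    product = parts[, 3],
    total_production = as.numeric(tapply(h * proj$output / 1000, gkey, sum)),
    total_wf_green = as.numeric(tapply(h * fp$wf_green, gkey, sum)),
    total_wf_blue = as.numeric(tapply(h * fp$wf_blue, gkey, sum)),
    total_wf = as.numeric(tapply(h * fp$wf_total, gkey, sum)),
    total_lf_grazing = as.numeric(tapply(h * fp$lf_grazing, gkey, sum)),
    total_lf_cropland = as.numeric(tapply(h * fp$lf_cropland, gkey, sum)),
    total_lf = as.numeric(tapply(h * fp$lf_total, gkey, sum)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$scenario, out$year, out$product), , drop = FALSE]
  rownames(out) <- NULL
  out
}
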