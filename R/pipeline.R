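#' Run the full water- and land-footprint accounting
#'
#' The central driver: combines a [parameter_bundle()] with a
#' [projection_bundle()] and computes, for every (category, system, scenario,
#' year) cell with animals,
#'
#' * per-animal feed dry-matter demand (feed conversion ratio times
#'   per-animal output, allocated over the diet basket),
#' * the per-animal water footprint, split into green water (soil moisture
#'   transpired by feed) and blue water (irrigation plus drinking and
#'   service water), and the per-animal land footprint, split into grazing
#'   land and cropland,
#' * footprints per tonne of product and the corresponding water and land
#'   productivities (kg product per m3 and per ha),
#' * herd-level totals of production, water and land use per scenario, year
#'   and commodity (milk/meat), with commodity-level per-tonne footprints.
#'
#' @param params a `parameter_bundle`.
#' @param projection a `projection_bundle`.
#' @return object of class `livestock_footprint` with components
#'   `footprints` (per-animal and per-tonne components per cell),
#'   `productivity` (water/land productivity per cell), `totals`
#'   (per scenario x year x commodity) and `params`/`projection` echoes.
#' @examples
#' spec <- synthetic_spec(seed = 1, calibration = "paperlike")
#' run <- livestock_footprint(generate_parameters(spec),
#'                            generate_projection(spec)$projection)
#' summary(run)
#' @export
livestock_footprint <- function(params, projection) {
  stopifnot(inherits(params, "parameter_bundle"),
            inherits(projection, "projection_bundle"))
  cells <- projection$table
  fp <- .compute_cell_footprints(params, cells)

  tonnes <- fp$output / 1000
  fp$wf_green_per_tonne <- fp$wf_green / tonnes
  fp$wf_blue_per_tonne <- fp$wf_blue / tonnes
  fp$wf_per_tonne <- fp$wf_total / tonnes
  fp$lf_grazing_per_tonne <- fp$lf_grazing / tonnes
  fp$lf_cropland_per_tonne <- fp$lf_cropland / tonnes
  fp$lf_per_tonne <- fp$lf_total / tonnes

  productivity <- data.frame(
    fp[c("category", "system", "scenario", "year", "output")],
    water_productivity = water_productivity(fp$output, fp$wf_total),
    land_productivity = land_productivity(fp$output, fp$lf_total),
    wf_per_tonne = fp$wf_per_tonne,
    lf_per_tonne = fp$lf_per_tonne,
    stringsAsFactors = FALSE
  )

  totals <- aggregate_totals(projection, fp)
  totals$wf_per_tonne <- totals$total_wf / totals$total_production
  totals$lf_per_tonne <- totals$total_lf / totals$total_production

  structure(list(footprints = fp, productivity = productivity,
                 totals = totals, params = params, projection = projection),
            class = "livestock_footprint")
}

#' @export
print.livestock_footprint <- function(x, ...) {
  yrs <- range(x$footprints$year)
  cat("Livestock water/land footprint accounting\n")
  cat("  cells:    ", nrow(x$footprints), " (", yrs[1], "-", yrs[2], ", ",
      length(unique(x$footprints$scenario)), " scenarios)\n", sep = "")
  cat("  scenarios:", paste(sort(unique(x$footprints$scenario)),
                            collapse = ", "), "\n")
  cat("Use summary() for production and footprint totals.\n")
  invisible(x)
}

#' @export
summary.livestock_footprint <- function(object, ...) {
  t0 <- min(object$totals$year)
  t1 <- max(object$totals$year)
  tot <- object$totals
  first <- tot[tot$year == t0, ]
  last <- tot[tot$year == t1, ]
  key <- paste(first$scenario, first$product)
  idx <- match(paste(last$scenario, last$product), key)
  growth <- data.frame(
    scenario = last$scenario, product = last$product,
    production_multiple = last$total_production /
      first$total_production[idx],
    wf_per_tonne_start = first$wf_per_tonne[idx],
    wf_per_tonne_end = last$wf_per_tonne,
    lf_per_tonne_start = first$lf_per_tonne[idx],
    lf_per_tonne_end = last$lf_per_tonne,
    stringsAsFactors = FALSE
  )
  wp <- object$productivity
  out <- list(horizon = c(t0, t1), growth = growth,
              wp_range = range(wp$water_productivity),
              lp_range = range(wp$land_productivity),
              green_share = sum(tot$total_wf_green) / sum(tot$total_wf))
  class(out) <- "summary.livestock_footprint"
  out
}

#' @export
print.summary.livestock_footprint <- function(x, ...) {
  cat("Accounting horizon:", x$horizon[1], "-", x$horizon[2], "\n\n")
  cat(sprintf("Production multiples %d->%d and per-tonne footprints:\n",
              x$horizon[1], x$horizon[2]))
  g <- x$growth
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-6s %-5s x%.2f   WF/t %7.0f -> %7.0f m3   LF/t %6.2f -> %6.2f ha\n",
                g$scenario[i], g$product[i], g$production_multiple[i],
                g$wf_per_tonne_start[i], g$wf_per_tonne_end[i],
                g$lf_per_tonne_start[i], g$lf_per_tonne_end[i]))
  }
  cat(sprintf("\nWater productivity range: %.4f - %.4f kg/m3\n",
              x$wp_range[1], x$wp_range[2]))
  cat(sprintf("Land productivity range:  %.1f - %.1f kg/ha\n",
              x$lp_range[1], x$lp_range[2]))
  cat(sprintf("Green share of total water footprint: %.1f%%\n",
              100 * x$green_share))
  invisible(x)
}

#' Plot per-tonne footprint and productivity trajectories
#'
#' Draws commodity-level water footprint per tonne (left) and water
#' productivity (right) over the accounting horizon, one line per scenario.
#'
#' @param x a `livestock_footprint` object.
#' @param product `"milk"` or `"meat"`.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.livestock_footprint <- function(x, product = c("milk", "meat"), ...) {
  product <- match.arg(product)
  tot <- x$totals[x$totals$product == product, ]
  scn <- sort(unique(tot$scenario))
  cols <- grDevices::hcl.colors(max(3, length(scn)), "Dark 3")
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(NULL, xlim = range(tot$year), ylim = range(tot$wf_per_tonne),
                 xlab = "year", ylab = expression(m^3 ~ "per tonne"),
                 main = paste("water footprint,", product))
  for (i in seq_along(scn)) {
    s <- tot[tot$scenario == scn[i], ]
    graphics::lines(s$year, s$wf_per_tonne, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = scn, col = cols[seq_along(scn)],
                   lwd = 2, bty = "n")
  graphics::plot(NULL, xlim = range(tot$year),
                 ylim = range(1000 / tot$wf_per_tonne),
                 xlab = "year", ylab = "kg per m3",
                 main = paste("water productivity,", product))
  for (i in seq_along(scn)) {
    s <- tot[tot$scenario == scn[i], ]
    graphics::lines(s$year, 1000 / s$wf_per_tonne, col = cols[i], lwd = 2)
  }
  invisible(x)
}

.to_long <- function(df, idcols) {
  mcols <- setdiff(names(df), idcols)
  out <- do.call(rbind, lapply(mcols, function(m) {
    data.frame(df[idcols], metric = m, value = df[[m]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(df[idcols], metric = character(0), value = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Write the result tables of a run
#'
#' Writes `footprints.csv`, `productivity.csv` and `totals.csv` into `path`
#' in tidy long format (one row per index tuple and metric), via
#' [write_results()]. Output is byte-stable: two runs from the same inputs
#' produce identical files.
#'
#' @param x a `livestock_footprint` object.
#' @param path output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_footprint_tables <- function(x, path) {
  stopifnot(inherits(x, "livestock_footprint"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  id <- c("category", "system", "scenario", "year")
  write_results(.to_long(x$footprints, id), file.path(path, "footprints.csv"))
  write_results(.to_long(x$productivity, id),
                file.path(path, "productivity.csv"))
  write_results(.to_long(x$totals, c("scenario", "year", "product")),
                file.path(path, "totals.csv"))
  invisible(path)
}
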