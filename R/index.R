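#' Index space of the accounting
#'
#' The whole accounting is indexed by animal category (species x purpose),
#' production system and scenario. These helpers define the valid levels and
#' the structural-zero mask; everything downstream iterates over this grid.
#'
#' @name index-space
NULL

.species_levels <- c("cattle", "shoats", "camel")
.purpose_levels <- c("dairy", "meat")
.system_levels <- c("arid", "semi_arid", "humid")
.scenario_levels <- c("BAU", "SDP", "V2030")
.feed_class_levels <- c("pasture", "planted_forage", "crop_residue", "concentrate")

#' Construct a validated animal-category identifier
#'
#' Animal categories combine a species with a production purpose. Camels are
#' accounted only for dairy: camel meat production is excluded from the
#' analysis, so `animal_category("camel", "meat")` is an error. Sheep and
#' goats are a single aggregated category ("shoats") and are never split.
#'
#' @param species one of `"cattle"`, `"shoats"`, `"camel"`.
#' @param purpose one of `"dairy"`, `"meat"`.
#' @return a length-1 character id, e.g. `"cattle_dairy"`.
#' @examples
#' animal_category("cattle", "dairy")
#' @export
animal_category <- function(species, purpose) {
  species <- match.arg(species, .species_levels)
  purpose <- match.arg(purpose, .purpose_levels)
  if (species == "camel" && purpose == "meat") {
    stop("invalid animal category: camel meat is excluded from the accounting",
         call. = FALSE)
  }
  paste(species, purpose, sep = "_")
}

#' Valid animal categories
#'
#' @return data.frame with columns `category`, `species`, `purpose` covering
#'   the five valid categories (camel meat excluded).
#' @export
animal_categories <- function() {
  grid <- expand.grid(species = .species_levels, purpose = .purpose_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[!(grid$species == "camel" & grid$purpose == "meat"), ]
  out <- data.frame(category = paste(grid$species, grid$purpose, sep = "_"),
                    species = grid$species, purpose = grid$purpose,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$category), , drop = FALSE]
}

#' @rdname animal_categories
#' @export
production_systems <- function() .system_levels

#' @rdname animal_categories
#' @export
scenario_ids <- function() .scenario_levels

#' @rdname animal_categories
#' @export
feed_classes <- function() .feed_class_levels

#' Land class of a feed class
#'
#' Pasture (including hay and silage) occupies grazing land; planted forage,
#' crop residues and concentrates originate from cropland.
#'
#' @param feed_class character vector of feed classes.
#' @return character vector, `"grazing"` or `"cropland"`.
#' @export
land_class_of <- function(feed_class) {
  bad <- setdiff(unique(feed_class), .feed_class_levels)
  if (length(bad) > 0) {
    stop("unknown feed class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ifelse(feed_class == "pasture", "grazing", "cropland")
}

.check_levels <- function(x, levels, what) {
  bad <- setdiff(unique(as.character(x)), levels)
  if (length(bad) > 0) {
    stop("invalid ", what, ": ", paste(bad, collapse = ", "),
         " (expected one of ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Structural-zero cells
#'
#' Dairy shoats and dairy camels are not kept in the humid system; those
#' (category, system) cells are structurally zero in every scenario and year.
#'
#' @param category character vector of category ids.
#' @param system character vector of production systems.
#' @return logical vector, `TRUE` where the cell is structurally zero.
#' @export
is_structural_zero <- function(category, system) {
  .check_levels(category, animal_categories()$category, "animal category")
  .check_levels(system, .system_levels, "production system")
  (category %in% c("shoats_dairy", "camel_dairy")) & system == "humid"
}

#' Valid (category, system) cells
#'
#' @return data.frame of all (category, system) combinations that are not
#'   structural zeros.
#' @export
valid_cells <- function() {
  grid <- expand.grid(category = animal_categories()$category,
                      system = .system_levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[!is_structural_zero(grid$category, grid$system), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

# relative tolerance used for conservation / normalization assertions
.REL_TOL <- 1e-9

.rel_close <- function(a, b, tol = .REL_TOL) {
  abs(a - b) <= tol * pmax(abs(a), abs(b), 1)
}
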