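#' Species-by-cell occurrence structure on a regular grid
#'
#' @param presence data frame with columns `species`, `cell_id`
#'   (duplicates dropped).
#' @param cells data frame with columns `cell_id`, `x`, `y` (integer grid
#'   indices) and optionally `realm`.
#' @param cell_km grid cell side length in km.
#' @return object of class `occurrence_grid`: list with `species`, `cells`,
#'   `presence`, `range_size` (occupied-cell counts per species), `cell_km`.
#' @export
occurrence_grid <- function(presence, cells, cell_km = 100) {
  stopifnot(all(c("species", "cell_id") %in% names(presence)),
            all(c("cell_id", "x", "y") %in% names(cells)),
            cell_km > 0)
  if (anyDuplicated(cells$cell_id)) stop("duplicated cell ids")
  presence <- unique(presence[, c("species", "cell_id")])
  bad <- setdiff(presence$cell_id, cells$cell_id)
  if (length(bad)) stop("presence refers to unknown cells: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  presence$species <- as.character(presence$species)
  species <- sort(unique(presence$species))
  rs <- table(factor(presence$species, levels = species))
  structure(list(species = species, cells = cells,
                 presence = presence,
                 range_size = stats::setNames(as.integer(rs), species),
                 cell_km = cell_km),
            class = "occurrence_grid")
}

#' @export
print.occurrence_grid <- function(x, ...) {
  cat(sprintf("occurrence_grid: %d species x %d cells (%g km), %d presences\n",
              length(x$species), nrow(x$cells), x$cell_km, nrow(x$presence)))
  invisible(x)
}

#' Per-cell weighted endemism
#'
#' WE(cell) = sum over resident species of 1 / (range size in cells), so a
#' single-cell endemic contributes 1 and a widespread species very little;
#' summed over the grid each species contributes exactly 1.
#'
#' @param occ an [occurrence_grid()].
#' @return named numeric vector over all cells (0 for empty cells).
#' @export
weighted_endemism <- function(occ) {
  w <- 1 / occ$range_size[occ$presence$species]
  v <- tapply(w, factor(occ$presence$cell_id, levels = occ$cells$cell_id),
              sum, default = 0)
  stats::setNames(as.numeric(v), occ$cells$cell_id)
}

#' Per-cell species richness
#'
#' @param occ an [occurrence_grid()].
#' @param species optional subset of species to count.
#' @return named integer vector of counts over all cells.
#' @export
species_richness <- function(occ, species = NULL) {
  pres <- occ$presence
  if (!is.null(species)) pres <- pres[pres$species %in% species, , drop = FALSE]
  v <- tapply(rep(1L, nrow(pres)),
              factor(pres$cell_id, levels = occ$cells$cell_id),
              sum, default = 0L)
  stats::setNames(as.integer(v), occ$cells$cell_id)
}

#' Cell partition into hotspot and non-hotspot classes
#'
#' @param cell_id cell identifiers (the occupied-cell universe).
#' @param hotspot logical vector, same length.
#' @param realm realm name per cell (recycled if length 1).
#' @param metric,clade optional provenance labels.
#' @return `region_partition` data frame with columns `cell_id`, `class`,
#'   `realm`.
#' @export
region_partition <- function(cell_id, hotspot, realm = "all",
                             metric = NA_character_, clade = NA_character_) {
  stopifnot(length(cell_id) == length(hotspot))
  out <- data.frame(cell_id = cell_id,
                    class = ifelse(hotspot, "hotspot", "non-hotspot"),
                    realm = rep_len(realm, length(cell_id)))
  attr(out, "metric") <- metric
  attr(out, "clade") <- clade
  class(out) <- c("region_partition", "data.frame")
  out
}

#' Delineate hotspots as the top quantile of a per-cell metric
#'
#' Marks the `ceiling(fraction * n)` highest-valued occupied cells as
#' hotspots.  Cells with zero species are excluded from the quantile
#' universe; ties at the threshold are broken by cell id so the result is
#' deterministic.
#'
#' @param values named per-cell metric (names = cell ids).
#' @param occ the [occurrence_grid()] (used for occupancy and realms).
#' @param fraction proportion of occupied cells to mark (default 0.20).
#' @return a [region_partition()] over the occupied cells.
#' @export
delineate_top_quantile <- function(values, occ, fraction = 0.20) {
  stopifnot(fraction > 0, fraction < 1)
  sr <- species_richness(occ)
  occupied <- names(sr)[sr > 0]
  if (!all(occupied %in% names(values)))
    stop("metric does not cover all occupied cells")
  v <- values[occupied]
  if (length(unique(v)) == 1L)
    stop("metric is degenerate (all values equal); hotspots undefined")
  n_hot <- ceiling(fraction * length(v))
  ord <- order(-v, occupied)  # ties broken by cell id
  hot <- occupied[ord[seq_len(n_hot)]]
  realms <- if ("realm" %in% names(occ$cells))
    occ$cells$realm[match(occupied, occ$cells$cell_id)] else "all"
  region_partition(occupied, occupied %in% hot, realms)
}

#' Cell count equivalent of a narrow-range area threshold
#'
#' @param cell_km grid cell side (km); @param area_km2 range-area threshold.
#' @return threshold expressed in whole grid cells.
#' @export
nrs_max_cells <- function(cell_km = 100, area_km2 = 1e5) {
  floor(area_km2 / cell_km^2)
}

#' Delineate hotspots as cells holding narrow-ranged species
#'
#' Every cell occupied by at least one species whose range is at most
#' `max_cells` cells is a hotspot (a center of endemism).  With 100-km cells
#' the default reproduces the 100,000 km2 narrow-range threshold (10 cells).
#'
#' @param occ an [occurrence_grid()].
#' @param max_cells range-size ceiling in cells.
#' @return a [region_partition()] over the occupied cells.
#' @export
delineate_nrs <- function(occ, max_cells = nrs_max_cells(occ$cell_km)) {
  stopifnot(max_cells >= 1)
  nrs <- names(occ$range_size)[occ$range_size <= max_cells]
  sr <- species_richness(occ)
  occupied <- names(sr)[sr > 0]
  hot_cells <- unique(occ$presence$cell_id[occ$presence$species %in% nrs])
  realms <- if ("realm" %in% names(occ$cells))
    occ$cells$realm[match(occupied, occ$cells$cell_id)] else "all"
  region_partition(occupied, occupied %in% hot_cells, realms)
}

#' Percent overlap between two hotspot delineations
#'
#' Default denominator is the smaller hotspot set, giving a symmetric
#' percentage when the two sets differ slightly in size; `method = "jaccard"`
#' uses the union instead.
#'
#' @param a,b [region_partition()]s on the same cell universe.
#' @param method `"min"` (fraction of the smaller set) or `"jaccard"`.
#' @return overlap percentage in \[0, 100\].
#' @export
partition_overlap <- function(a, b, method = c("min", "jaccard")) {
  method <- match.arg(method)
  if (!setequal(a$cell_id, b$cell_id))
    stop("partitions cover different cell universes")
  ha <- a$cell_id[a$class == "hotspot"]
  hb <- b$cell_id[b$class == "hotspot"]
  if (length(ha) == 0L || length(hb) == 0L) stop("empty hotspot set")
  inter <- length(intersect(ha, hb))
  denom <- if (method == "min") min(length(ha), length(hb))
           else length(union(ha, hb))
  100 * inter / denom
}
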