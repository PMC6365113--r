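#' Writers and readers for the pipeline's file formats
#'
#' All tabular interchange is plain CSV; trees are Newick.  Every writer has
#' a reader that round-trips the object.
#'
#' @param x object to write; @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
write_occurrence_csv <- function(x, path) {
  utils::write.csv(x$presence, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param cells cell table; @param cell_km cell size for the reconstructed
#'   grid.
#' @export
read_occurrence_csv <- function(path, cells, cell_km = 100) {
  occurrence_grid(utils::read.csv(path), cells, cell_km)
}

#' @rdname io
#' @export
write_cells_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cells_csv <- function(path) utils::read.csv(path)

#' @rdname io
#' @export
write_partition_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_partition_csv <- function(path) {
  df <- utils::read.csv(path)
  region_partition(df$cell_id, df$class == "hotspot", df$realm)
}

#' @rdname io
#' @export
write_tree_newick <- function(x, path) {
  ape::write.tree(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_tree_newick <- function(path) ape::read.tree(path)

#' @rdname io
#' @export
write_env_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_env_csv <- function(path) utils::read.csv(path)

#' @rdname io
#' @param series a `rate_series`; @param realm label column value.
#' @export
write_rate_series_csv <- function(series, path, realm = "all") {
  df <- data.frame(realm = realm, series = series$series,
                   bin_start = series$bins$start, bin_end = series$bins$end,
                   median = series$median, q10 = series$q10,
                   q90 = series$q90, n_maps = nrow(series$per_map))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param truth list of ground-truth values.
#' @export
write_ground_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_ground_truth_json <- function(path) jsonlite::read_json(path)
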