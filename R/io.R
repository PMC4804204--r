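#' Write a landscape grid to a CSV cell table
#'
#' One row per cell; columns are the documented cell attributes plus
#' `occupancy0`, `carrying_capacity` and the constant `cell_width` (metres).
#' Optionally writes a JSON sidecar echoing the generator configuration.
#'
#' @param grid a `landscape_grid`.
#' @param path output CSV path.
#' @param config optional `generator_config` (or any list) echoed to
#'   `<path>.config.json`.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(grid, path, config = NULL) {
  df <- grid$cells
  df$occupancy0 <- grid$occupancy0
  df$carrying_capacity <- grid$carrying_capacity
  df$cell_width <- grid$cell_width
  write.csv(df, path, row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a landscape grid from a CSV cell table
#'
#' Validates the schema and the grid invariants (occupancy within `[0, K]`,
#' invasion confined to forest cells, binary fields 0/1). Unknown columns are
#' carried through untouched in `$cells`.
#'
#' @param path CSV path written by [write_cell_table()] (or hand-built with the
#'   same mandatory columns).
#' @return A `landscape_grid`.
#' @export
read_cell_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  mandatory <- c(
    "cell_id", "x", "y", "land_type", "slope", "water_adjacent", "tmax",
    "precip", "stand_age", "site_productivity", "artificial_regen",
    "road_distance", "fire_disturbance", "private_ownership",
    "physiographic_class", "occupancy0", "carrying_capacity", "cell_width"
  )
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0) {
    stop("cell table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  cell_width <- df$cell_width[1]
  cells <- df[setdiff(names(df), c("occupancy0", "carrying_capacity",
                                   "cell_width"))]
  new_landscape_grid(
    cells = cells,
    cell_width = cell_width,
    carrying_capacity = df$carrying_capacity,
    occupancy0 = df$occupancy0
  )
}
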