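#' Build nested planning-unit grids clipped to reef
#'
#' Tiles the reefscape with two aligned square grids: small units of 1 km2
#' and large units of 25 km2, so 25 small units nest in each large one.
#' Units are trimmed to reef: a unit's area is the reef it contains, and
#' units with no reef are dropped. Edge units (square footprint not fully
#' reef) are flagged.
#'
#' @param reefscape A [generate_reefscape()] result.
#' @param small_km Side of a small unit in km (default 1).
#' @param large_km Side of a large unit in km (default 5).
#' @return A `pu_grid`: list with `units` (tibble: `pu_id`, `size_class`
#'   "S"/"L", `row0`, `col0`, `reef_area_km2`, `parent_id`, `is_edge`,
#'   `n_cells`), `cell_map` (tibble: `cell_id`, `small_id`, `large_id` for
#'   reef cells), and `nesting` (tibble: `large_id`, `small_id`).
#' @export
build_grids <- function(reefscape, small_km = 1, large_km = 5) {
  stopifnot(inherits(reefscape, "reefscape"))
  cs <- reefscape$cell_size_km
  s_span <- small_km / cs
  l_span <- large_km / cs
  if (abs(s_span - round(s_span)) > 1e-9 || abs(l_span - round(l_span)) > 1e-9)
    abort("planning-unit sides must be integer multiples of the cell size")
  s_span <- as.integer(round(s_span)); l_span <- as.integer(round(l_span))
  if (reefscape$n_rows %% l_span != 0 || reefscape$n_cols %% l_span != 0)
    abort(paste0("grid dimensions must be divisible by the large-unit span (",
                 l_span, " cells); no ragged tiling"))

  cells <- reefscape$cells
  reef <- dplyr::filter(cells, .data$reef_fraction > 0)
  if (nrow(reef) == 0) {
    warn("reefscape contains no reef; returning an empty grid")
    empty <- tibble::tibble(pu_id = integer(), size_class = character(),
                            row0 = integer(), col0 = integer(),
                            reef_area_km2 = double(), parent_id = integer(),
                            is_edge = logical(), n_cells = integer())
    return(structure(list(units = empty,
                          cell_map = tibble::tibble(cell_id = integer(),
                                                    reef_fraction = double(),
                                                    small_id = integer(),
                                                    large_id = integer()),
                          nesting = tibble::tibble(large_id = integer(),
                                                   small_id = integer()),
                          small_span = s_span, large_span = l_span,
                          cell_size_km = cs,
                          cell_area_km2 = reefscape$cell_area_km2),
                     class = "pu_grid"))
  }

  n_scol <- reefscape$n_cols %/% s_span
  n_lcol <- reefscape$n_cols %/% l_span
  sr <- reef$row %/% s_span; sc <- reef$col %/% s_span
  lr <- reef$row %/% l_span; lc <- reef$col %/% l_span
  small_key <- sr * n_scol + sc + 1L
  large_key <- lr * n_lcol + lc + 1L

  area <- reefscape$cell_area_km2
  mk_units <- function(key, span, size_class, n_kcol) {
    tb <- tibble::tibble(key = key, frac = reef$reef_fraction) |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(reef_area_km2 = sum(.data$frac) * area,
                       n_cells = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(.data$key)
    tb$pu_id <- seq_len(nrow(tb))
    tb$row0 <- ((tb$key - 1L) %/% n_kcol) * span
    tb$col0 <- ((tb$key - 1L) %% n_kcol) * span
    # edge = footprint not fully reef (missing cells or partial fractions)
    full_area <- (span * cs)^2
    tb$is_edge <- tb$reef_area_km2 < full_area - 1e-9
    tb$size_class <- size_class
    tb
  }
  small <- mk_units(small_key, s_span, "S", n_scol)
  large <- mk_units(large_key, l_span, "L", n_lcol)

  small_id_of <- small$pu_id[match(small_key, small$key)]
  large_id_of <- large$pu_id[match(large_key, large$key)]
  cell_map <- tibble::tibble(cell_id = reef$cell_id,
                             reef_fraction = reef$reef_fraction,
                             small_id = small_id_of, large_id = large_id_of)

  nesting <- dplyr::distinct(tibble::tibble(large_id = large_id_of,
                                            small_id = small_id_of)) |>
    dplyr::arrange(.data$large_id, .data$small_id)
  small$parent_id <- nesting$large_id[match(small$pu_id, nesting$small_id)]
  large$parent_id <- NA_integer_

  units <- dplyr::bind_rows(small, large) |>
    dplyr::select("pu_id", "size_class", "row0", "col0", "reef_area_km2",
                  "parent_id", "is_edge", "n_cells")
  structure(list(units = units, cell_map = cell_map, nesting = nesting,
                 small_span = s_span, large_span = l_span,
                 cell_size_km = cs, cell_area_km2 = area),
            class = "pu_grid")
}

#' @export
print.pu_grid <- function(x, ...) {
  ns <- sum(x$units$size_class == "S"); nl <- sum(x$units$size_class == "L")
  cat("<pu_grid> ", ns, " small + ", nl, " large planning units (",
    x$small_span, "/", x$large_span, " cells per side)\n", sep = "")
  invisible(x)
}

#' Intersect a planning-unit grid with reef classes at one thematic level
#'
#' The amount of a class in a unit is the reef area (cell reef fraction times
#' cell area) of the unit's cells carrying that class label. Amounts at any
#' level sum to the total reef area.
#'
#' @param reefscape A reefscape.
#' @param grid A [build_grids()] result.
#' @param level Thematic level 1-5.
#' @param size_class "S" or "L".
#' @return Feature table tibble: `pu_id`, `size_class`, `level`, `class_id`,
#'   `amount_km2` (only rows with positive amount).
#' @export
intersect_features <- function(reefscape, grid, level, size_class = "S") {
  stopifnot(inherits(grid, "pu_grid"), level %in% 1:5,
            size_class %in% c("S", "L"))
  lab <- paste0("l", level)
  id_col <- if (size_class == "S") "small_id" else "large_id"
  reefscape$cells |>
    dplyr::inner_join(
      dplyr::select(grid$cell_map, "cell_id", "small_id", "large_id"),
      by = "cell_id") |>
    dplyr::group_by(pu_id = .data[[id_col]], class_id = .data[[lab]]) |>
    dplyr::summarise(
      amount_km2 = sum(.data$reef_fraction) * reefscape$cell_area_km2,
      .groups = "drop") |>
    dplyr::filter(.data$amount_km2 > 0) |>
    dplyr::mutate(size_class = size_class, level = as.integer(level)) |>
    dplyr::select("pu_id", "size_class", "level", "class_id", "amount_km2") |>
    dplyr::arrange(.data$pu_id, .data$class_id)
}

#' Per-unit uniform and variable costs
#'
#' Uniform cost equals the unit's reef area exactly (cost proportional to
#' amount of reef contained). Variable cost aggregates the cell-level cost
#' surface weighted by reef area, so a constant surface reduces to a
#' multiple of the uniform layer.
#'
#' @param grid A [build_grids()] result.
#' @param cost_surface A [generate_variable_cost()] result covering the grid.
#' @param size_class "S" or "L".
#' @return Tibble `pu_id`, `size_class`, `uniform_cost`, `variable_cost`.
#' @export
compute_costs <- function(grid, cost_surface, size_class = "S") {
  stopifnot(inherits(grid, "pu_grid"), size_class %in% c("S", "L"))
  id_col <- if (size_class == "S") "small_id" else "large_id"
  units <- dplyr::filter(grid$units, .data$size_class == !!size_class)
  cs <- grid$cell_map |>
    dplyr::inner_join(
      dplyr::select(cost_surface, "cell_id", "cost"), by = "cell_id")
  if (nrow(cs) < nrow(grid$cell_map))
    abort("cost surface does not cover the planning-unit grid")
  var <- cs |>
    dplyr::group_by(pu_id = .data[[id_col]]) |>
    dplyr::summarise(
      variable_cost = sum(.data$cost * .data$reef_fraction) * grid$cell_area_km2,
      .groups = "drop")
  out <- units |>
    dplyr::transmute(.data$pu_id, size_class = !!size_class,
                     uniform_cost = .data$reef_area_km2) |>
    dplyr::left_join(var, by = "pu_id") |>
    dplyr::arrange(.data$pu_id)
  if (any(!is.finite(out$variable_cost)) || any(out$variable_cost <= 0) ||
      any(out$uniform_cost <= 0))
    abort("non-positive or non-finite planning-unit cost")
  out
}
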