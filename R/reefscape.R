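#' Configure a synthetic reefscape
#'
#' A reefscape is a raster of square cells, each carrying the fraction of its
#' area occupied by reef and, where reef occurs, a five-level hierarchical
#' reef-class label path (coarse level 1 to fine level 5, mimicking a
#' geomorphic reef classification). Cell size defaults to 0.2 km so that a
#' 1 km2 planning unit is exactly 5 x 5 cells and a 25 km2 unit 25 x 25.
#'
#' @param grid_rows,grid_cols Cell counts of the raster.
#' @param cell_size_km Side length of one cell in km. Must divide 1 km into an
#'   integer number of cells so small planning units tile exactly.
#' @param reef_fraction_target Fraction of cells that are reef, in (0, 1].
#' @param n_patches Number of contiguous (4-connected) reef patches to grow.
#' @param classes_per_level Five integers: distinct class counts at levels
#'   1, 2, 3 and 5, and the number of level-4 branches (level-3 parent x
#'   level-4 child pairs). Non-decreasing across levels 1-3 and
#'   `classes_per_level[4] >= classes_per_level[3]`.
#' @param level4_sharing Fraction in [0, 1) of level-4 branches relabelled to
#'   reuse a level-4 label from a different level-3 parent, so that the same
#'   level-4 class recurs under several level-3 classes (as real geomorphic
#'   classifications do at that level).
#' @param rarity_skew Positive gamma shape for class-extent proportions.
#'   Values below 1 produce many small classes and a few extensive ones
#'   (a strongly skewed rarity distribution); larger values even them out.
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A `reefscape_config` list.
#' @export
reefscape_config <- function(grid_rows = 100, grid_cols = 100,
                             cell_size_km = 0.2,
                             reef_fraction_target = 0.55,
                             n_patches = 4,
                             classes_per_level = c(2, 11, 25, 43, 120),
                             level4_sharing = 0.3,
                             rarity_skew = 0.8,
                             seed = 1L) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, cell_size_km > 0,
            reef_fraction_target > 0, reef_fraction_target <= 1,
            n_patches >= 1, length(classes_per_level) == 5,
            level4_sharing >= 0, level4_sharing < 1, rarity_skew > 0)
  cl <- as.integer(classes_per_level)
  if (any(diff(cl[1:3]) < 0))
    abort("classes_per_level must be non-decreasing over levels 1-3")
  if (cl[4] < cl[3])
    abort("level-4 branch count must be at least the level-3 class count")
  if (cl[5] < cl[4])
    abort("level-5 class count must be at least the level-4 branch count")
  cells_per_km <- 1 / cell_size_km
  if (abs(cells_per_km - round(cells_per_km)) > 1e-9)
    abort("cell_size_km must divide 1 km exactly (e.g. 0.2, 0.25, 0.5)")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size_km = cell_size_km,
                 reef_fraction_target = reef_fraction_target,
                 n_patches = as.integer(n_patches),
                 classes_per_level = cl,
                 level4_sharing = level4_sharing,
                 rarity_skew = rarity_skew,
                 seed = as.integer(seed)),
            class = "reefscape_config")
}

# Recursively split a set of cells into k spatially coherent groups.
# Cells are ordered along the longer axis of their bounding box and cut at
# the weight-proportional quantile; recursion yields blocky, zone-like
# classes rather than salt-and-pepper labels.
split_cells <- function(rows, cols, idx, k, weights) {
  if (k == 1L) return(rep(1L, length(idx)))
  k1 <- k %/% 2L
  w1 <- sum(weights[seq_len(k1)]) / sum(weights)
  r <- rows[idx]; c <- cols[idx]
  axis_row <- (max(r) - min(r)) >= (max(c) - min(c))
  ord <- if (axis_row) order(r, c) else order(c, r)
  n1 <- max(k1, min(length(idx) - (k - k1), round(w1 * length(idx))))
  first <- ord[seq_len(n1)]
  lab <- integer(length(idx))
  lab[first] <- split_cells(rows, cols, idx[first], k1, weights[seq_len(k1)])
  rest <- ord[-seq_len(n1)]
  lab[rest] <- k1 +
    split_cells(rows, cols, idx[rest], k - k1, weights[-seq_len(k1)])
  lab
}

# Distribute `total` child classes over parents (each parent >= 1 child),
# extra children going preferentially to larger parents.
allocate_children <- function(parent_sizes, total) {
  p <- length(parent_sizes)
  stopifnot(total >= p)
  n_child <- rep(1L, p)
  extra <- total - p
  if (extra > 0) {
    share <- parent_sizes / sum(parent_sizes)
    add <- floor(share * extra)
    rem <- extra - sum(add)
    if (rem > 0) {
      ord <- order(share * extra - add, decreasing = TRUE)
      add[ord[seq_len(rem)]] <- add[ord[seq_len(rem)]] + 1
    }
    n_child <- n_child + as.integer(add)
  }
  # parents cannot host more children than they have cells
  over <- n_child > parent_sizes
  while (any(over)) {
    surplus <- sum(n_child[over] - parent_sizes[over])
    n_child[over] <- parent_sizes[over]
    room <- parent_sizes - n_child
    give <- which(room > 0)
    for (g in give) {
      take <- min(room[g], surplus)
      n_child[g] <- n_child[g] + take
      surplus <- surplus - take
      if (surplus == 0) break
    }
    if (surplus > 0) abort("not enough reef cells to host the class counts")
    over <- n_child > parent_sizes
  }
  n_child
}

#' Generate a synthetic reefscape
#'
#' Grows `n_patches` 4-connected reef patches to the target reef fraction,
#' assigns partial reef fractions to patch-boundary cells, then assigns the
#' five-level class hierarchy by recursive spatial subdivision so that finer
#' classes nest inside coarser ones and class extents follow a skewed
#' (many-rare, few-common) distribution. Level-4 labels are optionally shared
#' across level-3 parents (see [reefscape_config()]).
#'
#' @param config A [reefscape_config()].
#' @return A `reefscape` object: a list with `cells` (tibble: `cell_id`,
#'   `row`, `col`, `reef_fraction`, `l1`..`l5`), the config, and summary
#'   fields (`cell_area_km2`, `total_reef_area_km2`). Rows/cols are 0-based.
#' @export
generate_reefscape <- function(config) {
  stopifnot(inherits(config, "reefscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  n_cells <- nr * nc
  n_reef <- round(config$reef_fraction_target * n_cells)
  if (n_reef < config$n_patches)
    abort("reef_fraction_target unreachable: fewer reef cells than patches")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)

  # -- grow patches by seeded random accretion (4-connected) ----------------
  reef <- logical(n_cells)               # index = row * nc + col + 1
  id_of <- function(r, c) r * nc + c + 1L
  seeds_r <- sample.int(nr, config$n_patches, replace = TRUE) - 1L
  seeds_c <- sample.int(nc, config$n_patches, replace = TRUE) - 1L
  frontier <- integer(0)
  for (p in seq_len(config$n_patches)) {
    id <- id_of(seeds_r[p], seeds_c[p])
    while (reef[id]) {                   # avoid coinciding seeds
      id <- id_of(sample.int(nr, 1) - 1L, sample.int(nc, 1) - 1L)
    }
    reef[id] <- TRUE
  }
  neighbours <- function(id) {
    r <- (id - 1L) %/% nc; c <- (id - 1L) %% nc
    out <- integer(0)
    if (r > 0)      out <- c(out, id - nc)
    if (r < nr - 1) out <- c(out, id + nc)
    if (c > 0)      out <- c(out, id - 1L)
    if (c < nc - 1) out <- c(out, id + 1L)
    out
  }
  frontier <- unique(unlist(lapply(which(reef), neighbours)))
  frontier <- frontier[!reef[frontier]]
  n_have <- sum(reef)
  while (n_have < n_reef) {
    if (length(frontier) == 0)
      abort("reef_fraction_target unreachable with the given patch layout")
    pick <- frontier[sample.int(length(frontier), 1)]
    reef[pick] <- TRUE
    n_have <- n_have + 1L
    frontier <- frontier[frontier != pick]
    nb <- neighbours(pick)
    frontier <- unique(c(frontier, nb[!reef[nb]]))
  }

  rows <- (which(reef) - 1L) %/% nc
  cols <- (which(reef) - 1L) %% nc
  reef_idx <- which(reef)

  # boundary cells (reef cells with a non-reef or off-grid 4-neighbour) carry
  # a partial reef fraction, emulating trimmed reef edges
  is_boundary <- vapply(reef_idx, function(id) {
    nb <- neighbours(id)
    any(!reef[nb])
  }, logical(1))
  frac <- rep(1, length(reef_idx))
  frac[is_boundary] <- runif(sum(is_boundary), 0.25, 0.95)

  # -- hierarchical class assignment by recursive subdivision ---------------
  cl <- config$classes_per_level
  skew_w <- function(k) stats::rgamma(k, shape = config$rarity_skew) + 1e-6
  n_reef_cells <- length(reef_idx)
  if (n_reef_cells < cl[5])
    abort("fewer reef cells than level-5 classes; enlarge the grid")

  all_idx <- seq_len(n_reef_cells)
  l1 <- split_cells(rows, cols, all_idx, cl[1], skew_w(cl[1]))

  subdivide <- function(parent_lab, n_total) {
    sizes <- as.integer(table(factor(parent_lab, levels = seq_len(max(parent_lab)))))
    kids <- allocate_children(sizes, n_total)
    child <- integer(length(parent_lab))
    offset <- 0L
    for (p in seq_along(kids)) {
      sel <- which(parent_lab == p)
      child[sel] <- offset +
        split_cells(rows, cols, sel, kids[p], skew_w(kids[p]))
      offset <- offset + kids[p]
    }
    child
  }
  l2 <- subdivide(l1, cl[2])
  l3 <- subdivide(l2, cl[3])
  b4 <- subdivide(l3, cl[4])   # level-4 branches, one parent each

  # share a fraction of level-4 branches: relabel to a label already used
  # under a different level-3 parent
  branch_parent <- vapply(seq_len(cl[4]), function(b) l3[match(b, b4)], integer(1))
  l4_label <- seq_len(cl[4])
  n_share <- floor(config$level4_sharing * cl[4])
  if (n_share > 0) {
    donors <- sample(cl[4])
    shared <- 0L
    for (b in donors) {
      if (shared >= n_share) break
      cand <- which(branch_parent != branch_parent[b] & l4_label == seq_len(cl[4]))
      cand <- setdiff(cand, b)
      if (length(cand) == 0) next
      l4_label[b] <- l4_label[cand[sample.int(length(cand), 1)]]
      shared <- shared + 1L
    }
    # compact labels to 1..n_distinct
    l4_label <- as.integer(factor(l4_label))
  }
  l4 <- l4_label[b4]

  l5 <- subdivide(b4, cl[5])

  cells <- tibble::tibble(
    cell_id = seq_len(n_cells),
    row = rep(0:(nr - 1), each = nc),
    col = rep(0:(nc - 1), times = nr),
    reef_fraction = 0,
    l1 = NA_integer_, l2 = NA_integer_, l3 = NA_integer_,
    l4 = NA_integer_, l5 = NA_integer_)
  cells$reef_fraction[reef_idx] <- frac
  cells$l1[reef_idx] <- l1
  cells$l2[reef_idx] <- l2
  cells$l3[reef_idx] <- l3
  cells$l4[reef_idx] <- l4
  cells$l5[reef_idx] <- l5

  area <- config$cell_size_km^2
  structure(list(cells = cells,
                 config = config,
                 n_rows = nr, n_cols = nc,
                 cell_size_km = config$cell_size_km,
                 cell_area_km2 = area,
                 branch4 = tibble::tibble(branch = seq_len(cl[4]),
                                          l3_parent = branch_parent,
                                          l4_label = l4_label),
                 total_reef_area_km2 = sum(frac) * area),
            class = "reefscape")
}

#' @export
print.reefscape <- function(x, ...) {
  cat("<reefscape> ", x$n_rows, "x", x$n_cols, " cells (",
      x$cell_size_km, " km), reef area ",
      round(x$total_reef_area_km2, 2), " km2 in ",
      sum(x$cells$reef_fraction > 0), " reef cells\n", sep = "")
  cl <- x$config$classes_per_level
  cat("  classes/level: ", paste(cl, collapse = ", "),
      " (level-4 branches; ", length(unique(stats::na.omit(x$cells$l4))),
      " distinct level-4 labels)\n", sep = "")
  invisible(x)
}

#' Class extents of a reefscape at one thematic level
#'
#' @param reefscape A [generate_reefscape()] result.
#' @param level Thematic level 1-5.
#' @return Tibble with `class_id` and `extent_km2`; extents sum to the total
#'   reef area at every level.
#' @export
class_extents <- function(reefscape, level) {
  stopifnot(inherits(reefscape, "reefscape"), level %in% 1:5)
  lab <- paste0("l", level)
  reefscape$cells |>
    dplyr::filter(.data$reef_fraction > 0) |>
    dplyr::group_by(class_id = .data[[lab]]) |>
    dplyr::summarise(
      extent_km2 = sum(.data$reef_fraction) * reefscape$cell_area_km2,
      .groups = "drop")
}

#' Simulate fisher population centres
#'
#' Places population centres at random grid positions, biased toward the
#' vicinity of reef (fishing communities live near their grounds), with
#' log-normal population sizes. A stand-in for census-derived populations.
#'
#' @param reefscape A reefscape.
#' @param n_centres Number of centres.
#' @param mean_pop Median population size.
#' @param seed Integer seed.
#' @return Tibble `row`, `col`, `population` of class `fisher_population`.
#' @export
simulate_fishers <- function(reefscape, n_centres = 5, mean_pop = 500, seed = 1L) {
  stopifnot(n_centres >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  reef_cells <- dplyr::filter(reefscape$cells, .data$reef_fraction > 0)
  pick <- reef_cells[sample.int(nrow(reef_cells), n_centres, replace = TRUE), ]
  out <- tibble::tibble(
    row = pmin(pmax(pick$row + sample(-3:3, n_centres, TRUE), 0), reefscape$n_rows - 1),
    col = pmin(pmax(pick$col + sample(-3:3, n_centres, TRUE), 0), reefscape$n_cols - 1),
    population = pmax(1, round(stats::rlnorm(n_centres, log(mean_pop), 0.8))))
  class(out) <- c("fisher_population", class(out))
  out
}

#' Spatially variable cost surface from fisher populations
#'
#' Cell cost is the population-weighted linear distance decay
#' `sum_j pop_j * max(eps, 1 - d_ij / decay_radius_km)` with `d_ij` the
#' Euclidean centre-to-centre distance in km and `eps = 1e-6`, a proxy for
#' opportunity cost to fishers: highest adjacent to large populations,
#' declining linearly with distance.
#'
#' @param reefscape A reefscape.
#' @param fishers Tibble with `row`, `col`, `population` (>= 1 row).
#' @param decay_radius_km Distance at which a centre's influence reaches the
#'   floor; defaults to the grid diagonal so cost never truncates.
#' @return Tibble `cell_id`, `row`, `col`, `cost` of class `cost_surface`,
#'   strictly positive everywhere.
#' @export
generate_variable_cost <- function(reefscape, fishers, decay_radius_km = NULL) {
  if (is.null(fishers) || nrow(fishers) == 0)
    abort("at least one fisher population centre is required")
  stopifnot(all(fishers$population >= 1),
            all(fishers$row >= 0), all(fishers$row < reefscape$n_rows),
            all(fishers$col >= 0), all(fishers$col < reefscape$n_cols))
  if (is.null(decay_radius_km))
    decay_radius_km <- sqrt(reefscape$n_rows^2 + reefscape$n_cols^2) *
      reefscape$cell_size_km
  stopifnot(decay_radius_km > 0)
  eps <- 1e-6
  cells <- reefscape$cells
  cost <- rep(0, nrow(cells))
  for (j in seq_len(nrow(fishers))) {
    d <- sqrt((cells$row - fishers$row[j])^2 + (cells$col - fishers$col[j])^2) *
      reefscape$cell_size_km
    cost <- cost + fishers$population[j] * pmax(eps, 1 - d / decay_radius_km)
  }
  out <- tibble::tibble(cell_id = cells$cell_id, row = cells$row,
                        col = cells$col, cost = cost)
  class(out) <- c("cost_surface", class(out))
  out
}
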