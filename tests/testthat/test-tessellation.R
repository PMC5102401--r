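test_that("fully-reef reefscape tiles into exact nested grids", {
  rs <- full_reefscape(rows = 50, cols = 50)   # 10 x 10 km
  g <- build_grids(rs)
  small <- dplyr::filter(g$units, size_class == "S")
  large <- dplyr::filter(g$units, size_class == "L")
  expect_equal(nrow(small), 100)
  expect_equal(nrow(large), 4)
  expect_equal(small$reef_area_km2, rep(1, 100))
  expect_equal(large$reef_area_km2, rep(25, 4))
  expect_false(any(large$is_edge))
  comp <- dplyr::count(g$nesting, large_id)
  expect_equal(comp$n, rep(25L, 4))
  # partition: small areas within a large unit sum to its area
  part <- g$nesting |>
    dplyr::left_join(dplyr::select(small, pu_id, reef_area_km2),
                     by = c(small_id = "pu_id")) |>
    dplyr::group_by(large_id) |>
    dplyr::summarise(s = sum(reef_area_km2))
  expect_equal(part$s, large$reef_area_km2)
})

test_that("partial reef is clipped and flagged as edge", {
  rs <- full_reefscape(rows = 25, cols = 25)
  cells <- rs$cells
  cells$reef_fraction <- 0
  cells[c("l1", "l2", "l3", "l4", "l5")] <- NA_integer_
  cells$reef_fraction[100] <- 0.5
  cells$l1[100] <- cells$l2[100] <- cells$l3[100] <- cells$l4[100] <-
    cells$l5[100] <- 1L
  rs$cells <- cells
  g <- build_grids(rs)
  large <- dplyr::filter(g$units, size_class == "L")
  expect_equal(nrow(large), 1)
  expect_equal(large$reef_area_km2, 0.5 * 0.04)
  expect_true(large$is_edge)
})

test_that("no reef yields an empty grid with a warning", {
  rs <- full_reefscape(rows = 25, cols = 25)
  rs$cells$reef_fraction <- 0
  expect_warning(g <- build_grids(rs), "no reef")
  expect_equal(nrow(g$units), 0)
})

test_that("non-divisible grid dimensions are refused", {
  rs <- full_reefscape(rows = 30, cols = 30)  # 30 %% 25 != 0
  expect_error(build_grids(rs), "divisible")
})

test_that("nesting never exceeds 25 and partition holds on random reef", {
  rs <- tiny_reefscape(seed = 5)
  g <- build_grids(rs)
  comp <- dplyr::count(g$nesting, large_id)
  expect_true(all(comp$n <= 25))
  interior <- dplyr::filter(g$units, size_class == "L", !is_edge)
  if (nrow(interior) > 0)
    expect_true(all(comp$n[match(interior$pu_id, comp$large_id)] == 25))
  small <- dplyr::filter(g$units, size_class == "S")
  expect_true(all(small$reef_area_km2 > 0))
  expect_true(all(!is.na(small$parent_id)))
})

test_that("feature intersection conserves area and refines levels", {
  rs <- tiny_reefscape(seed = 9, rows = 25, cols = 25, frac = 0.6)
  g <- build_grids(rs)
  for (sz in c("S", "L")) for (lv in c(1L, 5L)) {
    ft <- intersect_features(rs, g, lv, sz)
    expect_equal(sum(ft$amount_km2), rs$total_reef_area_km2)
    expect_true(all(ft$amount_km2 > 0))
  }
  # level-5 amounts summed by l1 ancestor reproduce the level-1 table
  anc <- rs$cells |>
    dplyr::filter(reef_fraction > 0) |>
    dplyr::distinct(l5, l1)
  f5 <- intersect_features(rs, g, 5, "S") |>
    dplyr::left_join(anc, by = c(class_id = "l5")) |>
    dplyr::group_by(pu_id, class_id = l1) |>
    dplyr::summarise(amount_km2 = sum(amount_km2), .groups = "drop") |>
    dplyr::arrange(pu_id, class_id)
  f1 <- intersect_features(rs, g, 1, "S") |>
    dplyr::select(pu_id, class_id, amount_km2) |>
    dplyr::arrange(pu_id, class_id)
  expect_equal(as.data.frame(f5), as.data.frame(f1))
})

test_that("unit splits half-and-half by area give symmetric amounts", {
  rs <- full_reefscape(rows = 25, cols = 25)
  # one small planning unit: recolour its 25 cells half A half B by area
  g <- build_grids(rs)
  cells <- rs$cells
  first_pu <- g$cell_map$cell_id[g$cell_map$small_id == 1]
  # 25 cells of fraction possibly < 1 at boundary; force uniform fraction
  cells$reef_fraction[cells$cell_id %in% first_pu] <- 1
  cells$l5[cells$cell_id %in% first_pu] <- rep(c(7L, 8L), length.out = 25)
  rs$cells <- cells
  g2 <- build_grids(rs)
  ft <- intersect_features(rs, g2, 5, "S") |> dplyr::filter(pu_id == 1)
  a <- ft$amount_km2[ft$class_id == 7]
  b <- ft$amount_km2[ft$class_id == 8]
  expect_equal(a + b, 1)
  expect_equal(abs(a - b), 0.04)  # 13 vs 12 cells of 0.04 km2
})

test_that("unit costs: uniform equals reef area, variable aggregates cells", {
  rs <- full_reefscape(rows = 25, cols = 25)
  g <- build_grids(rs)
  # constant surface: variable cost is a multiple of area
  const <- tibble::tibble(cell_id = rs$cells$cell_id, cost = 1)
  cv <- compute_costs(g, const, "S")
  expect_equal(cv$uniform_cost,
               dplyr::filter(g$units, size_class == "S")$reef_area_km2)
  expect_equal(cv$variable_cost, cv$uniform_cost)
  # two equal-area cells with costs 2 and 4 average to 3 per unit area
  surf <- tibble::tibble(cell_id = rs$cells$cell_id,
                         cost = rep(c(2, 4), length.out = nrow(rs$cells)))
  cv2 <- compute_costs(g, surf, "L")
  large_area <- dplyr::filter(g$units, size_class == "L")$reef_area_km2
  expect_equal(cv2$variable_cost, 3 * large_area, tolerance = 0.05)
})
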