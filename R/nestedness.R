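#' High-priority planning units at a selection-frequency threshold
#'
#' Units selected in at least `threshold` of the replicate solutions
#' (inclusive). For large-unit scenarios the frequencies are first broadcast
#' to component small units, so all high-priority sets live at small-unit
#' resolution and can be overlaid.
#'
#' @param frequency Selection-frequency tibble (`pu_id`, `freq`) from
#'   [run_replicates()] or a `scenario_result$frequency`.
#' @param threshold Count threshold (the conventional cut-offs are 50 and 75
#'   of 100 replicates).
#' @param nesting Nesting map; required when `size_class = "L"`.
#' @param size_class "S" or "L".
#' @param code Optional scenario code carried along for reporting.
#' @return A `high_priority_set`: list with `pu_ids` (small units),
#'   `threshold`, `code`. Empty sets are returned with a warning.
#' @export
high_priority <- function(frequency, threshold, nesting = NULL,
                          size_class = "S", code = NULL) {
  R <- attr(frequency, "R") %||% max(frequency$freq, 1)
  stopifnot(threshold > 0, threshold <= R)
  vals <- dplyr::rename(frequency, value = "freq")
  if (size_class == "L") {
    if (is.null(nesting)) abort("nesting map required for large-unit scenarios")
    vals <- rasterize_to_small(vals, nesting, "L")
  }
  ids <- vals$pu_id[vals$value >= threshold]
  if (length(ids) == 0)
    warn(paste0("high-priority set is empty at threshold ", threshold))
  structure(list(pu_ids = sort(ids), threshold = threshold, code = code),
            class = "high_priority_set")
}

#' Spatial nestedness of one high-priority set within another
#'
#' Percentage of the test set's small planning units that fall inside the
#' coarse set: `100 * |test intersect coarse| / |test|`. Asymmetric by
#' construction — the denominator is always the test (fine-resolution) set.
#'
#' @param test High-priority set from a fine-resolution (test) scenario;
#'   must be non-empty.
#' @param coarse High-priority set from a coarse (large-unit) scenario,
#'   already at small-unit resolution.
#' @return Tibble with `test`, `coarse`, `threshold`, `n_test`, `n_overlap`,
#'   `percent_nested`.
#' @export
nestedness <- function(test, coarse) {
  stopifnot(inherits(test, "high_priority_set"),
            inherits(coarse, "high_priority_set"))
  if (length(test$pu_ids) == 0)
    abort("nestedness is undefined for an empty test set")
  ov <- length(intersect(test$pu_ids, coarse$pu_ids))
  n_test <- length(test$pu_ids)
  test_code <- test$code %||% NA_character_
  coarse_code <- coarse$code %||% NA_character_
  th <- test$threshold
  tibble::tibble(test = test_code, coarse = coarse_code, threshold = th,
                 n_test = n_test, n_overlap = ov,
                 percent_nested = 100 * ov / n_test)
}

#' Nestedness grid of fine test scenarios within all coarse scenarios
#'
#' Runs the standard comparison: high-priority sets of the small-unit,
#' level-5 test scenarios (default S5U and S5V) overlaid on the ten
#' large-unit scenarios, at selection-frequency thresholds 50 and 75.
#'
#' @param experiment A [run_experiment()] result.
#' @param test_codes Fine-resolution test scenario codes.
#' @param thresholds Frequency thresholds.
#' @return Tibble of [nestedness()] rows for every combination.
#' @export
nestedness_grid <- function(experiment, test_codes = c("S5U", "S5V"),
                            thresholds = c(50, 75)) {
  nesting <- experiment$grid$nesting
  coarse_codes <- names(experiment$results)[
    vapply(experiment$results, \(r) r$scenario$pu_size == "L", logical(1))]
  purrr::map_dfr(thresholds, function(th) {
    purrr::map_dfr(test_codes, function(tc) {
      test <- high_priority(experiment$results[[tc]]$frequency, th,
                            size_class = "S", code = tc)
      purrr::map_dfr(coarse_codes, function(cc) {
        coarse <- high_priority(experiment$results[[cc]]$frequency, th,
                                nesting = nesting, size_class = "L", code = cc)
        nestedness(test, coarse)
      })
    })
  })
}

#' Rarity of a reef class
#'
#' `100 * (1 - class extent / total planning extent)`: restricted classes
#' score near 100, a class covering the whole planning extent scores 0.
#'
#' @param class_extent_km2 Class extent(s), > 0.
#' @param total_planning_extent_km2 Total reef extent of the planning region.
#' @return Rarity percentage(s) in [0, 100).
#' @export
rarity <- function(class_extent_km2, total_planning_extent_km2) {
  if (any(class_extent_km2 <= 0))
    abort("rarity is undefined for zero-extent classes")
  if (any(class_extent_km2 > total_planning_extent_km2 + 1e-9))
    abort("class extent exceeds the total planning extent")
  100 * (1 - class_extent_km2 / total_planning_extent_km2)
}

#' Per-row expected-representation contributions
#'
#' Converts selection frequencies to selection probabilities `P = freq / R`
#' and multiplies by the reef-class area each unit contains, giving each
#' unit's expected contribution to a class's selected area (the worked-table
#' form of the calculation).
#'
#' @param frequency Selection-frequency tibble (`pu_id`, `freq`) of a
#'   large-unit scenario.
#' @param features Level-5 feature table (`pu_id`, `class_id`, `amount_km2`).
#' @param R Replicate count behind the frequencies.
#' @return Tibble `pu_id`, `freq`, `probability`, `class_id`, `amount_km2`,
#'   `contribution_km2`, full precision (round at export).
#' @export
representation_contributions <- function(frequency, features, R = 100) {
  stopifnot(all(frequency$freq >= 0), all(frequency$freq <= R))
  features |>
    dplyr::left_join(dplyr::select(frequency, "pu_id", "freq"), by = "pu_id") |>
    dplyr::mutate(freq = dplyr::coalesce(.data$freq, 0),
                  probability = .data$freq / R,
                  contribution_km2 = .data$probability * .data$amount_km2) |>
    dplyr::select("pu_id", "freq", "probability", "class_id", "amount_km2",
                  "contribution_km2")
}

#' Expected incidental representation of fine reef classes
#'
#' Sums the probability-weighted contributions over planning units to get
#' each level-5 class's expected selected area under a coarse scenario, the
#' percentage of the class total that represents, its rarity, and whether
#' the expectation meets the representation objective.
#'
#' @inheritParams representation_contributions
#' @param total_planning_extent_km2 Total reef extent; defaults to the sum
#'   of all feature amounts.
#' @param objective Representation objective as a proportion (default 0.30).
#' @return Tibble `class_id`, `class_total_km2`, `expected_area_km2`,
#'   `percent_of_class`, `rarity_percent`, `meets_objective`.
#' @export
expected_representation <- function(frequency, features, R = 100,
                                    total_planning_extent_km2 = NULL,
                                    objective = 0.3) {
  total_planning_extent_km2 <- total_planning_extent_km2 %||%
    sum(features$amount_km2)
  class_tot <- features |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(class_total_km2 = sum(.data$amount_km2), .groups = "drop")
  contrib <- representation_contributions(frequency, features, R)
  contrib |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(expected_area_km2 = sum(.data$contribution_km2),
                     .groups = "drop") |>
    dplyr::right_join(class_tot, by = "class_id") |>
    dplyr::mutate(
      expected_area_km2 = dplyr::coalesce(.data$expected_area_km2, 0),
      percent_of_class = 100 * .data$expected_area_km2 / .data$class_total_km2,
      rarity_percent = rarity(.data$class_total_km2,
                              total_planning_extent_km2),
      meets_objective = .data$expected_area_km2 >=
        objective * .data$class_total_km2) |>
    dplyr::select("class_id", "class_total_km2", "expected_area_km2",
                  "percent_of_class", "rarity_percent", "meets_objective") |>
    dplyr::arrange(.data$class_id)
}
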