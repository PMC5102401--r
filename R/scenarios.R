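#' Enumerate the factorial scenario design
#'
#' Full cross of planning-unit size (S, L), thematic resolution (1-5), and
#' cost variability (U uniform, V variable): 20 scenarios. Codes concatenate
#' size letter, level digit and cost letter (e.g. "L1U" = large units,
#' level 1, uniform cost). Stable order: size, then level, then cost.
#'
#' @return Tibble with `code`, `pu_size`, `level`, `cost`.
#' @export
enumerate_scenarios <- function() {
  tidyr::expand_grid(pu_size = c("S", "L"), level = 1:5, cost = c("U", "V")) |>
    dplyr::mutate(code = paste0(.data$pu_size, .data$level, .data$cost)) |>
    dplyr::select("code", "pu_size", "level", "cost")
}

#' Run one prioritisation scenario
#'
#' Builds the scenario's problem (features at its thematic level and
#' planning-unit size, its cost layer), calibrates species penalty factors,
#' runs `R` annealing replicates, and summarises each solution's extent and
#' cost proportion (solution cost over the total cost of all units under the
#' same layer). The calibration criterion is re-checked on the full
#' replicate set; offending features have their penalty doubled and the
#' replicates re-run, so every reported solution meets the objective.
#'
#' @param scenario One row of [enumerate_scenarios()].
#' @param features Feature table for the scenario's size and level
#'   (`pu_id`, `class_id`, `amount_km2`).
#' @param costs Cost table for the scenario's size ([compute_costs()]).
#' @param R Replicates (default 100).
#' @param scenario_seed Integer seed for calibration and replicates.
#' @param schedule [anneal_schedule()].
#' @param prop Representation target proportion (default 0.30).
#' @param criterion Minimum proportion met (default 0.999).
#' @param R_cal Calibration replicates per round.
#' @return A `scenario_result`: list with the scenario, calibrated problem,
#'   `solutions`, `frequency`, and `per_solution` tibble (`replicate`,
#'   `extent_km2`, `cost`, `cost_proportion`, `min_prop`).
#' @export
run_scenario <- function(scenario, features, costs, R = 100,
                         scenario_seed = 1L, schedule = anneal_schedule(),
                         prop = 0.3, criterion = 0.999, R_cal = 10) {
  cost_col <- if (scenario$cost == "U") "uniform_cost" else "variable_cost"
  cost_tbl <- tibble::tibble(pu_id = costs$pu_id, cost = costs[[cost_col]])
  area_tbl <- tibble::tibble(pu_id = costs$pu_id,
                             reef_area_km2 = costs$uniform_cost)
  problem <- make_problem(features, cost_tbl, reef_area = area_tbl, prop = prop)
  problem <- calibrate_spf(problem, R_cal = R_cal, criterion = criterion,
                           base_seed = scenario_seed, schedule = schedule)
  reps <- run_replicates(problem, R, base_seed = scenario_seed + 1000L,
                         schedule = schedule)
  # enforce the criterion on the reported replicates as well
  for (extra in seq_len(10)) {
    min_prop <- purrr::reduce(
      purrr::map(reps$solutions, \(s) s$representation$proportion), pmin)
    failing <- min_prop <= criterion
    if (!any(failing)) break
    if (extra == 10)
      abort(paste0("scenario ", scenario$code,
                   ": replicates missed the criterion after recalibration"))
    problem$spf[failing] <- problem$spf[failing] * 2
    reps <- run_replicates(problem, R, base_seed = scenario_seed + 1000L,
                           schedule = schedule)
  }
  total_cost_all <- sum(problem$cost)
  per_solution <- tibble::tibble(
    replicate = seq_len(R),
    extent_km2 = vapply(reps$solutions, \(s) s$total_extent_km2, numeric(1)),
    cost = vapply(reps$solutions, \(s) s$total_cost, numeric(1)),
    min_prop = vapply(reps$solutions,
                      \(s) min(s$representation$proportion), numeric(1))) |>
    dplyr::mutate(cost_proportion = .data$cost / total_cost_all)
  structure(list(scenario = scenario, problem = problem,
                 solutions = reps$solutions, frequency = reps$frequency,
                 per_solution = per_solution, R = as.integer(R)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", x$scenario$code, ": ", x$R,
      " solutions, median extent ",
      signif(median(x$per_solution$extent_km2), 4), " km2\n", sep = "")
  invisible(x)
}

#' Run the full factorial experiment on a reefscape
#'
#' Convenience pipeline: builds both planning-unit grids, intersects features
#' at all five thematic levels and both sizes, derives both cost layers, and
#' runs all 20 scenarios with per-scenario seeds hashed from
#' `experiment_seed` and the scenario code (any single solution is thereby
#' reproducible in isolation).
#'
#' @param reefscape A [generate_reefscape()] result.
#' @param fishers Fisher population centres ([simulate_fishers()]); generated
#'   from `experiment_seed` when `NULL`.
#' @param R Replicates per scenario (default 100).
#' @param experiment_seed Integer master seed.
#' @param schedule [anneal_schedule()].
#' @param prop,criterion,R_cal Passed to [run_scenario()].
#' @return A `reef_experiment`: list with `reefscape`, `grid`, `features`
#'   (nested tibble), `costs` (by size), `fishers`, and `results` (named list
#'   of `scenario_result`).
#' @export
run_experiment <- function(reefscape, fishers = NULL, R = 100,
                           experiment_seed = 1L,
                           schedule = anneal_schedule(),
                           prop = 0.3, criterion = 0.999, R_cal = 10) {
  grid <- build_grids(reefscape)
  if (is.null(fishers))
    fishers <- simulate_fishers(reefscape, seed = experiment_seed)
  surface <- generate_variable_cost(reefscape, fishers)
  costs <- list(S = compute_costs(grid, surface, "S"),
                L = compute_costs(grid, surface, "L"))
  features <- list()
  for (sz in c("S", "L")) for (lv in 1:5)
    features[[paste0(sz, lv)]] <- intersect_features(reefscape, grid, lv, sz)

  scenarios <- enumerate_scenarios()
  results <- purrr::pmap(scenarios, function(code, pu_size, level, cost) {
    run_scenario(scenario = tibble::tibble(code = code, pu_size = pu_size,
                                           level = level, cost = cost),
                 features = features[[paste0(pu_size, level)]],
                 costs = costs[[pu_size]], R = R,
                 scenario_seed = str_seed(experiment_seed, code),
                 schedule = schedule, prop = prop, criterion = criterion,
                 R_cal = R_cal)
  })
  names(results) <- scenarios$code
  structure(list(reefscape = reefscape, grid = grid, features = features,
                 costs = costs, fishers = fishers, results = results,
                 R = as.integer(R), experiment_seed = experiment_seed),
            class = "reef_experiment")
}

#' @export
print.reef_experiment <- function(x, ...) {
  cat("<reef_experiment> ", length(x$results), " scenarios x ", x$R,
      " replicates on a ", x$reefscape$n_rows, "x", x$reefscape$n_cols,
      " reefscape\n", sep = "")
  invisible(x)
}

#' Per-replicate extent and cost across scenarios
#'
#' @param experiment A [run_experiment()] result (or list of
#'   `scenario_result`).
#' @return Tibble: `code`, `pu_size`, `level`, `cost`, `replicate`,
#'   `extent_km2`, `cost_proportion`, `min_prop`.
#' @export
per_solution_table <- function(experiment) {
  results <- if (inherits(experiment, "reef_experiment")) experiment$results
             else experiment
  purrr::map_dfr(results, function(res) {
    dplyr::mutate(res$per_solution, code = res$scenario$code,
                  pu_size = res$scenario$pu_size, level = res$scenario$level,
                  cost = res$scenario$cost, .before = 1)
  })
}

#' Summarise reserve extent and cost proportion by scenario
#'
#' Five-number summaries (min, lower quartile, median, upper quartile, max)
#' of solution extent and cost proportion per scenario, the tabular analogue
#' of per-scenario boxplots.
#'
#' @inheritParams per_solution_table
#' @return Tibble with one row per scenario and metric.
#' @export
summarize_extent_cost <- function(experiment) {
  per_solution_table(experiment) |>
    tidyr::pivot_longer(c("extent_km2", "cost_proportion"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$code, .data$pu_size, .data$level, .data$cost,
                    .data$metric) |>
    dplyr::summarise(min = min(.data$value),
                     q1 = quantile(.data$value, 0.25, names = FALSE),
                     median = median(.data$value),
                     q3 = quantile(.data$value, 0.75, names = FALSE),
                     max = max(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$metric, .data$pu_size, .data$level, .data$cost)
}
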