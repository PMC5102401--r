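#' Build a minimum-set reserve-selection problem
#'
#' The objective is Marxan's minimum-set form: select planning units meeting
#' a representation target for every feature (reef class) at least total
#' cost. Targets are `prop` times each feature's total amount; unmet targets
#' incur a penalty `spf_f * shortfall_f / target_f` (normalised shortfall,
#' scale-free across thematic levels).
#'
#' @param features Tibble with `pu_id`, `class_id`, `amount_km2` (one
#'   thematic level of a feature table).
#' @param costs Tibble with `pu_id` and `cost` (> 0) for every unit in
#'   `features` (units may also appear only in `costs`).
#' @param reef_area Optional tibble `pu_id`, `reef_area_km2` used to report
#'   solution extents; defaults to `costs$cost` (exact under uniform cost).
#' @param prop Proportion of each feature's total to protect (default 0.30).
#' @param spf Species penalty factor: scalar or per-feature vector; default
#'   mean unit cost.
#' @return A `reef_problem` object.
#' @export
make_problem <- function(features, costs, reef_area = NULL, prop = 0.3,
                         spf = NULL) {
  stopifnot(prop > 0, prop <= 1, all(costs$cost > 0), nrow(features) > 0)
  pu_ids <- sort(unique(costs$pu_id))
  if (!all(features$pu_id %in% pu_ids))
    abort("features reference planning units missing from the cost table")
  feat_ids <- sort(unique(features$class_id))
  totals <- features |>
    dplyr::group_by(.data$class_id) |>
    dplyr::summarise(total = sum(.data$amount_km2), .groups = "drop") |>
    dplyr::arrange(.data$class_id)
  if (any(totals$total <= 0)) abort("every feature must have positive total amount")

  f <- features |>
    dplyr::mutate(pu_idx = match(.data$pu_id, pu_ids),
                  feat_idx = match(.data$class_id, feat_ids)) |>
    dplyr::arrange(.data$pu_idx, .data$feat_idx)
  # CSC-by-unit layout for the compiled solver
  cnt <- tabulate(f$pu_idx, nbins = length(pu_ids))
  pu_ptr <- c(0L, cumsum(cnt))

  cost <- costs$cost[match(pu_ids, costs$pu_id)]
  area <- if (is.null(reef_area)) cost
          else reef_area$reef_area_km2[match(pu_ids, reef_area$pu_id)]
  target <- prop * totals$total
  spf <- if (is.null(spf)) rep(mean(cost), length(feat_ids))
         else rep(spf, length.out = length(feat_ids))
  stopifnot(all(spf >= 0))
  structure(list(pu_ids = pu_ids, cost = cost, reef_area = area,
                 feature_ids = feat_ids, totals = totals$total,
                 target = target, prop = prop, spf = spf,
                 pu_ptr = pu_ptr,
                 feat_idx = as.integer(f$feat_idx - 1L),
                 amount = f$amount_km2),
            class = "reef_problem")
}

#' @export
print.reef_problem <- function(x, ...) {
  cat("<reef_problem> ", length(x$pu_ids), " units, ", length(x$feature_ids),
      " features, targets = ", x$prop, " x totals\n", sep = "")
  invisible(x)
}

representation_of <- function(problem, sel_logical) {
  rep_f <- numeric(length(problem$feature_ids))
  idx <- which(sel_logical)
  for (i in idx) {
    k <- (problem$pu_ptr[i] + 1L):problem$pu_ptr[i + 1L]
    if (problem$pu_ptr[i] < problem$pu_ptr[i + 1L]) {
      ff <- problem$feat_idx[k] + 1L
      rep_f[ff] <- rep_f[ff] + problem$amount[k]
    }
  }
  rep_f
}

#' Minimum-set objective of a candidate selection
#'
#' `sum of selected costs + sum_f spf_f * shortfall_f / target_f`; a
#' selection meeting every target scores exactly its cost.
#'
#' @param problem A [make_problem()] result.
#' @param selected Vector of selected `pu_id`s.
#' @return The objective value (scalar).
#' @export
objective <- function(problem, selected) {
  stopifnot(inherits(problem, "reef_problem"))
  if (!all(selected %in% problem$pu_ids))
    abort("selected contains unknown planning units")
  sel <- problem$pu_ids %in% selected
  rep_f <- representation_of(problem, sel)
  shortfall <- pmax(0, problem$target - rep_f)
  sum(problem$cost[sel]) + sum(problem$spf * shortfall / problem$target)
}

new_solution <- function(problem, sel_logical, objective_value, seed) {
  rep_f <- representation_of(problem, sel_logical)
  structure(list(
    selected = problem$pu_ids[sel_logical],
    total_cost = sum(problem$cost[sel_logical]),
    total_extent_km2 = sum(problem$reef_area[sel_logical]),
    representation = tibble::tibble(
      class_id = problem$feature_ids, amount = rep_f,
      target = problem$target,
      proportion = rep_f / problem$target),
    shortfall = pmax(0, problem$target - rep_f),
    objective_value = objective_value,
    seed = seed), class = "reef_solution")
}

#' @export
print.reef_solution <- function(x, ...) {
  cat("<reef_solution> ", length(x$selected), " units, cost ",
      signif(x$total_cost, 5), ", extent ", signif(x$total_extent_km2, 5),
      " km2, min target proportion ",
      signif(min(x$representation$proportion), 4), "\n", sep = "")
  invisible(x)
}

#' Annealing schedule
#'
#' Geometric cooling from `t_initial` to `t_final` over `n_iterations`
#' single-unit flips, followed by strict-descent iterative-improvement
#' sweeps in seeded random order.
#'
#' @param n_iterations Number of annealing iterations (default 1e5).
#' @param t_initial,t_final Initial/final temperature; `NULL` scales them to
#'   the mean unit cost of the problem at solve time.
#' @param improvement_passes Maximum improvement sweeps (default 50).
#' @return An `anneal_schedule` list.
#' @export
anneal_schedule <- function(n_iterations = 1e5, t_initial = NULL,
                            t_final = NULL, improvement_passes = 50) {
  stopifnot(n_iterations >= 1, improvement_passes >= 1)
  if (!is.null(t_initial) && !is.null(t_final))
    stopifnot(t_initial >= t_final, t_final > 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 t_initial = t_initial, t_final = t_final,
                 improvement_passes = as.integer(improvement_passes)),
            class = "anneal_schedule")
}

#' Solve a reserve-selection problem by simulated annealing
#'
#' Starts from a random selection (each unit with probability 0.5), proposes
#' uniformly-random single-unit flips, accepts improving moves always and
#' worsening moves with probability `exp(-delta / T)` under geometric
#' cooling, then applies iterative improvement. Deterministic given `seed`.
#'
#' @param problem A [make_problem()] result.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed for the solver's own RNG.
#' @return A `reef_solution`.
#' @export
anneal <- function(problem, schedule = anneal_schedule(), seed = 1L) {
  stopifnot(inherits(problem, "reef_problem"))
  t0 <- schedule$t_initial %||% (10 * mean(problem$cost))
  t1 <- schedule$t_final %||% (1e-5 * mean(problem$cost))
  res <- anneal_cpp(problem$cost, problem$pu_ptr, problem$feat_idx,
                    problem$amount, problem$target, problem$spf,
                    schedule$n_iterations, t0, t1,
                    schedule$improvement_passes, 0.5, as.numeric(seed))
  new_solution(problem, res$selected, res$objective, seed)
}

#' Exhaustive optimum of a small problem
#'
#' Enumerates all subsets (refused above 20 units); ties broken toward fewer
#' units, then lexicographically smaller id sets. Intended as a test oracle.
#'
#' @inheritParams anneal
#' @return A `reef_solution` with the global minimum objective.
#' @export
brute_force_optimum <- function(problem) {
  stopifnot(inherits(problem, "reef_problem"))
  if (length(problem$pu_ids) > 20)
    abort("brute_force_optimum refuses problems with more than 20 units")
  res <- brute_force_cpp(problem$cost, problem$pu_ptr, problem$feat_idx,
                         problem$amount, problem$target, problem$spf)
  new_solution(problem, res$selected, res$objective, NA_integer_)
}

#' Replicate solutions and selection frequency
#'
#' Runs `R` annealing replicates with seeds `base_seed + 1 .. base_seed + R`
#' and tallies how often each unit is selected (its selection frequency, a
#' proxy for irreplaceability).
#'
#' @inheritParams anneal
#' @param R Number of replicates.
#' @param base_seed Integer; replicate r uses seed `base_seed + r`.
#' @return List with `solutions` (list of `reef_solution`) and `frequency`
#'   (tibble `pu_id`, `freq` with attribute `R`).
#' @export
run_replicates <- function(problem, R = 100, base_seed = 0L,
                           schedule = anneal_schedule()) {
  stopifnot(R >= 1)
  sols <- purrr::map(seq_len(R), \(r) anneal(problem, schedule, base_seed + r))
  freq <- integer(length(problem$pu_ids))
  for (s in sols) freq[match(s$selected, problem$pu_ids)] <-
    freq[match(s$selected, problem$pu_ids)] + 1L
  frequency <- tibble::tibble(pu_id = problem$pu_ids, freq = freq)
  attr(frequency, "R") <- as.integer(R)
  list(solutions = sols, frequency = frequency)
}

min_proportion <- function(solutions) {
  min(vapply(solutions, \(s) min(s$representation$proportion), numeric(1)))
}

#' Calibrate species penalty factors
#'
#' Starting from `spf = mean unit cost` for every feature, runs `R_cal`
#' replicates and doubles the penalty factor of any feature whose minimum
#' achieved proportion of target over the replicates is at or below
#' `criterion` (default 0.999, the conventional "minimum proportion met").
#' Stops when all features exceed the criterion in all replicates, or fails
#' loudly after `max_rounds`.
#'
#' @inheritParams anneal
#' @param R_cal Replicates per calibration round.
#' @param criterion Required minimum achieved proportion (in (0, 1]).
#' @param base_seed Seed for calibration replicates.
#' @param max_rounds Doubling cap (default 50).
#' @return The problem with calibrated `spf`, with attribute `rounds`.
#' @export
calibrate_spf <- function(problem, R_cal = 10, criterion = 0.999,
                          base_seed = 0L, schedule = anneal_schedule(),
                          max_rounds = 50) {
  stopifnot(criterion > 0, criterion <= 1)
  problem$spf <- rep(mean(problem$cost), length(problem$feature_ids))
  for (round in seq_len(max_rounds)) {
    reps <- run_replicates(problem, R_cal, base_seed + (round - 1L) * R_cal,
                           schedule)
    min_prop <- purrr::reduce(
      purrr::map(reps$solutions, \(s) s$representation$proportion), pmin)
    failing <- min_prop <= criterion
    if (!any(failing)) {
      attr(problem, "rounds") <- round
      return(problem)
    }
    problem$spf[failing] <- problem$spf[failing] * 2
  }
  abort(paste0("SPF calibration did not reach criterion ", criterion,
               " within ", max_rounds, " rounds for features: ",
               paste(problem$feature_ids[failing], collapse = ", ")))
}
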