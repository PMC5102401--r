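test_that("objective: empty, saturated, and hand-computed selections", {
  pr <- three_unit_problem(target_amount = 9, spf = 1)
  expect_equal(objective(pr, integer(0)), 1)          # full normalised shortfall
  expect_equal(objective(pr, 1:3), 6)                 # all units: cost only
  expect_equal(objective(pr, 1L), 1)                  # unit 1 covers T = 9
  # monotone penalty: raising any spf never decreases a fixed selection's score
  pr_hi <- pr
  for (sel in list(integer(0), 1L, 3L, c(1L, 3L))) {
    pr_hi$spf <- pr$spf * 7
    expect_gte(objective(pr_hi, sel), objective(pr, sel))
  }
})

test_that("brute force finds hand-enumerable optima with stated tie-breaks", {
  # two units, either alone meets the target: pick the cheaper
  feats <- tibble::tibble(pu_id = c(1L, 2L), class_id = 1L,
                          amount_km2 = c(10, 10))
  costs <- tibble::tibble(pu_id = 1:2, cost = c(1, 5))
  pr <- make_problem(feats, costs, prop = 0.3, spf = 100)
  sol <- brute_force_optimum(pr)
  expect_equal(sol$selected, 1L)
  expect_equal(sol$objective_value, 1)
  # three-unit toy with T = 25 forces units 1 and 3, score 4
  pr3 <- three_unit_problem(target_amount = 25, spf = 100)
  sol3 <- brute_force_optimum(pr3)
  expect_equal(sol3$selected, c(1L, 3L))
  expect_equal(sol3$objective_value, 4)
  expect_error(brute_force_optimum(make_toy_problem(21, 3, seed = 1)),
               "refuses")
})

test_that("annealing solves forced problems and is deterministic", {
  feats <- tibble::tibble(pu_id = 1L, class_id = 1L, amount_km2 = 10)
  costs <- tibble::tibble(pu_id = 1L, cost = 1)
  pr <- make_problem(feats, costs, prop = 0.3, spf = 100)
  sol <- anneal(pr, anneal_schedule(1000), seed = 3)
  expect_equal(sol$selected, 1L)
  expect_equal(sol$objective_value, 1)
  pr18 <- make_toy_problem(18, 5, seed = 42)
  s1 <- anneal(pr18, anneal_schedule(5000), seed = 9)
  s2 <- anneal(pr18, anneal_schedule(5000), seed = 9)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$objective_value, s2$objective_value)
})

test_that("oracle is never beaten and is single-flip locally optimal", {
  for (seed in 1:10) {
    pr <- make_toy_problem(sample(10:15, 1), sample(3:5, 1), seed = seed)
    opt <- brute_force_optimum(pr)
    an <- anneal(pr, anneal_schedule(5000), seed = seed)
    expect_gte(an$objective_value, opt$objective_value - 1e-9)
    # no single flip improves the global optimum
    base <- objective(pr, opt$selected)
    for (u in pr$pu_ids) {
      flipped <- if (u %in% opt$selected) setdiff(opt$selected, u)
                 else c(opt$selected, u)
      expect_gte(objective(pr, flipped), base - 1e-9)
    }
  }
})

test_that("zero-temperature annealing reduces to strict descent", {
  pr <- make_toy_problem(15, 4, seed = 5)
  sch <- anneal_schedule(5000, t_initial = 1e-12, t_final = 1e-12)
  sol <- anneal(pr, sch, seed = 2)
  # a strict-descent run ends in a single-flip local optimum
  base <- sol$objective_value
  for (u in pr$pu_ids) {
    flipped <- if (u %in% sol$selected) setdiff(sol$selected, u)
               else c(sol$selected, u)
    expect_gte(objective(pr, flipped), base - 1e-9)
  }
})

test_that("replicates tally selection frequency correctly", {
  pr <- make_toy_problem(12, 3, seed = 8)
  one <- run_replicates(pr, R = 1, base_seed = 5, anneal_schedule(2000))
  ind <- as.integer(pr$pu_ids %in% one$solutions[[1]]$selected)
  expect_equal(one$frequency$freq, ind)
  # forced single-unit problem: frequency R in all replicates
  feats <- tibble::tibble(pu_id = 1L, class_id = 1L, amount_km2 = 10)
  pr1 <- make_problem(feats, tibble::tibble(pu_id = 1L, cost = 1),
                      prop = 0.3, spf = 100)
  reps <- run_replicates(pr1, R = 50, base_seed = 0, anneal_schedule(500))
  expect_equal(reps$frequency$freq, 50L)
  expect_equal(attr(reps$frequency, "R"), 50L)
})

test_that("replicate frequencies track oracle-enumerated importance", {
  pr <- make_toy_problem(14, 4, seed = 21)
  opt <- brute_force_optimum(pr)
  reps <- run_replicates(pr, R = 50, base_seed = 100, anneal_schedule(2e4))
  freq <- reps$frequency
  in_opt <- freq$freq[freq$pu_id %in% opt$selected]
  out_opt <- freq$freq[!freq$pu_id %in% opt$selected]
  if (length(in_opt) > 0 && length(out_opt) > 0)
    expect_gte(min(in_opt), max(0, max(out_opt) - 50 * 0.5))
  expect_true(all(freq$freq >= 0 & freq$freq <= 50))
})

test_that("SPF calibration reaches the criterion and analytic thresholds", {
  # already satisfiable at the initial spf: returned unchanged
  feats <- tibble::tibble(pu_id = 1L, class_id = 1L, amount_km2 = 10)
  pr1 <- make_problem(feats, tibble::tibble(pu_id = 1:2, cost = c(1, 3)),
                      prop = 0.3)
  cal1 <- calibrate_spf(pr1, R_cal = 3, schedule = anneal_schedule(500))
  expect_equal(cal1$spf, pr1$spf)      # initial spf = mean cost, unchanged
  expect_equal(attr(cal1, "rounds"), 1)
  # the needed unit costs 10; spf must grow past it before selection pays
  feats2 <- tibble::tibble(pu_id = 1L, class_id = 1L, amount_km2 = 5)
  costs2 <- tibble::tibble(pu_id = 1:2, cost = c(10, 0.1))
  pr2 <- make_problem(feats2, costs2, prop = 0.9, spf = NULL)
  cal2 <- calibrate_spf(pr2, R_cal = 5, schedule = anneal_schedule(2000))
  expect_gte(max(cal2$spf), 10)
  reps <- run_replicates(cal2, R = 20, base_seed = 77, anneal_schedule(2000))
  minp <- min(purrr::map_dbl(reps$solutions,
                             \(s) min(s$representation$proportion)))
  expect_gt(minp, 0.999)
})
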