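# Shared fixtures and independent oracles for the suite. Heavy objects are
# built once per session and memoised in this environment.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, .fixtures)) assign(key, builder(), .fixtures)
  get(key, .fixtures)
}

# small seeded reefscape used by unit tests
tiny_reefscape <- function(seed = 7, rows = 50, cols = 50,
                           classes = c(2, 4, 8, 12, 20), frac = 0.5) {
  generate_reefscape(reefscape_config(
    grid_rows = rows, grid_cols = cols, reef_fraction_target = frac,
    n_patches = 3, classes_per_level = classes, seed = seed))
}

# fully-reef single-class reefscape: every structural quantity is exact
full_reefscape <- function(rows = 50, cols = 50,
                           classes = c(1, 1, 1, 1, 1)) {
  generate_reefscape(reefscape_config(
    grid_rows = rows, grid_cols = cols, reef_fraction_target = 1,
    n_patches = 1, classes_per_level = classes, level4_sharing = 0,
    seed = 1))
}

# random minimum-set toy with a handful of features; spf large so targets bind
make_toy_problem <- function(n, m, seed, spf = 100) {
  set.seed(seed)
  feats <- purrr::map_dfr(seq_len(m), function(f) {
    k <- sample(2:max(2, n %/% 2), 1)
    tibble::tibble(pu_id = sample.int(n, k), class_id = f,
                   amount_km2 = runif(k, 0.1, 2))
  })
  costs <- tibble::tibble(pu_id = seq_len(n), cost = runif(n, 0.5, 2))
  make_problem(feats, costs, prop = 0.3, spf = spf)
}

# the three-unit worked problem used across solver tests:
# costs 1,2,3; one feature with amounts 10, 0, 20
three_unit_problem <- function(target_amount, spf = 1) {
  feats <- tibble::tibble(pu_id = c(1L, 3L), class_id = 1L,
                          amount_km2 = c(10, 20))
  costs <- tibble::tibble(pu_id = 1:3, cost = c(1, 2, 3))
  pr <- make_problem(feats, costs, prop = target_amount / 30, spf = spf)
  pr
}

# desk-scale factorial experiments (the study conditions); memoised because
# three full runs back several acceptance checks
desk_experiment <- function(k) {
  memo(paste0("experiment_", k), function() {
    rs <- generate_reefscape(reefscape_config(
      grid_rows = 150, grid_cols = 150, reef_fraction_target = 0.55,
      n_patches = 4, classes_per_level = c(2, 4, 8, 12, 20), seed = 6 + k))
    run_experiment(rs, R = 100, experiment_seed = 40 + k,
                   schedule = anneal_schedule(1e4))
  })
}

# -- independent oracles ----------------------------------------------------

naive_euclidean <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((m[i, ] - m[j, ])^2))
  d
}

# O(n^3) UPGMA with lowest-pair-index tie-break; returns merge heights and
# the cophenetic distance matrix
naive_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  active <- seq_len(n)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (ii >= jj) next
      a <- active[ii]; b <- active[jj]
      ma <- members[[a]]; mb <- members[[b]]
      h <- mean(d[ma, mb])
      if (h < bh - 1e-12) { bh <- h; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    for (x in members[[a]]) for (y in members[[b]]) {
      coph[x, y] <- bh; coph[y, x] <- bh
    }
    heights <- c(heights, bh)
    members[[a]] <- c(members[[a]], members[[b]])
    active <- setdiff(active, b)
  }
  list(heights = heights, cophenetic = coph)
}
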