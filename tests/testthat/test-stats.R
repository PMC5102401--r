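test_that("broadcasting to small units follows the frequency rule", {
  nesting <- tibble::tibble(large_id = c(1L, 1L, 1L, 2L, 2L),
                            small_id = c(10L, 11L, 12L, 20L, 21L))
  out <- rasterize_to_small(tibble::tibble(pu_id = 1L, value = 50),
                            nesting, "L")
  expect_equal(out$value[out$pu_id %in% 10:12], rep(50, 3))
  expect_equal(out$value[out$pu_id %in% 20:21], rep(0, 2))
  # binary selection broadcasts too
  out2 <- rasterize_to_small(tibble::tibble(pu_id = 2L, value = 1),
                             nesting, "L")
  expect_equal(sum(out2$value), 2)
  # small rows pass through as the identity
  sm <- tibble::tibble(pu_id = c(10L, 20L), value = c(3, 4))
  out3 <- rasterize_to_small(sm, nesting, "S")
  expect_equal(out3$value[match(c(10L, 20L), out3$pu_id)], c(3, 4))
  expect_error(rasterize_to_small(tibble::tibble(pu_id = 99L, value = 1),
                                  nesting, "S"), "not in the grid")
  expect_error(rasterize_to_small(tibble::tibble(pu_id = 99L, value = 1),
                                  nesting, "L"), "not in the nesting")
})

test_that("Hellinger transform normalises rows and rejects bad input", {
  expect_equal(hellinger(rbind(c(1, 0, 0)))[1, ], c(1, 0, 0))
  expect_equal(hellinger(rbind(c(1, 1, 1, 1)))[1, ], rep(0.5, 4))
  set.seed(4)
  m <- matrix(rpois(200, 3), 20, 10)
  m[1, ] <- c(5, rep(0, 9))              # keep rows non-zero
  H <- hellinger(m)
  expect_lt(max(abs(rowSums(H^2) - 1)), 1e-12)
  expect_error(hellinger(rbind(c(0, 0))), "all-zero")
  expect_error(hellinger(rbind(c(-1, 2))), "non-negative")
  skip_if_not_installed("vegan")
  expect_equal(H, vegan::decostand(m, "hellinger"), ignore_attr = TRUE)
})

test_that("Euclidean distances match a naive oracle and the sqrt(2) bound", {
  set.seed(11)
  m <- matrix(runif(60), 10, 6)
  d <- as.matrix(euclidean_distance(m))
  expect_equal(d, naive_euclidean(m), ignore_attr = TRUE)
  expect_equal(diag(d), rep(0, 10), ignore_attr = TRUE)
  expect_equal(d, t(d))
  # identical rows at distance zero; orthogonal presence rows at sqrt(2)
  m2 <- rbind(c(1, 0, 0), c(1, 0, 0), c(0, 1, 0))
  d2 <- as.matrix(euclidean_distance(m2))
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 3], sqrt(2))
  # Hellinger rows of presence/absence data are bounded by sqrt(2)
  pa <- matrix(rbinom(300, 1, 0.3), 30, 10)
  pa[rowSums(pa) == 0, 1] <- 1
  dh <- euclidean_distance(hellinger(pa))
  expect_lte(max(dh), sqrt(2) + 1e-12)
})

test_that("UPGMA matches hand cases and a naive O(n^3) oracle", {
  # two points: single merge at their distance
  d2 <- dist(c(0, 3))
  t2 <- average_linkage_cluster(d2)
  expect_equal(t2$height, 3)
  # three points: {1,2} at 1, then {12,3} at 5
  d3 <- structure(c(1, 5, 5), Size = 3L, class = "dist")
  t3 <- average_linkage_cluster(d3)
  expect_equal(t3$height, c(1, 5))
  expect_false(is.unsorted(t3$height))
  # random 15-point oracle comparison: heights and cophenetic distances
  set.seed(30)
  m <- matrix(rnorm(15 * 4), 15, 4)
  d <- dist(m)
  tr <- average_linkage_cluster(d)
  oracle <- naive_upgma(d)
  expect_equal(sort(tr$height), sort(oracle$heights))
  expect_equal(as.matrix(stats::cophenetic(tr)), oracle$cophenetic,
               ignore_attr = TRUE)
})

balanced_labels <- function(reps = 2) {
  tidyr::expand_grid(cost = c("U", "V"), pu_size = c("S", "L"),
                     level = 1:5, rep = seq_len(reps))
}

test_that("RDA recovers perfectly explained and hand-computable variance", {
  lab <- balanced_labels(2)
  # response depends only on the factors: residual variance must vanish
  mu <- as.numeric(factor(lab$cost)) * 2 + as.numeric(factor(lab$pu_size)) +
    lab$level * 0.5
  Y <- cbind(mu, -mu, mu * 0.1)
  r <- rda_factors(Y, lab)
  expect_equal(r$residual_variance, 0, tolerance = 1e-10)
  expect_equal(r$proportion_axes12, 1, tolerance = 1e-12)
  # constrained variance equals between-group variance of the centred rows
  set.seed(8)
  Y2 <- Y + matrix(rnorm(length(Y), sd = 0.3), nrow(Y))
  r2 <- rda_factors(Y2, lab)
  # balanced factorial: factor spaces are orthogonal, so the constrained
  # variance is the sum of the per-factor between-group variances
  Yc <- scale(Y2, center = TRUE, scale = FALSE)
  between_for <- function(g)
    sum((rowsum(Yc, g) / as.vector(table(g)))[g, ]^2) / (nrow(Y2) - 1)
  between <- between_for(lab$cost) + between_for(lab$pu_size) +
    between_for(factor(lab$level))
  expect_equal(r2$constrained_variance, between, tolerance = 1e-9)
  # partition: constrained + residual = total
  expect_equal(r2$constrained_variance + r2$residual_variance,
               r2$total_variance, tolerance = 1e-9)
})

test_that("RDA agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(17)
  lab <- balanced_labels(3)
  Y <- matrix(rnorm(nrow(lab) * 8), nrow(lab), 8) +
    outer(lab$level, 1:8, \(a, b) 0.2 * a * (b < 4))
  r <- rda_factors(Y, lab)
  lf <- dplyr::mutate(lab, cost = factor(cost), pu_size = factor(pu_size),
                      level = factor(level))
  vr <- vegan::rda(Y ~ cost + pu_size + level, data = lf)
  expect_equal(r$constrained_variance, unname(vr$CCA$tot.chi),
               tolerance = 1e-10)
  expect_equal(r$eigenvalues, unname(vr$CCA$eig[seq_along(r$eigenvalues)]),
               tolerance = 1e-9)
  expect_equal(r$residual_variance, unname(vr$CA$tot.chi), tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the aliased terms", {
  lab <- balanced_labels(1)
  lab$pu_size <- lab$cost          # size aliased with cost
  Y <- matrix(rnorm(nrow(lab) * 3), nrow(lab), 3)
  expect_error(rda_factors(Y, lab), "aliased")
})

test_that("permutation test reports Table-style df and honours its floor", {
  set.seed(3)
  lab <- balanced_labels(2)
  Y <- matrix(rnorm(nrow(lab) * 6), nrow(lab), 6)
  pt <- permutation_test(Y, lab, n_perm = 99, seed = 12)
  expect_equal(pt$term, c("cost", "size", "level"))
  expect_equal(pt$df, c(1L, 1L, 4L))
  expect_true(all(pt$p.value >= 1 / 100))
  expect_true(all(pt$p.value <= 1))
  # deterministic given the seed
  pt2 <- permutation_test(Y, lab, n_perm = 99, seed = 12)
  expect_identical(pt$p.value, pt2$p.value)
  # a strong real effect is detected at the floor
  Y3 <- Y + outer(as.numeric(factor(lab$cost)), rep(1, 6)) * 3
  pt3 <- permutation_test(Y3, lab, n_perm = 199, seed = 5)
  expect_equal(pt3$p.value[1], 1 / 200)
})

test_that("solution matrices stack scenarios at small-unit resolution", {
  ex_small <- local({
    rs <- tiny_reefscape(seed = 13, rows = 25, cols = 25, frac = 0.6)
    run_experiment(rs, R = 3, experiment_seed = 5,
                   schedule = anneal_schedule(2000))
  })
  sm <- solution_matrix(ex_small, "binary")
  expect_equal(nrow(sm$matrix), 20 * 3)
  expect_true(all(rowSums(sm$matrix) > 0))
  expect_equal(nrow(sm$labels), nrow(sm$matrix))
  smf <- solution_matrix(ex_small, "frequency")
  expect_equal(nrow(smf$matrix), 20)
  expect_true(all(smf$matrix >= 0 & smf$matrix <= 3))
  expect_identical(colnames(sm$matrix), colnames(smf$matrix))
})
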