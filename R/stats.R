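#' Broadcast planning-unit values to small-unit resolution
#'
#' Solutions and selection frequencies from large-unit scenarios are
#' compared with small-unit scenarios at small-unit resolution: each large
#' unit's value is broadcast to its (up to 25) component small units, e.g. a
#' large unit with selection frequency 50 yields a value of 50 for every
#' nested small unit. Small-unit input passes through unchanged.
#'
#' @param values Tibble with `pu_id` and `value`.
#' @param nesting Nesting map tibble (`large_id`, `small_id`) from
#'   [build_grids()].
#' @param size_class "S" (identity) or "L" (broadcast).
#' @param small_ids All small-unit ids defining the output column set;
#'   defaults to those in `nesting`. Units not mentioned get value 0.
#' @return Tibble `pu_id` (small), `value`, one row per small unit.
#' @export
rasterize_to_small <- function(values, nesting, size_class = "S",
                               small_ids = sort(unique(nesting$small_id))) {
  stopifnot(size_class %in% c("S", "L"))
  if (size_class == "S") {
    orphan <- setdiff(values$pu_id, small_ids)
    if (length(orphan) > 0)
      abort(paste0("small units not in the grid: ",
                   paste(head(orphan, 5), collapse = ", ")))
    out <- tibble::tibble(pu_id = small_ids,
                          value = values$value[match(small_ids, values$pu_id)])
  } else {
    orphan <- setdiff(values$pu_id, nesting$large_id)
    if (length(orphan) > 0)
      abort(paste0("large units not in the nesting map: ",
                   paste(head(orphan, 5), collapse = ", ")))
    expanded <- nesting |>
      dplyr::inner_join(values, by = c(large_id = "pu_id"))
    out <- tibble::tibble(
      pu_id = small_ids,
      value = expanded$value[match(small_ids, expanded$small_id)])
  }
  out$value[is.na(out$value)] <- 0
  out
}

#' Compile solutions into a community-style matrix
#'
#' Treats solutions as sampling "sites" and small planning units as
#' "species": `type = "binary"` stacks all individual solutions (R per
#' scenario; selected = 1) and `type = "frequency"` stacks one
#' selection-frequency row per scenario (0..R). Large-unit scenarios are
#' rasterised to small units first.
#'
#' @param experiment A [run_experiment()] result.
#' @param type "binary" or "frequency".
#' @return A `solution_matrix`: list with `matrix` (rows = solutions or
#'   scenarios, columns = small units) and `labels` tibble (`code`,
#'   `pu_size`, `level`, `cost`, and `replicate` for binary).
#' @export
solution_matrix <- function(experiment, type = c("binary", "frequency")) {
  type <- match.arg(type)
  nesting <- experiment$grid$nesting
  small_ids <- sort(unique(nesting$small_id))
  rows <- list(); labels <- list()
  for (res in experiment$results) {
    sc <- res$scenario
    if (type == "frequency") {
      v <- rasterize_to_small(
        dplyr::rename(res$frequency, value = "freq"), nesting, sc$pu_size,
        small_ids)
      rows[[length(rows) + 1L]] <- v$value
      labels[[length(labels) + 1L]] <-
        dplyr::mutate(sc, replicate = NA_integer_)
    } else {
      for (r in seq_along(res$solutions)) {
        sel <- res$solutions[[r]]$selected
        v <- rasterize_to_small(
          tibble::tibble(pu_id = sel, value = 1), nesting, sc$pu_size,
          small_ids)
        rows[[length(rows) + 1L]] <- v$value
        labels[[length(labels) + 1L]] <- dplyr::mutate(sc, replicate = r)
      }
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("pu", small_ids)
  labels <- dplyr::bind_rows(labels)
  rownames(m) <- if (type == "frequency") labels$code
                 else paste0(labels$code, "_", labels$replicate)
  structure(list(matrix = m, labels = labels, type = type),
            class = "solution_matrix")
}

#' @export
print.solution_matrix <- function(x, ...) {
  cat("<solution_matrix> ", nrow(x$matrix), " ", x$type, " rows x ",
      ncol(x$matrix), " small planning units\n", sep = "")
  invisible(x)
}

#' Hellinger transformation
#'
#' Row-wise square root of relative abundance: `y_ij' = sqrt(y_ij / y_i+)`.
#' Each transformed row has unit Euclidean norm, making Euclidean distance
#' appropriate for sparse presence/absence or frequency matrices.
#'
#' @param m Non-negative numeric matrix (or `solution_matrix`) with no
#'   all-zero rows.
#' @return Transformed matrix of the same shape.
#' @export
hellinger <- function(m) {
  if (inherits(m, "solution_matrix")) m <- m$matrix
  m <- as.matrix(m)
  if (any(m < 0)) abort("Hellinger transformation requires non-negative entries")
  rs <- rowSums(m)
  if (any(rs == 0)) abort("all-zero rows cannot be Hellinger-transformed")
  sqrt(sweep(m, 1, rs, "/"))
}

#' Euclidean dissimilarity between rows
#'
#' @param m Numeric matrix (typically Hellinger-transformed).
#' @return A `dist` object (zero diagonal, symmetric).
#' @export
euclidean_distance <- function(m) {
  if (inherits(m, "solution_matrix")) m <- m$matrix
  dist(as.matrix(m), method = "euclidean")
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' @param d A `dist` object.
#' @return An `hclust` tree with non-decreasing merge heights.
#' @export
average_linkage_cluster <- function(d) {
  stopifnot(inherits(d, "dist"))
  hclust(d, method = "average")
}

# nested sequential design matrices for cost, size, level (Table-5 order);
# returns orthonormal bases Q_j of the cumulative column spaces
sequential_design <- function(labels) {
  labels <- dplyr::mutate(labels,
                          cost = factor(.data$cost),
                          pu_size = factor(.data$pu_size),
                          level = factor(.data$level))
  terms <- list(cost = ~cost, size = ~ cost + pu_size,
                level = ~ cost + pu_size + level)
  X_full <- stats::model.matrix(~ cost + pu_size + level, labels)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    aliased <- colnames(X_full)[qr_full$pivot[-seq_len(qr_full$rank)]]
    abort(paste0("rank-deficient design; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }
  Qs <- purrr::map(terms, function(f) {
    X <- stats::model.matrix(f, labels)
    qr.Q(qr(X))[, seq_len(qr(X)$rank), drop = FALSE]
  })
  dfs <- c(cost = nlevels(labels$cost) - 1L,
           size = nlevels(labels$pu_size) - 1L,
           level = nlevels(labels$level) - 1L)
  list(Q = Qs, df = dfs, n = nrow(labels))
}

#' Redundancy analysis constrained by the prioritisation factors
#'
#' Constrained ordination: the (column-centred) response matrix is regressed
#' on the dummy-coded factors cost variability, planning-unit size and
#' thematic resolution; the fitted values are eigen-decomposed. Reports
#' constrained eigenvalues, site scores (linear-combination and
#' weighted-average flavours), factor-level centroids, sequentially
#' partitioned per-factor variance, and the proportion of constrained
#' variance on the first two axes.
#'
#' @param m Numeric matrix, typically [hellinger()]-transformed, or a
#'   `solution_matrix` (transformed internally is NOT assumed).
#' @param labels Tibble with factor columns `cost`, `pu_size`, `level`
#'   aligned with the rows of `m`.
#' @return A `reef_rda` object.
#' @export
rda_factors <- function(m, labels) {
  if (inherits(m, "solution_matrix")) {
    labels <- m$labels
    m <- m$matrix
  }
  m <- as.matrix(m)
  stopifnot(nrow(m) == nrow(labels))
  des <- sequential_design(labels)
  n <- nrow(m)
  Y <- scale(m, center = TRUE, scale = FALSE)
  Q <- des$Q$level                       # full-model basis
  fitted <- Q %*% crossprod(Q, Y)
  eig <- eigen(crossprod(fitted) / (n - 1), symmetric = TRUE)
  rank <- sum(eig$values > max(eig$values) * 1e-10)
  lambda <- eig$values[seq_len(rank)]
  V <- eig$vectors[, seq_len(rank), drop = FALSE]
  lc <- fitted %*% V
  wa <- Y %*% V
  colnames(lc) <- colnames(wa) <- paste0("RDA", seq_len(rank))

  # sequential variance decomposition in Table-5 row order
  ss <- purrr::map_dbl(des$Q, \(q) sum(crossprod(q, Y)^2))
  ss_term <- c(ss[1], diff(ss))
  names(ss_term) <- names(des$Q)
  total_var <- sum(Y^2) / (n - 1)

  lab_f <- dplyr::mutate(labels, cost = factor(.data$cost),
                         pu_size = factor(.data$pu_size),
                         level = factor(.data$level))
  centroid_tbl <- purrr::map_dfr(c("cost", "pu_size", "level"), function(fac) {
    g <- lab_f[[fac]]
    agg <- rowsum(lc, g) / as.vector(table(g))
    dplyr::bind_cols(tibble::tibble(factor = fac,
                                    level_value = rownames(agg)),
                     tibble::as_tibble(agg))
  })

  structure(list(
    eigenvalues = lambda,
    site_scores = lc, wa_scores = wa,
    centroids = centroid_tbl,
    factor_variance = tibble::tibble(
      term = c("cost", "size", "level"),
      df = unname(des$df),
      variance = unname(ss_term) / (n - 1)),
    constrained_variance = sum(lambda),
    residual_variance = total_var - sum(ss[length(ss)]) / (n - 1),
    total_variance = total_var,
    proportion_axes12 = sum(lambda[seq_len(min(2, rank))]) / sum(lambda),
    labels = labels), class = "reef_rda")
}

#' @export
print.reef_rda <- function(x, ...) {
  cat("<reef_rda> ", length(x$eigenvalues), " constrained axes; axes 1-2 carry ",
      sprintf("%.2f%%", 100 * x$proportion_axes12),
      " of constrained variance\n", sep = "")
  invisible(x)
}

#' @export
tidy.reef_rda <- function(x, ...) {
  tibble::tibble(axis = paste0("RDA", seq_along(x$eigenvalues)),
                 eigenvalue = x$eigenvalues,
                 proportion = x$eigenvalues / sum(x$eigenvalues))
}

#' @export
glance.reef_rda <- function(x, ...) {
  tibble::tibble(constrained_variance = x$constrained_variance,
                 residual_variance = x$residual_variance,
                 total_variance = x$total_variance,
                 proportion_axes12 = x$proportion_axes12,
                 n_axes = length(x$eigenvalues))
}

#' Permutation test on the constrained ordination
#'
#' Sequential (type-I) decomposition in the order cost variability,
#' planning-unit size, thematic resolution. Per term,
#' `F = (SS_term / df_term) / (SS_resid / df_resid)`; significance is
#' assessed by freely permuting the rows of the response matrix, with
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`.
#'
#' @inheritParams rda_factors
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed for the permutations.
#' @return A `reef_permtest` tibble: `term`, `df`, `variance`, `statistic`,
#'   `p.value`, with attributes `n_perm` and `seed`.
#' @export
permutation_test <- function(m, labels, n_perm = 999, seed = 1L) {
  if (inherits(m, "solution_matrix")) {
    labels <- m$labels
    m <- m$matrix
  }
  stopifnot(n_perm >= 99)
  m <- as.matrix(m)
  des <- sequential_design(labels)
  n <- nrow(m)
  Y <- scale(m, center = TRUE, scale = FALSE)
  total_ss <- sum(Y^2)
  df_resid <- n - 1L - sum(des$df)

  f_stats <- function(Yp) {
    ss <- purrr::map_dbl(des$Q, \(q) sum(crossprod(q, Yp)^2))
    ss_term <- c(ss[1], diff(ss))
    ss_res <- sum(Yp^2) - ss[length(ss)]
    (ss_term / des$df) / (ss_res / df_resid)
  }
  obs <- f_stats(Y)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  exceed <- numeric(3)
  for (b in seq_len(n_perm)) {
    Yp <- Y[sample.int(n), , drop = FALSE]
    exceed <- exceed + (f_stats(Yp) >= obs)
  }
  ss <- purrr::map_dbl(des$Q, \(q) sum(crossprod(q, Y)^2))
  ss_term <- c(ss[1], diff(ss))
  out <- tibble::tibble(
    term = c("cost", "size", "level"),
    df = unname(des$df),
    variance = unname(ss_term) / (n - 1),
    statistic = unname(obs),
    p.value = unname((1 + exceed) / (1 + n_perm)))
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "df_resid") <- df_resid
  class(out) <- c("reef_permtest", class(out))
  out
}

#' @export
tidy.reef_permtest <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.reef_permtest <- function(x, ...) {
  tibble::tibble(n_perm = attr(x, "n_perm"), df_resid = attr(x, "df_resid"),
                 seed = attr(x, "seed"))
}
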