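#' Write Marxan-dialect input files
#'
#' Writes `pu.dat` (id, cost, status), `spec.dat` (id, name, prop, spf) and
#' `puvspr.dat` (species, pu, amount; sorted by species then pu) for a
#' problem, so an external Marxan binary can be substituted for the internal
#' solver.
#'
#' @param problem A [make_problem()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_marxan_input <- function(problem, dir) {
  stopifnot(inherits(problem, "reef_problem"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pu <- data.frame(id = problem$pu_ids, cost = problem$cost, status = 0L)
  spec <- data.frame(id = problem$feature_ids,
                     name = paste0("class_", problem$feature_ids),
                     prop = problem$prop, spf = problem$spf)
  nper <- diff(problem$pu_ptr)
  puvspr <- data.frame(species = problem$feature_ids[problem$feat_idx + 1L],
                       pu = rep(problem$pu_ids, nper),
                       amount = problem$amount)
  puvspr <- puvspr[order(puvspr$species, puvspr$pu), ]
  paths <- file.path(dir, c("pu.dat", "spec.dat", "puvspr.dat"))
  utils::write.table(pu, paths[1], sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(spec, paths[2], sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(puvspr, paths[3], sep = ",", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

# tab/comma tolerant reader for the Marxan dat dialect
read_dat <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep))
}

#' Read Marxan-dialect input files
#'
#' @param dir Directory containing `pu.dat`, `spec.dat`, `puvspr.dat`
#'   (comma- or tab-separated).
#' @return List of tibbles `pu`, `spec`, `puvspr`.
#' @export
read_marxan_input <- function(dir) {
  list(pu = read_dat(file.path(dir, "pu.dat")),
       spec = read_dat(file.path(dir, "spec.dat")),
       puvspr = read_dat(file.path(dir, "puvspr.dat")))
}

#' Reconstruct a problem from Marxan-dialect files
#'
#' @inheritParams read_marxan_input
#' @return A `reef_problem` (reef areas default to costs).
#' @export
read_marxan_problem <- function(dir) {
  x <- read_marxan_input(dir)
  features <- tibble::tibble(pu_id = x$puvspr$pu, class_id = x$puvspr$species,
                             amount_km2 = x$puvspr$amount)
  costs <- tibble::tibble(pu_id = x$pu$id, cost = x$pu$cost)
  prop <- unique(x$spec$prop)
  if (length(prop) != 1)
    abort("per-feature prop values differ; a single prop is required")
  pr <- make_problem(features, costs, prop = prop)
  pr$spf <- x$spec$spf[match(pr$feature_ids, x$spec$id)]
  pr
}

#' Write per-replicate solutions and selection frequencies
#'
#' One CSV per replicate (`pu_id`, `selected`) plus an ssoln-style summary
#' (`pu_id`, `freq`).
#'
#' @param replicates A [run_replicates()] result.
#' @param problem The problem solved.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_solutions <- function(replicates, problem, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (r in seq_along(replicates$solutions)) {
    p <- file.path(dir, sprintf("solution_%03d.csv", r))
    utils::write.csv(data.frame(
      pu_id = problem$pu_ids,
      selected = as.integer(problem$pu_ids %in%
                              replicates$solutions[[r]]$selected)),
      p, row.names = FALSE)
    paths <- c(paths, p)
  }
  fp <- file.path(dir, "ssoln.csv")
  utils::write.csv(as.data.frame(replicates$frequency), fp, row.names = FALSE)
  invisible(c(paths, fp))
}

#' Write a cell layer as an ESRI-style ASCII grid
#'
#' @param reefscape The reefscape providing the grid shape.
#' @param values Per-cell values in `cell_id` order (length rows x cols).
#' @param path Output file.
#' @param nodata NODATA marker (default -9999).
#' @return Invisibly, `path`.
#' @export
write_ascii_grid <- function(reefscape, values, path, nodata = -9999) {
  stopifnot(length(values) == reefscape$n_rows * reefscape$n_cols)
  values[is.na(values)] <- nodata
  hdr <- c(paste("ncols", reefscape$n_cols),
           paste("nrows", reefscape$n_rows),
           paste("xllcorner", 0), paste("yllcorner", 0),
           paste("cellsize", reefscape$cell_size_km),
           paste("NODATA_value", nodata))
  m <- matrix(values, nrow = reefscape$n_rows, ncol = reefscape$n_cols,
              byrow = TRUE)
  writeLines(c(hdr, apply(m, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' Read an ESRI-style ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or compatible).
#' @return List with `values` (row-major vector, NODATA as NA), `nrows`,
#'   `ncols`, `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  get <- function(key) as.numeric(kv[tolower(kv[, 1]) == tolower(key), 2])
  ncols <- get("ncols"); nrows <- get("nrows")
  nodata <- get("NODATA_value")
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:6)]), "\\s+")))
  stopifnot(length(vals) == nrows * ncols)
  vals[vals == nodata] <- NA
  list(values = vals, nrows = nrows, ncols = ncols, cellsize = get("cellsize"))
}

#' Export the reefscape class table
#'
#' @param reefscape A reefscape.
#' @param path CSV path (`cell_id`, `l1`..`l5`, `reef_fraction`).
#' @return Invisibly, `path`.
#' @export
write_class_table <- function(reefscape, path) {
  utils::write.csv(
    dplyr::select(reefscape$cells, "cell_id", "l1", "l2", "l3", "l4", "l5",
                  "reef_fraction"),
    path, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram as Newick
#'
#' @param tree An `hclust` from [average_linkage_cluster()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
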