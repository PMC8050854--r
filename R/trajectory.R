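#' Build per-gene community trajectories
#'
#' The trajectory of a gene is the ordered sequence of communities it belongs
#' to across the resolution grid. Row `g`, column `t` holds the canonical
#' community id of gene `g` at the `t`-th resolution.
#'
#' @param profile A `resolution_profile` from [resolution_sweep()].
#' @return An object of class `trajectory_matrix`: integer matrix genes x
#'   resolutions with the grid stored in attribute `grid`.
#' @export
build_trajectories <- function(profile) {
  stopifnot(inherits(profile, "resolution_profile"))
  mat <- vapply(
    profile$partitions,
    function(p) unname(p$membership[profile$nodes]),
    integer(length(profile$nodes))
  )
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(profile$nodes))
  dimnames(mat) <- list(profile$nodes, paste0("gamma_", profile$grid))
  structure(mat, grid = profile$grid, class = c("trajectory_matrix", "matrix"))
}

#' @export
print.trajectory_matrix <- function(x, ...) {
  cat("A trajectory matrix: ", nrow(x), " genes x ", ncol(x),
      " resolutions\n", sep = "")
  invisible(x)
}

#' @method as_tibble trajectory_matrix
#' @export
as_tibble.trajectory_matrix <- function(x, ...) {
  tibble::tibble(
    gene = rep(rownames(x), ncol(x)),
    gamma = rep(attr(x, "grid"), each = nrow(x)),
    community = as.integer(x)
  )
}

#' Write / read a trajectory matrix as TSV
#'
#' Gene rows, one column per resolution (header `gamma_<value>`), first
#' column `gene`.
#'
#' @param traj A `trajectory_matrix`.
#' @param path TSV path.
#' @return `path` invisibly; `read_trajectories()` returns the matrix.
#' @export
write_trajectories <- function(traj, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(traj)))
  df <- dplyr::bind_cols(tibble::tibble(gene = rownames(traj)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  mode(mat) <- "integer"
  rownames(mat) <- df$gene
  grid <- as.numeric(sub("^gamma_", "", colnames(mat)))
  structure(mat, grid = grid, class = c("trajectory_matrix", "matrix"))
}

#' Hamming distance between two community trajectories
#'
#' The number of resolution-grid positions at which the two genes sit in
#' different communities. Comparison is by co-membership within each
#' resolution's partition, so the distance is invariant to arbitrary
#' per-resolution relabeling of community ids. The count is not normalized:
#' it ranges from 0 to the grid length, and the selection threshold theta is
#' expressed on the same scale.
#'
#' @param traj_a,traj_b Integer label vectors of equal length (rows of a
#'   `trajectory_matrix`).
#' @param normalize If `TRUE`, divide by the grid length.
#' @return Integer count (or fraction when normalized).
#' @export
trajectory_hamming <- function(traj_a, traj_b, normalize = FALSE) {
  if (length(traj_a) != length(traj_b)) {
    stop("trajectories differ in length", call. = FALSE)
  }
  d <- sum(traj_a != traj_b)
  if (normalize) d / length(traj_a) else as.integer(d)
}

#' All pairwise trajectory Hamming distances
#'
#' @param traj A `trajectory_matrix`.
#' @param subset Optional character vector of genes (e.g. one patient's
#'   altered genes) to restrict the matrix to.
#' @inheritParams trajectory_hamming
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
trajectory_distances <- function(traj, subset = NULL, normalize = FALSE) {
  stopifnot(inherits(traj, "trajectory_matrix"))
  m <- unclass(traj)
  if (!is.null(subset)) {
    unknown <- setdiff(subset, rownames(m))
    if (length(unknown)) {
      stop("gene(s) not in trajectory matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
    m <- m[subset, , drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (t in seq_len(ncol(m))) {
    d <- d + outer(m[, t], m[, t], "!=")
  }
  if (normalize) d / ncol(m) else d
}

#' Birth, death and resurgence events of communities along the sweep
#'
#' A community is identified by its exact member set; tracking those sets
#' across the resolution grid yields presence intervals. Each interval start
#' is a birth; each interval end before the last grid point is a death
#' (optionally also at the last point, see `count_terminal`); each
#' re-appearance after an absence is a resurgence. For every community with
#' `k` presence intervals: resurgences `= k - 1`, and deaths `= k - 1` if the
#' community is present at the final grid point, else `k`.
#'
#' @param profile A `resolution_profile`.
#' @param count_terminal Count a death for communities still present at the
#'   final resolution? Default `FALSE`.
#' @return An object of class `community_events`: tibble with one row per
#'   unique community (`community` key, `size`, `births`, `deaths`,
#'   `resurgences`, `intervals`, `present_at_end`), with totals in attribute
#'   `totals`.
#' @export
community_events <- function(profile, count_terminal = FALSE) {
  stopifnot(inherits(profile, "resolution_profile"))
  T_ <- length(profile$grid)
  keys <- lapply(profile$partitions, function(p) {
    split(names(p$membership), p$membership) |>
      vapply(function(g) paste(sort(g), collapse = "|"), "")
  })
  all_keys <- unique(unlist(keys))
  present <- matrix(FALSE, length(all_keys), T_,
                    dimnames = list(all_keys, NULL))
  for (t in seq_len(T_)) present[keys[[t]], t] <- TRUE
  per <- purrr::map_dfr(seq_along(all_keys), function(i) {
    p <- present[i, ]
    r <- rle(p)
    k <- sum(r$values) # number of presence intervals
    at_end <- p[T_]
    deaths <- if (at_end && !count_terminal) k - 1L else k
    tibble::tibble(
      community = all_keys[i],
      size = lengths(strsplit(all_keys[i], "|", fixed = TRUE)),
      births = k,
      deaths = as.integer(deaths),
      resurgences = k - 1L,
      intervals = k,
      present_at_end = at_end
    )
  })
  attr(per, "totals") <- list(
    communities = nrow(per),
    births = sum(per$births),
    deaths = sum(per$deaths),
    resurgences = sum(per$resurgences)
  )
  class(per) <- c("community_events", class(per))
  per
}

#' @method glance community_events
#' @export
glance.community_events <- function(x, ...) {
  tot <- attr(x, "totals")
  tibble::tibble(
    communities = tot$communities, births = tot$births,
    deaths = tot$deaths, resurgences = tot$resurgences
  )
}

#' Agglomerative dendrogram of gene trajectories
#'
#' Hierarchical clustering of the trajectory Hamming distance matrix,
#' average linkage (UPGMA) by default.
#'
#' @param dist_matrix Symmetric distance matrix (genes x genes), e.g. from
#'   [trajectory_distances()].
#' @param linkage Agglomeration method passed to [stats::hclust()]
#'   (`"average"`, `"complete"`, `"ward.D2"`, ...).
#' @return An `hclust` tree over the genes.
#' @export
trajectory_dendrogram <- function(dist_matrix, linkage = "average") {
  if (nrow(as.matrix(dist_matrix)) < 2) {
    stop("need at least 2 genes to build a dendrogram", call. = FALSE)
  }
  stats::hclust(stats::as.dist(dist_matrix), method = linkage)
}

#' Serialize an hclust tree to newick
#' @param tree An `hclust` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Write a community event log as JSON
#' @param events A `community_events` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  jsonlite::write_json(
    list(
      totals = attr(events, "totals"),
      communities = as.data.frame(events)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
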