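# --- shared helpers -------------------------------------------------------

# Jaccard distance between the rows of a (possibly column-resampled) binary
# matrix; a pair of all-zero rows gets distance 0.
binary_jaccard_dist <- function(m) {
  m <- m * 1
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- ifelse(uni == 0, 0, 1 - inter / pmax(uni, 1))
  diag(d) <- 0
  stats::as.dist(d)
}

feature_dist <- function(m, method) {
  switch(method,
    jaccard = binary_jaccard_dist(m),
    euclidean = stats::dist(m),
    stop("unknown distance method: ", method, call. = FALSE)
  )
}

pick_dist_method <- function(m, method) {
  if (method != "auto") return(method)
  if (all(m %in% c(0, 1))) "jaccard" else "euclidean"
}

# internal nodes of an hclust tree as member-id sets (leaf label keys)
tree_node_members <- function(tree) {
  n <- length(tree$labels)
  members <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    kids <- tree$merge[k, ]
    mem <- integer(0)
    for (kid in kids) {
      mem <- c(mem, if (kid < 0) -kid else members[[kid]])
    }
    members[[k]] <- sort(mem)
  }
  lapply(members, function(ix) tree$labels[ix])
}

node_key <- function(members) paste(sort(members), collapse = "|")

#' Multiscale-bootstrap AU values for a patient dendrogram
#'
#' The feature matrix is the binary patients x selected-genes incidence at
#' the optimal `(theta, lambda)` (rows = patients, columns = genes). For each
#' scale `r`, `B` bootstrap replicates resample `round(r * n_features)`
#' feature columns with replacement; each replicate's Jaccard distances and
#' Ward tree are recomputed, and `BP(r)` is the fraction of replicates whose
#' tree contains each original node's member set. The approximately unbiased
#' value is obtained by fitting
#' `qnorm(1 - BP(r)) ~ v * sqrt(r) + c / sqrt(r)` by weighted least squares
#' and setting `AU = 1 - pnorm(v - c)`. Nodes recovered in every (or no)
#' replicate at every scale are clamped to AU 1 (or 0).
#'
#' @param x Binary matrix patients x features (e.g. built with
#'   [selection_incidence()]).
#' @param scales Bootstrap scales `r` (default `seq(0.5, 1.4, by = 0.1)`).
#' @param B Replicates per scale (>= 100).
#' @param seed Integer seed.
#' @param dist_method `"auto"` (Jaccard for binary input, Euclidean
#'   otherwise), `"jaccard"` or `"euclidean"`.
#' @return An object of class `node_significance`: tibble with one row per
#'   internal node (`node`, `n`, `members`, `au`, `bp1` = BP at scale 1),
#'   the full BP-by-scale matrix in attribute `bp`, and the tree in
#'   attribute `tree`.
#' @export
au_pvalues <- function(x, scales = seq(0.5, 1.4, by = 0.1), B = 1000L,
                       seed = 1L, dist_method = "auto") {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 patients", call. = FALSE)
  if (ncol(x) < 2) stop("need at least 2 feature columns", call. = FALSE)
  stopifnot(all(scales > 0), B >= 100)
  dist_method <- pick_dist_method(x, dist_method)
  d0 <- feature_dist(x, dist_method)
  tree <- stats::hclust(d0, method = "ward.D2")
  members <- tree_node_members(tree)
  keys <- vapply(members, node_key, "")
  p <- ncol(x)
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(keys, paste0("r_", scales)))
  withr::with_seed(as.integer(seed), {
    for (si in seq_along(scales)) {
      psub <- max(2L, round(scales[si] * p))
      hits <- stats::setNames(numeric(length(keys)), keys)
      for (b in seq_len(B)) {
        cols <- sample.int(p, psub, replace = TRUE)
        db <- feature_dist(x[, cols, drop = FALSE], dist_method)
        tb <- stats::hclust(db, method = "ward.D2")
        kb <- unique(vapply(tree_node_members(tb), node_key, ""))
        found <- intersect(kb, keys)
        hits[found] <- hits[found] + 1
      }
      bp[, si] <- hits / B
    }
  })
  au <- vapply(seq_along(keys), function(i) {
    fit_au(bp[i, ], scales, B)
  }, 1.0)
  out <- tibble::tibble(
    node = seq_along(keys),
    n = lengths(members),
    members = keys,
    au = au,
    bp1 = if ("r_1" %in% colnames(bp)) bp[, "r_1"] else NA_real_
  )
  attr(out, "bp") <- bp
  attr(out, "tree") <- tree
  attr(out, "scales") <- scales
  class(out) <- c("node_significance", class(out))
  out
}

# weighted least-squares fit of the multiscale-bootstrap model for one node
fit_au <- function(bp_r, scales, B) {
  usable <- bp_r > 0 & bp_r < 1
  if (sum(usable) < 2) {
    return(if (mean(bp_r) >= 0.5) 1 else 0)
  }
  r <- scales[usable]
  bp <- bp_r[usable]
  z <- stats::qnorm(1 - bp)
  # binomial delta-method weights on the probit scale
  w <- B * stats::dnorm(z)^2 / (bp * (1 - bp))
  X <- cbind(sqrt(r), 1 / sqrt(r))
  fit <- stats::lm.wfit(X, z, w)
  v <- fit$coefficients[1]
  cc <- fit$coefficients[2]
  min(1, max(0, 1 - stats::pnorm(v - cc)))
}

#' Monte Carlo empirical and Gaussian p values for dendrogram nodes
#'
#' For each internal node with at least 3 members: the node's sub-distance
#' matrix is embedded by classical multidimensional scaling; the observed
#' statistic is the two-group separation index of the node's children (ratio
#' of between-group to total dispersion of the embedded points). The null
#' draws `M` datasets from a single multivariate Gaussian conditioned on the
#' embedded sub-data's sample mean and covariance, re-applies the same
#' procedure (Ward tree on the null points, cut in two, separation index)
#' and reports the add-one empirical p
#' value `(1 + #\{null >= observed\}) / (M + 1)` together with a Gaussian
#' approximate p value (upper tail of a normal with the null replicates'
#' moments). The separation statistic is a documented construction of this
#' package (the outputs mirror an empirical and a Gaussian approximate p per
#' cluster); it is not imported from elsewhere.
#'
#' @param x Feature matrix patients x features (binary or numeric).
#' @param tree Optional `hclust` over the patients; recomputed from `x`
#'   (Ward on the feature distances) when missing.
#' @param M Null replicates (>= 19; default 999).
#' @param seed Integer seed.
#' @inheritParams au_pvalues
#' @return An object of class `node_significance`: tibble with one row per
#'   internal node (`node`, `n`, `members`, `statistic`, `p_empirical`,
#'   `p_gaussian`); nodes with fewer than 3 members carry `NA` p values.
#' @export
monte_carlo_pvalues <- function(x, tree = NULL, M = 999L, seed = 1L,
                                dist_method = "auto") {
  x <- as.matrix(x)
  stopifnot(M >= 19)
  dist_method <- pick_dist_method(x, dist_method)
  d0 <- feature_dist(x, dist_method)
  if (is.null(tree)) tree <- stats::hclust(d0, method = "ward.D2")
  members <- tree_node_members(tree)
  dm <- as.matrix(d0)
  merge <- tree$merge
  child_sets <- function(k) {
    lapply(merge[k, ], function(kid) {
      if (kid < 0) tree$labels[-kid] else members[[kid]]
    })
  }
  rows <- vector("list", length(members))
  withr::with_seed(as.integer(seed), {
    for (k in seq_along(members)) {
      mem <- members[[k]]
      nm <- length(mem)
      if (nm < 3) {
        rows[[k]] <- tibble::tibble(
          node = k, n = nm, members = node_key(mem),
          statistic = NA_real_, p_empirical = NA_real_, p_gaussian = NA_real_
        )
        next
      }
      Y <- embed_points(dm[mem, mem, drop = FALSE])
      kids <- child_sets(k)
      grp <- ifelse(mem %in% kids[[1]], 1L, 2L)
      obs <- separation_index(Y, grp)
      mu <- colMeans(Y)
      Sigma <- stats::cov(Y)
      null <- vapply(seq_len(M), function(r) {
        # conditioning each null draw on the observed sample moments
        # (empirical = TRUE) avoids the double anisotropy of a plain
        # parametric bootstrap with an estimated covariance, which would
        # inflate the null separation and make the p values conservative
        Z <- MASS::mvrnorm(nm, mu, Sigma, tol = 1e-6, empirical = TRUE)
        tz <- stats::hclust(stats::dist(Z), method = "ward.D2")
        separation_index(Z, stats::cutree(tz, k = 2))
      }, 1.0)
      p_emp <- (1 + sum(null >= obs)) / (M + 1)
      sd_null <- stats::sd(null)
      p_gau <- if (is.na(sd_null) || sd_null == 0) {
        as.numeric(obs <= mean(null))
      } else {
        stats::pnorm(obs, mean(null), sd_null, lower.tail = FALSE)
      }
      rows[[k]] <- tibble::tibble(
        node = k, n = nm, members = node_key(mem),
        statistic = obs, p_empirical = p_emp, p_gaussian = p_gau
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "tree") <- tree
  class(out) <- c("node_significance", class(out))
  out
}

# classical MDS embedding, keeping the informative positive-eigenvalue axes
embed_points <- function(dsub) {
  n <- nrow(dsub)
  # cmdscale warns when fewer than k eigenvalues are positive (duplicated
  # points); the positive axes are filtered below anyway
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(dsub), k = n - 1, eig = TRUE)
  )
  keep <- fit$eig > max(fit$eig) * 1e-8 & fit$eig > 0
  keep <- keep[seq_len(ncol(fit$points))]
  Y <- fit$points[, keep, drop = FALSE]
  if (ncol(Y) == 0) Y <- matrix(0, n, 1)
  Y
}

# between-group over total dispersion of embedded points, in [0, 1]
separation_index <- function(Y, grp) {
  center <- colMeans(Y)
  tss <- sum(sweep(Y, 2, center)^2)
  if (tss == 0) return(0)
  bss <- 0
  for (g in unique(grp)) {
    idx <- grp == g
    cg <- colMeans(Y[idx, , drop = FALSE])
    bss <- bss + sum(idx) * sum((cg - center)^2)
  }
  bss / tss
}

#' Binary patients x selected-genes incidence matrix
#'
#' The feature matrix consumed by [au_pvalues()] and
#' [monte_carlo_pvalues()]: one row per patient, one column per gene in the
#' union of the selected sets, entries 1 where the gene was selected for the
#' patient.
#'
#' @param selected_sets Named list patient -> selected genes.
#' @return Binary matrix with patient rownames and gene colnames.
#' @export
selection_incidence <- function(selected_sets) {
  genes <- sort(unique(unlist(selected_sets)))
  if (length(genes) < 2) {
    stop("need at least 2 distinct selected genes", call. = FALSE)
  }
  m <- vapply(selected_sets, function(s) as.numeric(genes %in% s),
              numeric(length(genes)))
  t(matrix(m, nrow = length(genes),
           dimnames = list(genes, names(selected_sets))))
}

#' Write annotated node significance as JSON
#' @param nodes A `node_significance` tibble.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_node_significance <- function(nodes, path) {
  payload <- list(nodes = as.data.frame(nodes))
  bp <- attr(nodes, "bp")
  if (!is.null(bp)) payload$bp <- as.data.frame(bp)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
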