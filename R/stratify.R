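#' Selection parameters for minimal gene sets
#'
#' `theta` is the persistence tolerance: the maximum trajectory Hamming
#' distance (in resolution steps) allowed within a gene group; `theta = 0`
#' keeps only genes that never separate along the sweep. `lambda` caps the
#' group size: only groups of at most `lambda` genes are retained ("sets of
#' at most lambda"). `smin` is the minimum group size; its default of 2
#' excludes singletons, since a selected gene should be tightly associated
#' with at least one co-member.
#'
#' @param theta Integer `>= 0`, resolution steps.
#' @param lambda Integer `>= 1`, group size cap.
#' @param smin Integer `>= 1`, minimum group size (default 2).
#' @return A `selection_params` list.
#' @export
selection_params <- function(theta = 0L, lambda = 6L, smin = 2L) {
  stopifnot(theta >= 0, lambda >= 1, smin >= 1)
  structure(
    list(theta = as.integer(theta), lambda = as.integer(lambda),
         smin = as.integer(smin)),
    class = "selection_params"
  )
}

# complete-linkage gene groups at height theta among `genes`
# (theta = 0 reduces to equivalence classes of identical trajectories)
trajectory_groups <- function(genes, traj, theta) {
  if (length(genes) == 1) {
    return(stats::setNames(1L, genes))
  }
  d <- trajectory_distances(traj, subset = genes)
  hc <- stats::hclust(stats::as.dist(d), method = "complete")
  stats::cutree(hc, h = theta)
}

#' Select a patient's minimal gene sets
#'
#' Groups the patient's altered genes by the similarity of their community
#' trajectories — complete-linkage clusters of the patient-restricted
#' Hamming-distance matrix cut at height `theta` (for `theta = 0` these are
#' exactly the classes of genes that are always part of the same communities)
#' — and keeps the groups whose size `s` satisfies `smin <= s <= lambda`.
#'
#' @param patient_genes Character vector of the patient's altered genes; must
#'   all be present in the trajectory matrix (apply [restrict_to_network()]
#'   first).
#' @param traj A `trajectory_matrix`.
#' @param params A [selection_params()] object.
#' @return List with `selected` (sorted character vector) and `groups`
#'   (list of the retained gene groups).
#' @export
select_patient_genes <- function(patient_genes, traj, params = selection_params()) {
  if (length(patient_genes) == 0) stop("empty patient gene set", call. = FALSE)
  grp <- trajectory_groups(patient_genes, traj, params$theta)
  groups <- split(names(grp), grp)
  keep <- groups[lengths(groups) >= params$smin & lengths(groups) <= params$lambda]
  keep <- unname(lapply(keep, sort))
  list(selected = sort(unlist(keep, use.names = FALSE) %||% character(0)),
       groups = keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select minimal gene sets for every patient of a cohort
#'
#' @param x A `cohort` (already restricted to the trajectory genes).
#' @param traj A `trajectory_matrix`.
#' @param params A [selection_params()] object.
#' @return Named list patient -> selected gene vector (possibly empty).
#' @export
select_cohort_genes <- function(x, traj, params = selection_params()) {
  stopifnot(inherits(x, "cohort"))
  lapply(x$patients, function(g) select_patient_genes(g, traj, params)$selected)
}

#' Jaccard similarity between patients' selected gene sets
#'
#' `J(p, q) = |Sp intersect Sq| / |Sp union Sq|`; two empty sets have `J = 1`
#' and exactly one empty set gives `J = 0`.
#'
#' @param selected_sets Named list patient -> selected gene vector.
#' @return An object of class `patient_similarity`: symmetric matrix of
#'   Jaccard indices with unit diagonal.
#' @export
patient_similarity <- function(selected_sets) {
  if (length(selected_sets) < 2) stop("need at least 2 patients", call. = FALSE)
  if (all(lengths(selected_sets) == 0)) {
    stop("all selected sets are empty: no signal at these parameters",
         call. = FALSE)
  }
  ids <- names(selected_sets)
  genes <- sort(unique(unlist(selected_sets)))
  inc <- vapply(selected_sets, function(s) genes %in% s, logical(length(genes)))
  if (is.null(dim(inc))) inc <- matrix(inc, nrow = length(genes))
  inc <- t(inc) * 1 # patients x genes
  inter <- inc %*% t(inc)
  sizes <- rowSums(inc)
  uni <- outer(sizes, sizes, "+") - inter
  J <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  diag(J) <- 1
  dimnames(J) <- list(ids, ids)
  structure(J, class = c("patient_similarity", "matrix"))
}

#' Cluster a cohort from its patient similarity
#'
#' Agglomerates patients by Ward linkage (squared-distance Lance-Williams
#' update, `ward.D2`) on the Jaccard distance `1 - J`. The number of clusters
#' is chosen by running PAM (k-medoids, deterministic BUILD + SWAP) for
#' `k = 2..kmax` on the same distances and maximizing the average silhouette
#' width (ties broken toward the smallest k); the tree is then cut at that k
#' (set `method = "pam"` to return the PAM clusters themselves).
#'
#' @param sim A `patient_similarity` matrix.
#' @param kmax Largest number of clusters to consider (`2 <= k <= kmax < n`).
#' @param method `"ward"` (cut the Ward tree, default) or `"pam"`.
#' @return An object of class `cohort_clustering`: list with `labels` (named
#'   integer), `k`, `tree` (hclust), `silhouette` (tibble k / avg width) and
#'   `method`.
#' @export
cluster_cohort <- function(sim, kmax = 8L, method = c("ward", "pam")) {
  method <- match.arg(method)
  n <- nrow(sim)
  if (n < 3) stop("need at least 3 patients", call. = FALSE)
  if (kmax >= n) stop("kmax must be smaller than the number of patients", call. = FALSE)
  kmax <- max(2L, as.integer(kmax))
  d <- stats::as.dist(1 - unclass(sim))
  tree <- stats::hclust(d, method = "ward.D2")
  sil <- purrr::map_dfr(2:kmax, function(k) {
    fit <- cluster::pam(d, k, diss = TRUE)
    tibble::tibble(k = k, avg_silhouette = fit$silinfo$avg.width)
  })
  k_best <- sil$k[which.max(sil$avg_silhouette)] # ties -> smallest k
  labels <- if (method == "ward") {
    stats::cutree(tree, k = k_best)
  } else {
    fit <- cluster::pam(d, k_best, diss = TRUE)
    stats::setNames(fit$clustering, rownames(sim))
  }
  structure(
    list(labels = labels, k = k_best, tree = tree, silhouette = sil,
         method = method),
    class = "cohort_clustering"
  )
}

#' @export
print.cohort_clustering <- function(x, ...) {
  cat("A cohort clustering: k = ", x$k, " (", x$method, "), sizes ",
      paste(table(x$labels), collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Score a clustering against reference subgroup labels
#'
#' Each cluster is mapped to its majority reference label (ties broken
#' lexicographically), which allows more clusters than reference subgroups —
#' e.g. a fifth mixed cluster absorbing patients from two subgroups. Reported
#' are the micro accuracy (percent of patients whose mapped label matches
#' their reference), the macro accuracy (mean per-reference-class recall) and
#' the multiclass Matthews correlation coefficient (Gorodkin) of the mapped
#' confusion table (0 when its denominator vanishes).
#'
#' @param clusters Named vector of cluster ids.
#' @param reference Named vector of reference labels (same patient ids).
#' @return An object of class `clustering_score`: list with `accuracy`,
#'   `macro_accuracy` (both percent), `mcc`, `k`, `mapping` and `confusion`.
#' @export
score_clustering <- function(clusters, reference) {
  if (length(clusters) == 0) stop("empty clustering", call. = FALSE)
  ids <- names(clusters)
  if (is.null(ids) || !setequal(ids, names(reference))) {
    stop("clusters and reference must be named by the same patients", call. = FALSE)
  }
  reference <- reference[ids]
  mapping <- tapply(as.character(reference), clusters, function(lab) {
    tt <- sort(table(lab), decreasing = TRUE)
    winners <- names(tt)[tt == tt[1]]
    sort(winners)[1]
  })
  mapped <- unname(mapping[as.character(clusters)])
  acc <- 100 * mean(mapped == reference)
  macro <- mean(tapply(mapped == reference, reference, mean))
  conf <- table(predicted = mapped, reference = as.character(reference))
  structure(
    list(
      accuracy = acc, macro_accuracy = 100 * macro,
      mcc = multiclass_mcc(mapped, as.character(reference)),
      k = length(unique(clusters)),
      mapping = mapping, confusion = conf
    ),
    class = "clustering_score"
  )
}

# Gorodkin multiclass MCC from two label vectors
multiclass_mcc <- function(pred, truth) {
  classes <- sort(unique(c(pred, truth)))
  C <- table(factor(truth, classes), factor(pred, classes))
  s <- sum(C)
  c_ <- sum(diag(C))
  t_k <- rowSums(C) # true counts
  p_k <- colSums(C) # predicted counts
  num <- c_ * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' @export
print.clustering_score <- function(x, ...) {
  cat(sprintf(
    "accuracy %.2f%% (macro %.2f%%), MCC %.3f, k = %d\n",
    x$accuracy, x$macro_accuracy, x$mcc, x$k
  ))
  invisible(x)
}

#' @method glance clustering_score
#' @export
glance.clustering_score <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, macro_accuracy = x$macro_accuracy,
    mcc = x$mcc, k = x$k
  )
}

#' Optimize the selection parameters against reference subgroups
#'
#' For every `(theta, lambda)` pair: select each labeled patient's minimal
#' gene sets, build the Jaccard similarity, cluster (Ward + PAM-selected k)
#' and score against the reference subgroups. The best pair maximizes
#' accuracy, with ties broken by larger MCC, then fewer average selected
#' genes per patient, then smaller lambda, then smaller theta.
#'
#' @param x A labeled `cohort` (patients without labels are ignored), already
#'   restricted to the trajectory genes.
#' @param traj A `trajectory_matrix`.
#' @param theta_grid,lambda_grid Integer grids (defaults `0:3` and `2:10`).
#' @param kmax Passed to [cluster_cohort()].
#' @param smin Minimum group size for [selection_params()].
#' @return An object of class `parameter_scan`: list with `results` (tibble:
#'   theta, lambda, avg_genes, accuracy, macro_accuracy, mcc, k), `best`
#'   ([selection_params()]), `best_score`, `selected_sets` and `clustering`
#'   at the optimum, plus the reference labels used.
#' @export
optimize_parameters <- function(x, traj, theta_grid = 0:3, lambda_grid = 2:10,
                                kmax = 8L, smin = 2L) {
  stopifnot(inherits(x, "cohort"))
  if (length(theta_grid) == 0 || length(lambda_grid) == 0) {
    stop("parameter grids must be non-empty", call. = FALSE)
  }
  labeled <- names(x$labels)
  if (length(labeled) < 3) stop("need at least 3 labeled patients", call. = FALSE)
  genes <- x$patients[labeled]
  reference <- x$labels[labeled]
  rows <- list()
  cache <- list() # per-theta group assignments per patient
  for (theta in sort(theta_grid)) {
    grp <- lapply(genes, trajectory_groups, traj = traj, theta = theta)
    for (lambda in sort(lambda_grid)) {
      sel <- lapply(grp, function(g) {
        gs <- split(names(g), g)
        keep <- gs[lengths(gs) >= smin & lengths(gs) <= lambda]
        sort(unlist(keep, use.names = FALSE) %||% character(0))
      })
      row <- tibble::tibble(
        theta = theta, lambda = lambda,
        avg_genes = mean(lengths(sel)),
        accuracy = NA_real_, macro_accuracy = NA_real_,
        mcc = NA_real_, k = NA_integer_
      )
      if (any(lengths(sel) > 0)) {
        sim <- patient_similarity(sel)
        cl <- cluster_cohort(sim, kmax = kmax)
        sc <- score_clustering(cl$labels, reference)
        row$accuracy <- sc$accuracy
        row$macro_accuracy <- sc$macro_accuracy
        row$mcc <- sc$mcc
        row$k <- cl$k
      }
      rows[[length(rows) + 1L]] <- row
      cache[[paste(theta, lambda)]] <- sel
    }
  }
  results <- dplyr::bind_rows(rows)
  valid <- dplyr::filter(results, !is.na(.data$accuracy))
  if (nrow(valid) == 0) {
    stop("every (theta, lambda) pair produced all-empty selections", call. = FALSE)
  }
  ord <- order(-valid$accuracy, -valid$mcc, valid$avg_genes,
               valid$lambda, valid$theta)
  best_row <- valid[ord[1], ]
  best <- selection_params(best_row$theta, best_row$lambda, smin)
  sel_best <- cache[[paste(best_row$theta, best_row$lambda)]]
  sim <- patient_similarity(sel_best)
  cl <- cluster_cohort(sim, kmax = kmax)
  structure(
    list(
      results = results, best = best,
      best_score = score_clustering(cl$labels, reference),
      selected_sets = sel_best, clustering = cl, reference = reference
    ),
    class = "parameter_scan"
  )
}

#' @export
print.parameter_scan <- function(x, ...) {
  cat("A parameter scan over ", nrow(x$results), " (theta, lambda) pairs\n",
      "best: theta = ", x$best$theta, ", lambda = ", x$best$lambda,
      sprintf(" -> accuracy %.2f%%, MCC %.3f, k = %d\n",
              x$best_score$accuracy, x$best_score$mcc, x$best_score$k),
      sep = "")
  invisible(x)
}

#' @method tidy parameter_scan
#' @export
tidy.parameter_scan <- function(x, ...) x$results

#' @method glance parameter_scan
#' @export
glance.parameter_scan <- function(x, ...) {
  tibble::tibble(
    theta = x$best$theta, lambda = x$best$lambda,
    accuracy = x$best_score$accuracy,
    macro_accuracy = x$best_score$macro_accuracy,
    mcc = x$best_score$mcc, k = x$best_score$k,
    avg_genes = mean(lengths(x$selected_sets))
  )
}

#' Classify a held-out patient by Jaccard similarity
#'
#' Selects the held-out patient's genes at the trained optimum and assigns
#' the cluster of the most Jaccard-similar training patient; the full
#' similarity ranking is returned.
#'
#' @param heldout_genes Character vector of the held-out patient's altered
#'   genes (restricted to the trajectory genes).
#' @param scan A `parameter_scan` from [optimize_parameters()].
#' @param traj The `trajectory_matrix` used in training.
#' @return List with `cluster` (assigned id, `NA` when unclassifiable),
#'   `unclassifiable` (logical), `best_match` and `ranking` (tibble patient /
#'   jaccard / cluster, non-increasing).
#' @export
classify_heldout <- function(heldout_genes, scan, traj) {
  stopifnot(inherits(scan, "parameter_scan"))
  sel <- select_patient_genes(heldout_genes, traj, scan$best)$selected
  train <- scan$selected_sets
  jac <- vapply(train, function(s) {
    u <- length(union(sel, s))
    if (u == 0) 1 else length(intersect(sel, s)) / u
  }, 1.0)
  ranking <- tibble::tibble(
    patient = names(train), jaccard = unname(jac),
    cluster = unname(scan$clustering$labels[names(train)])
  )
  ranking <- ranking[order(-ranking$jaccard, ranking$patient), ]
  if (length(sel) == 0) {
    return(list(cluster = NA_integer_, unclassifiable = TRUE,
                best_match = NA_character_, ranking = ranking))
  }
  list(
    cluster = ranking$cluster[1], unclassifiable = FALSE,
    best_match = ranking$patient[1], ranking = ranking
  )
}

#' Per-patient and cohort selection statistics
#'
#' Reports, per patient, the altered and selected gene counts and the
#' dimensionality reduction `100 * (1 - selected/altered)` (percent); cohort
#' means and SDs of both; and, when cluster labels are supplied, the genes
#' selected in every patient of one cluster and in no patient of any other
#' (uniquely-selected genes).
#'
#' @param x The `cohort` the selection was computed on.
#' @param selected_sets Named list patient -> selected genes.
#' @param clusters Optional named cluster labels.
#' @return List with `per_patient` (tibble), `summary` (tibble of means/SDs)
#'   and `unique_genes` (named list per cluster, or `NULL`).
#' @export
selection_summary <- function(x, selected_sets, clusters = NULL) {
  stopifnot(inherits(x, "cohort"))
  ids <- names(selected_sets)
  per <- tibble::tibble(
    patient = ids,
    n_altered = unname(lengths(x$patients[ids])),
    n_selected = unname(lengths(selected_sets)),
    reduction_pct = 100 * (1 - .data$n_selected / .data$n_altered)
  )
  summary <- tibble::tibble(
    mean_selected = mean(per$n_selected), sd_selected = stats::sd(per$n_selected),
    mean_reduction = mean(per$reduction_pct), sd_reduction = stats::sd(per$reduction_pct)
  )
  uniq <- NULL
  if (!is.null(clusters)) {
    clusters <- clusters[ids]
    uniq <- lapply(sort(unique(clusters)), function(cl) {
      inside <- selected_sets[ids[clusters == cl]]
      outside <- selected_sets[ids[clusters != cl]]
      shared <- Reduce(intersect, inside)
      setdiff(shared, unique(unlist(outside)))
    })
    names(uniq) <- sort(unique(clusters))
  }
  list(per_patient = per, summary = summary, unique_genes = uniq)
}
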