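#' Shuffle altered genes across a cohort
#'
#' Permutes the pooled (patient, gene) incidence while preserving both
#' marginals exactly: every patient keeps its original number of altered
#' genes, and the pooled gene multiset is unchanged. Duplicates created
#' within a patient by the permutation are repaired by random pairwise swaps
#' with other patients; the repair is bounded and errors out on pathological
#' inputs.
#'
#' @param x A `cohort`.
#' @param seed Integer seed; the shuffle is deterministic given the seed.
#' @return A shuffled `cohort` with the same labels.
#' @export
shuffle_cohort <- function(x, seed = 1L) {
  stopifnot(inherits(x, "cohort"))
  if (length(x$patients) < 2) stop("need at least 2 patients", call. = FALSE)
  sizes <- lengths(x$patients)
  pool <- unlist(x$patients, use.names = FALSE)
  owner <- rep(seq_along(sizes), sizes)
  withr::with_seed(as.integer(seed), {
    genes <- sample(pool)
    max_tries <- 100L * length(pool)
    tries <- 0L
    repeat {
      dup <- which(duplicated_within(genes, owner))
      if (length(dup) == 0) break
      for (d in dup) {
        repeat {
          tries <- tries + 1L
          if (tries > max_tries) {
            stop("could not repair within-patient duplicates", call. = FALSE)
          }
          cand <- sample.int(length(genes), 1L)
          if (owner[cand] == owner[d]) next
          # swap must not create a duplicate on either side
          if (genes[cand] %in% genes[owner == owner[d] & seq_along(genes) != d]) next
          if (genes[d] %in% genes[owner == owner[cand] & seq_along(genes) != cand]) next
          tmp <- genes[d]; genes[d] <- genes[cand]; genes[cand] <- tmp
          break
        }
      }
    }
  })
  shuffled <- split(genes, owner)
  names(shuffled) <- names(x$patients)
  cohort(shuffled, if (length(x$labels)) x$labels else NULL)
}

# flags positions whose gene already occurred for the same owner
duplicated_within <- function(genes, owner) {
  duplicated(paste(owner, genes, sep = "\r"))
}

#' Shuffled-cohort null distribution of clustering accuracy
#'
#' Repeats, `n_replicates` times: shuffle the cohort ([shuffle_cohort()]),
#' select each patient's minimal gene sets at fixed `(theta, lambda)`,
#' cluster, and score against the original reference labels. A replicate
#' whose selections are all empty is recorded as accuracy 0 and flagged.
#'
#' @param x A labeled `cohort` restricted to the trajectory genes.
#' @param traj A `trajectory_matrix`.
#' @param params Fixed [selection_params()] (the optimum of the real data).
#' @param n_replicates Number of shuffles (default 10000; use a small number
#'   for exploration).
#' @param kmax Passed to [cluster_cohort()].
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return An object of class `shuffle_null`: list with `accuracies`,
#'   `mean`, `sd`, `params`, `n_replicates`, `seed` and `flagged` (indices of
#'   all-empty replicates).
#' @export
shuffle_analysis <- function(x, traj, params = selection_params(),
                             n_replicates = 10000L, kmax = 8L, seed = 1L) {
  stopifnot(inherits(x, "cohort"), n_replicates >= 1)
  labeled <- names(x$labels)
  if (length(labeled) < 3) stop("need at least 3 labeled patients", call. = FALSE)
  reference <- x$labels[labeled]
  acc <- numeric(n_replicates)
  flagged <- integer(0)
  for (r in seq_len(n_replicates)) {
    sh <- shuffle_cohort(x, seed = as.integer(seed) + r)
    sel <- select_cohort_genes(
      cohort(sh$patients[labeled], reference), traj, params
    )
    if (all(lengths(sel) == 0)) {
      acc[r] <- 0
      flagged <- c(flagged, r)
      next
    }
    sim <- patient_similarity(sel)
    cl <- cluster_cohort(sim, kmax = kmax)
    acc[r] <- score_clustering(cl$labels, reference)$accuracy
  }
  structure(
    list(accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
         params = params, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), flagged = flagged),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf(
    "Shuffle null (N = %d, theta = %d, lambda = %d): mean accuracy %.2f%% (SD %.2f)\n",
    x$n_replicates, x$params$theta, x$params$lambda, x$mean,
    ifelse(is.na(x$sd), 0, x$sd)
  ))
  invisible(x)
}

#' @method tidy shuffle_null
#' @export
tidy.shuffle_null <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$accuracies), accuracy = x$accuracies)
}

#' @method glance shuffle_null
#' @export
glance.shuffle_null <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates, mean_accuracy = x$mean,
    sd_accuracy = x$sd, theta = x$params$theta, lambda = x$params$lambda,
    n_flagged = length(x$flagged)
  )
}

#' Recursive gene-exclusion analysis
#'
#' Runs the parameter optimization, removes each patient's selected genes
#' from that patient's altered set, and repeats on the depleted cohort. The
#' loop stops when a selection is empty for every patient, when a patient's
#' altered set would empty, when the accuracy reaches 0, or after
#' `max_iterations`.
#'
#' @inheritParams optimize_parameters
#' @param max_iterations Upper bound on iterations (default 25).
#' @return An object of class `exclusion_trace`: tibble with one row per
#'   iteration (`iteration`, `theta`, `lambda`, `accuracy`, `mcc`, `k`,
#'   `avg_removed`, `cum_removed`), with the per-iteration removed sets in
#'   attribute `removed`.
#' @export
iterative_exclusion <- function(x, traj, theta_grid = 0:3, lambda_grid = 2:10,
                                kmax = 8L, smin = 2L, max_iterations = 25L) {
  stopifnot(inherits(x, "cohort"))
  labeled <- names(x$labels)
  current <- x$patients[labeled]
  reference <- x$labels[labeled]
  rows <- list()
  removed_log <- list()
  cum <- stats::setNames(numeric(length(labeled)), labeled)
  for (it in seq_len(max_iterations)) {
    co <- cohort(current, reference)
    scan <- tryCatch(
      optimize_parameters(co, traj, theta_grid, lambda_grid, kmax, smin),
      error = function(e) NULL
    )
    if (is.null(scan)) break
    sel <- scan$selected_sets
    cum <- cum + lengths(sel)[labeled]
    rows[[it]] <- tibble::tibble(
      iteration = it,
      theta = scan$best$theta, lambda = scan$best$lambda,
      accuracy = scan$best_score$accuracy, mcc = scan$best_score$mcc,
      k = scan$best_score$k,
      avg_removed = mean(lengths(sel)),
      cum_removed = mean(cum)
    )
    removed_log[[it]] <- sel
    if (all(lengths(sel) == 0) || scan$best_score$accuracy <= 0) break
    nxt <- purrr::map2(current, sel[labeled], setdiff)
    if (any(lengths(nxt) == 0)) break
    current <- nxt
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "removed") <- removed_log
  class(out) <- c("exclusion_trace", class(out))
  out
}

#' @method glance exclusion_trace
#' @export
glance.exclusion_trace <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x),
    final_accuracy = x$accuracy[nrow(x)],
    total_removed_per_patient = x$cum_removed[nrow(x)]
  )
}
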