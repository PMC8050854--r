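# hand-built trajectory matrix with known equivalence structure:
# A,B identical; C differs from A,B at 1 position; D far from everything;
# E1..E7 a 7-gene identical block; F,G an identical pair
toy_traj <- function() {
  T_ <- 6
  rows <- rbind(
    A = c(1, 1, 1, 1, 1, 1),
    B = c(1, 1, 1, 1, 1, 1),
    C = c(1, 1, 1, 1, 1, 2),
    D = c(3, 4, 5, 6, 7, 8)
  )
  block <- matrix(rep(c(2, 2, 2, 2, 2, 3), 7), nrow = 7, byrow = TRUE)
  rownames(block) <- paste0("E", 1:7)
  fg <- rbind(F = c(9, 9, 9, 9, 9, 9), G = c(9, 9, 9, 9, 9, 9))
  m <- rbind(rows, block, fg)
  structure(m, grid = as.numeric(1:T_),
            class = c("trajectory_matrix", "matrix"))
}

test_that("selection keeps groups within the size bounds", {
  traj <- toy_traj()
  # only {A,B} qualifies at theta = 0 among A-D
  sel <- select_patient_genes(c("A", "B", "C", "D"), traj, selection_params(0, 6))
  expect_equal(sel$selected, c("A", "B"))
  # the 7-gene identical block is excluded by lambda = 6
  sel7 <- select_patient_genes(paste0("E", 1:7), traj, selection_params(0, 6))
  expect_length(sel7$selected, 0)
  # ... but admitted at lambda = 7
  expect_length(select_patient_genes(paste0("E", 1:7), traj,
                                     selection_params(0, 7))$selected, 7)
  # lambda = 1 with smin = 2 contradicts the bounds: empty selection
  expect_length(select_patient_genes(c("A", "B"), traj,
                                     selection_params(0, 1, 2))$selected, 0)
  # theta = 1 absorbs C into the {A,B} class
  expect_equal(select_patient_genes(c("A", "B", "C", "D"), traj,
                                    selection_params(1, 6))$selected,
               c("A", "B", "C"))
  expect_error(select_patient_genes(character(0), traj), "empty")
})

test_that("selection is monotone in lambda", {
  sc <- small_scenario()
  genes <- rownames(sc$traj)[1:35]
  for (theta in 0:1) {
    prev <- character(0)
    for (lambda in c(2, 4, 6, 9)) {
      cur <- select_patient_genes(genes, sc$traj,
                                  selection_params(theta, lambda))$selected
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("patient Jaccard similarity follows set arithmetic", {
  sets <- list(p1 = c("a", "b"), p2 = c("b", "c"), p3 = c("a", "b"),
               p4 = c("x", "y"), p5 = character(0))
  J <- patient_similarity(sets)
  expect_equal(J["p1", "p2"], 1 / 3)
  expect_equal(J["p1", "p3"], 1)
  expect_equal(J["p1", "p4"], 0)
  expect_equal(J["p1", "p5"], 0) # one empty set
  expect_equal(unname(diag(J)), rep(1, 5))
  expect_equal(J, t(J))
  # both-empty convention
  J2 <- patient_similarity(list(a = character(0), b = character(0), c = "g"))
  expect_equal(J2["a", "b"], 1)
  expect_error(patient_similarity(list(a = character(0), b = character(0))),
               "empty")
  expect_error(patient_similarity(list(a = "g")), "2 patients")
})

test_that("Jaccard distance satisfies the triangle inequality on random sets", {
  withr::with_seed(88, {
    for (rep in 1:20) {
      sets <- lapply(1:6, function(i) {
        sample(letters, sample(0:10, 1))
      })
      names(sets) <- paste0("p", 1:6)
      if (all(lengths(sets) == 0)) next
      D <- 1 - unclass(patient_similarity(sets))
      for (i in 1:6) for (j in 1:6) for (k in 1:6) {
        expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
      }
    }
  })
})

test_that("cluster number selection follows silhouette arithmetic", {
  # two tight groups: within 0.1, between 0.9
  ids <- paste0("p", 1:6)
  J <- matrix(1 - 0.9, 6, 6, dimnames = list(ids, ids))
  J[1:3, 1:3] <- 1 - 0.1
  J[4:6, 4:6] <- 1 - 0.1
  diag(J) <- 1
  class(J) <- c("patient_similarity", "matrix")
  cl <- cluster_cohort(J, kmax = 4)
  expect_equal(cl$k, 2L)
  expect_equal(unname(cl$labels[1:3]), rep(cl$labels[[1]], 3))
  expect_equal(unname(cl$labels[4:6]), rep(cl$labels[[4]], 3))
  # silhouette oracle at k = 2: a(i) = 0.1, b(i) = 0.9 for every point
  sil2 <- cl$silhouette$avg_silhouette[cl$silhouette$k == 2]
  expect_equal(sil2, (0.9 - 0.1) / 0.9, tolerance = 1e-9)
  # all distances equal: silhouettes <= 0, smallest k wins the tie rule
  Jeq <- matrix(0.5, 6, 6, dimnames = list(ids, ids))
  diag(Jeq) <- 1
  class(Jeq) <- c("patient_similarity", "matrix")
  cleq <- cluster_cohort(Jeq, kmax = 4)
  expect_true(all(cleq$silhouette$avg_silhouette <= 0))
  expect_equal(cleq$k, 2L)
  expect_error(cluster_cohort(J, kmax = 6), "kmax")
})

test_that("cluster memberships are stable under patient permutation", {
  sc <- small_scenario()
  co <- simulate_cohort(sc$sim$truth, n_subgroups = 2, patients_per_subgroup = 4,
                        n_background_genes = 10, seed = 5)
  co <- suppressMessages(restrict_to_network(co, rownames(sc$traj)))
  sel <- select_cohort_genes(co, sc$traj, selection_params(0, 6))
  J <- patient_similarity(sel)
  cl1 <- cluster_cohort(J, kmax = 4)
  perm <- rev(rownames(J))
  Jp <- J[perm, perm]
  class(Jp) <- c("patient_similarity", "matrix")
  cl2 <- cluster_cohort(Jp, kmax = 4)
  expect_equal(cl2$k, cl1$k)
  expect_equal(adjusted_rand(cl1$labels[perm], cl2$labels[perm]), 1)
})

test_that("clustering scores match hand-computed accuracy and MCC", {
  # perfect 4-cluster match
  ref <- stats::setNames(rep(c("W", "S", "G3", "G4"), each = 3),
                         paste0("p", 1:12))
  perfect <- stats::setNames(rep(1:4, each = 3), paste0("p", 1:12))
  sc <- score_clustering(perfect, ref)
  expect_equal(sc$accuracy, 100)
  expect_equal(sc$mcc, 1)
  # one cluster of 3 X + 2 Y: accuracy 60, degenerate MCC -> 0
  ref2 <- stats::setNames(c("X", "X", "X", "Y", "Y"), paste0("p", 1:5))
  one <- stats::setNames(rep(1, 5), paste0("p", 1:5))
  sc2 <- score_clustering(one, ref2)
  expect_equal(sc2$accuracy, 60)
  expect_equal(sc2$mcc, 0)
  # one swapped patient out of 10
  ref3 <- stats::setNames(rep(c("A", "B"), each = 5), paste0("p", 1:10))
  cl3 <- stats::setNames(c(rep(1, 4), 2, rep(2, 5)), paste0("p", 1:10))
  expect_equal(score_clustering(cl3, ref3)$accuracy, 90)
  # invariance under cluster relabeling
  relab <- stats::setNames(c(7, 7, 7, 7, 3, 3, 3, 3, 3, 3)[c(1:4, 5, 6:10)],
                           paste0("p", 1:10))
  expect_equal(score_clustering(relab, ref3)$accuracy,
               score_clustering(cl3, ref3)$accuracy)
  expect_error(score_clustering(stats::setNames(1, "p1"),
                                stats::setNames("A", "p2")), "same patients")
})

test_that("macro accuracy averages per-class recall", {
  # 4 of class A correct, 0 of class B correct under majority mapping
  ref <- stats::setNames(c(rep("A", 4), rep("B", 2)), paste0("p", 1:6))
  cl <- stats::setNames(rep(1, 6), paste0("p", 1:6)) # all -> majority A
  sc <- score_clustering(cl, ref)
  expect_equal(sc$accuracy, 100 * 4 / 6)
  expect_equal(sc$macro_accuracy, 100 * mean(c(1, 0)))
})

test_that("parameter scans cover the grid and expose the optimum", {
  sc <- small_scenario()
  co <- simulate_cohort(sc$sim$truth, n_subgroups = 2, patients_per_subgroup = 4,
                        n_background_genes = 10, seed = 9)
  co <- suppressMessages(restrict_to_network(co, rownames(sc$traj)))
  scan <- optimize_parameters(co, sc$traj, theta_grid = 0:1,
                              lambda_grid = c(4, 6), kmax = 4)
  expect_equal(nrow(scan$results), 4)
  expect_s3_class(glance(scan), "tbl_df")
  expect_true(scan$best_score$accuracy >= 50)
  # 1x1 grid returns that pair
  scan1 <- optimize_parameters(co, sc$traj, theta_grid = 0, lambda_grid = 6,
                               kmax = 4)
  expect_equal(nrow(scan1$results), 1)
  expect_equal(scan1$best$theta, 0L)
  expect_equal(scan1$best$lambda, 6L)
  expect_error(optimize_parameters(co, sc$traj, integer(0), 2:3), "non-empty")
})

test_that("held-out patients inherit the cluster of their best match", {
  sc <- small_scenario()
  co <- simulate_cohort(sc$sim$truth, n_subgroups = 2, patients_per_subgroup = 4,
                        n_background_genes = 10, seed = 9)
  co <- suppressMessages(restrict_to_network(co, rownames(sc$traj)))
  scan <- optimize_parameters(co, sc$traj, theta_grid = 0, lambda_grid = 6,
                              kmax = 4)
  pid <- names(scan$selected_sets)[1]
  res <- classify_heldout(co$patients[[pid]], scan, sc$traj)
  expect_false(res$unclassifiable)
  expect_equal(res$ranking$jaccard[1], 1) # identical to training patient pid
  expect_equal(res$cluster, unname(scan$clustering$labels[pid]))
  expect_equal(nrow(res$ranking), length(scan$selected_sets))
  expect_true(all(diff(res$ranking$jaccard) <= 0))
})

test_that("selection summaries report reduction and unique genes", {
  co <- cohort(list(p1 = sprintf("g%03d", 1:100), p2 = sprintf("g%03d", 1:100),
                    p3 = sprintf("g%03d", 101:200)))
  sel <- list(p1 = sprintf("g%03d", 1:20), p2 = sprintf("g%03d", 1:20),
              p3 = sprintf("g%03d", 101:110))
  out <- selection_summary(co, sel, clusters = c(p1 = 1, p2 = 1, p3 = 2))
  expect_equal(out$per_patient$reduction_pct, c(80, 80, 90))
  expect_equal(out$summary$sd_selected, stats::sd(c(20, 20, 10)))
  # p1/p2 share all 20 genes, none of which appear in p3's selection
  expect_equal(out$unique_genes[["1"]], sprintf("g%03d", 1:20))
  expect_equal(out$unique_genes[["2"]], sprintf("g%03d", 101:110))
  # identical patients give zero SD
  out2 <- selection_summary(co, sel[c(1, 2)], clusters = NULL)
  expect_equal(out2$summary$sd_selected, 0)
  expect_null(out2$unique_genes)
})
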