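test_that("trajectory matrices are built from profiles and round trip", {
  sc <- small_scenario()
  traj <- sc$traj
  expect_s3_class(traj, "trajectory_matrix")
  expect_equal(rownames(traj), sc$profile$nodes)
  expect_equal(ncol(traj), length(sc$profile$grid))
  # column t equals partition t
  expect_equal(unname(traj[, 3]),
               unname(sc$profile$partitions[[3]]$membership[rownames(traj)]))
  # single-resolution profile gives a one-column matrix
  one <- resolution_sweep(two_triangles(), 1, seed = 1)
  expect_equal(ncol(build_trajectories(one)), 1)
  # TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(traj, path)
  back <- read_trajectories(path)
  expect_equal(unclass(back), unclass(traj))
  expect_equal(attr(back, "grid"), attr(traj, "grid"))
})

test_that("trajectory Hamming counts differing co-membership positions", {
  expect_equal(trajectory_hamming(c(1, 1, 2), c(1, 2, 2)), 1L)
  expect_equal(trajectory_hamming(1:5, 1:5), 0L)
  expect_equal(trajectory_hamming(rep(1, 10), rep(2, 10)), 10L)
  expect_equal(trajectory_hamming(c(1, 2), c(2, 1), normalize = TRUE), 1)
  expect_error(trajectory_hamming(1:3, 1:4), "length")
})

test_that("distance matrix matches the brute-force pairwise loop", {
  prof <- random_profile(20, 8, seed = 33)
  traj <- build_trajectories(prof)
  d <- trajectory_distances(traj)
  brute <- matrix(0, 20, 20)
  for (i in 1:20) for (j in 1:20) {
    brute[i, j] <- trajectory_hamming(traj[i, ], traj[j, ])
  }
  expect_equal(unname(d), brute)
  expect_error(trajectory_distances(traj, subset = "nope"), "not in")
  # two identical genes -> zero 2x2 block
  t2 <- trajectory_distances(traj, subset = rownames(traj)[1:2])
  expect_equal(dim(t2), c(2, 2))
  expect_equal(diag(t2), stats::setNames(c(0, 0), rownames(traj)[1:2]))
})

test_that("trajectory distance is a pseudometric invariant to relabeling", {
  for (sd in c(3, 14)) {
    prof <- random_profile(12, 6, seed = sd)
    traj <- build_trajectories(prof)
    d <- trajectory_distances(traj)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 6))
    # triangle inequality over all triples
    for (i in 1:12) for (j in 1:12) for (k in 1:12) {
      expect_lte(d[i, k], d[i, j] + d[j, k])
    }
    # per-column relabeling leaves distances unchanged
    relab <- traj
    withr::with_seed(sd + 1, {
      for (t in seq_len(ncol(relab))) {
        perm <- sample(100, max(relab[, t]))
        relab[, t] <- perm[relab[, t]]
      }
    })
    expect_equal(trajectory_distances(relab), d)
  }
})

test_that("community events follow the interval accounting", {
  # hand-built profile: track a community of {g1,g2} present at steps 1-2 and
  # 4-5 (end), absent at 3
  genes <- c("g1", "g2", "g3")
  memb_t <- list(
    c(1, 1, 2), c(1, 1, 2), c(1, 2, 2), c(1, 1, 2), c(1, 1, 2)
  )
  parts <- lapply(seq_along(memb_t), function(t) {
    structure(list(membership = stats::setNames(as.integer(memb_t[[t]]), genes),
                   gamma = t, quality = NA_real_, seed = 1),
              class = "partition")
  })
  prof <- structure(list(grid = as.numeric(1:5), partitions = parts,
                         seed = 1, nodes = genes),
                    class = "resolution_profile")
  ev <- community_events(prof)
  row <- ev[ev$community == "g1|g2", ]
  expect_equal(row$births, 2L)
  expect_equal(row$deaths, 1L) # alive at the end, no terminal death
  expect_equal(row$resurgences, 1L)
  evT <- community_events(prof, count_terminal = TRUE)
  expect_equal(evT[evT$community == "g1|g2", ]$deaths, 2L)
  # one-interval community: present at steps 1-2 only ({g3} as {g3})
  # {g3} exists at steps 1,2,4,5 -> intervals {1,2} and {4,5}
  row3 <- ev[ev$community == "g3", ]
  expect_equal(row3$births, 2L)
  expect_equal(row3$resurgences, 1L)
})

test_that("event accounting satisfies deaths - resurgences in {0, 1}", {
  for (sd in c(2, 9, 27)) {
    prof <- random_profile(10, 7, seed = sd)
    ev <- community_events(prof)
    gap <- ev$deaths - ev$resurgences
    expect_true(all(gap %in% c(0L, 1L)))
    expect_true(all(gap == 1L - ev$present_at_end))
    # total resurgences = total intervals - number of unique communities
    expect_equal(sum(ev$resurgences), sum(ev$intervals) - nrow(ev))
    # terminal convention adds exactly one death per end-surviving community
    evT <- community_events(prof, count_terminal = TRUE)
    expect_equal(sum(evT$deaths) - sum(ev$deaths), sum(ev$present_at_end))
  }
})

test_that("dendrograms follow average-linkage arithmetic and serialize", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  tree <- trajectory_dendrogram(d, linkage = "average")
  # first merge at height 2, then (4 + 6) / 2 = 5
  expect_equal(tree$height, c(2, 5))
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, c("g1", "g2", "g3"))
  # zero-distance pair merges first
  d0 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t0 <- trajectory_dendrogram(d0)
  expect_equal(t0$height[1], 0)
  expect_setequal(abs(t0$merge[1, ]), c(1, 2))
  expect_error(trajectory_dendrogram(matrix(0, 1, 1)), "at least 2")
})

test_that("event logs serialize to JSON with totals", {
  prof <- random_profile(8, 5, seed = 4)
  ev <- community_events(prof)
  js <- withr::local_tempfile(fileext = ".json")
  write_events(ev, js)
  back <- jsonlite::read_json(js)
  expect_equal(back$totals$communities, nrow(ev))
  expect_equal(back$totals$deaths, sum(ev$deaths))
})
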