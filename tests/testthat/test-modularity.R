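test_that("multiplex modularity reproduces hand-evaluated values", {
  tri <- two_triangles()
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  # one layer, two triangles: 2 x (3/6 - (6/12)^2)
  expect_equal(multiplex_modularity(tri, memb, 1), 0.5)
  # two identical layers: layer additivity doubles the value
  tri2 <- multiplex_network(dplyr::bind_rows(
    tibble::as_tibble(tri),
    dplyr::mutate(tibble::as_tibble(tri), layer = "L2")
  ))
  expect_equal(multiplex_modularity(tri2, memb, 1), 1.0)
  # gamma = 0, all nodes together: Q = number of layers
  expect_equal(multiplex_modularity(tri2, rep(1, 6), 0), 2)
  expect_equal(multiplex_modularity(tri, rep(1, 6), 0), 1)
})

test_that("modularity is invariant under community relabeling", {
  net <- bridged_triangles()
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  relab <- c(a = 9, b = 9, c = 9, d = 4, e = 4, f = 4)
  for (g in c(0.3, 1, 2.5)) {
    expect_equal(multiplex_modularity(net, memb, g),
                 multiplex_modularity(net, relab, g))
  }
})

test_that("identical layer copies multiply Q exactly", {
  withr::with_seed(5, {
    base <- tibble::tibble(
      layer = "L1",
      from = sprintf("n%d", sample(1:8, 12, replace = TRUE)),
      to = sprintf("n%d", sample(1:8, 12, replace = TRUE))
    )
    base <- base[base$from != base$to, ]
  })
  copies <- dplyr::bind_rows(lapply(1:3, function(s) {
    dplyr::mutate(base, layer = paste0("L", s))
  }))
  net1 <- multiplex_network(base)
  net3 <- multiplex_network(copies)
  memb <- stats::setNames(rep(1:2, length.out = length(net1$nodes)), net1$nodes)
  expect_equal(multiplex_modularity(net3, memb, 1.3),
               3 * multiplex_modularity(net1, memb, 1.3))
})

test_that("louvain attains the exhaustive maximum on the bridged triangles", {
  net <- bridged_triangles()
  part <- louvain_multiplex(net, 1, seed = 7)
  expect_equal(part$quality, multiplex_modularity(net, part$membership, 1))
  expect_equal(part$quality, exhaustive_max_modularity(net, 1))
  # the two triangles are the optimum
  expect_equal(unname(part$membership), c(1, 1, 1, 2, 2, 2))
})

test_that("louvain matches the exhaustive oracle on random tiny multiplexes", {
  for (sd in 1:5) {
    withr::with_seed(sd, {
      n <- 7
      e <- tibble::tibble(
        layer = sample(c("A", "B"), 12, replace = TRUE),
        from = sprintf("n%d", sample(n, 12, replace = TRUE)),
        to = sprintf("n%d", sample(n, 12, replace = TRUE))
      )
      e <- e[e$from != e$to, ]
    })
    net <- multiplex_network(e)
    # every layer must be represented for the modularity to be defined
    if (length(layer_names(net)) < 2) next
    part <- louvain_multiplex(net, 1, seed = sd)
    best <- exhaustive_max_modularity(net, 1)
    expect_gte(part$quality + 1e-9, multiplex_modularity(
      net, stats::setNames(seq_along(net$nodes), net$nodes), 1
    )) # at least as good as all-singletons
    expect_lte(part$quality, best + 1e-9)
  }
})

test_that("gamma = 0 merges any connected network into one community", {
  net <- bridged_triangles()
  part <- louvain_multiplex(net, 0, seed = 3)
  expect_equal(length(unique(part$membership)), 1L)
})

test_that("louvain recovers a 2-block planted multiplex exactly", {
  withr::with_seed(21, {
    n <- 30
    block <- rep(1:2, each = n / 2)
    edges <- list()
    for (lyr in c("L1", "L2")) {
      pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
      p <- ifelse(block[pairs[, 1]] == block[pairs[, 2]], 0.9, 0.05)
      hit <- stats::runif(nrow(pairs)) < p
      edges[[lyr]] <- tibble::tibble(
        layer = lyr,
        from = sprintf("n%02d", pairs[hit, 1]),
        to = sprintf("n%02d", pairs[hit, 2])
      )
    }
  })
  net <- multiplex_network(dplyr::bind_rows(edges),
                           nodes = sprintf("n%02d", 1:30))
  part <- louvain_multiplex(net, 1, seed = 4)
  truth <- rep(1:2, each = 15)
  expect_equal(adjusted_rand(part$membership[net$nodes], truth), 1)
})

test_that("quality trace is non-decreasing within a run", {
  sc <- small_scenario()
  part <- louvain_multiplex(sc$sim$network, 3, seed = 11)
  expect_true(all(diff(part$trace) > -1e-9))
})

test_that("resolution sweeps are deterministic and canonically labeled", {
  net <- bridged_triangles()
  expect_error(resolution_sweep(net, numeric(0)), "empty")
  expect_error(resolution_sweep(net, c(2, 1)), "increasing")
  p1 <- resolution_sweep(net, c(0.1, 1.0), seed = 5)
  p2 <- resolution_sweep(net, c(0.1, 1.0), seed = 5)
  expect_identical(
    lapply(p1$partitions, `[[`, "membership"),
    lapply(p2$partitions, `[[`, "membership")
  )
  ncom <- vapply(p1$partitions, function(p) length(unique(p$membership)), 1L)
  expect_equal(ncom, c(1L, 2L))
  # exhaustive check at each gamma
  for (t in 1:2) {
    expect_equal(p1$partitions[[t]]$quality,
                 exhaustive_max_modularity(net, p1$grid[t]))
  }
  # canonical ids: first node appearance order
  memb <- p1$partitions[[2]]$membership
  expect_equal(memb[["a"]], 1L)
  expect_equal(unname(memb[unique(names(memb))][c("a", "d")]), c(1L, 2L))
  # single-point grid
  expect_length(resolution_sweep(net, 1, seed = 1)$partitions, 1)
})

test_that("partition writer emits TSV plus JSON sidecar", {
  part <- louvain_multiplex(bridged_triangles(), 1, seed = 2)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_partition(part, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$node, names(part$membership))
  side <- jsonlite::read_json(paste0(tsv, ".json"))
  expect_equal(side$gamma, 1)
  expect_equal(side$seed, 2)
})

test_that("partition enumeration yields Bell-number many partitions", {
  expect_length(enumerate_partitions(3), 5)
  expect_length(enumerate_partitions(6), 203)
  expect_true(all(vapply(enumerate_partitions(4), `[`, 1L, 1) == 1L))
})
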