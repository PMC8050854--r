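# Shared fixtures, built in code. Expensive objects are cached per session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# two disjoint triangles, one layer
two_triangles <- function(layer = "L1") {
  multiplex_network(tibble::tibble(
    layer = layer,
    from = c("a", "a", "b", "d", "d", "e"),
    to   = c("b", "c", "c", "e", "f", "f")
  ))
}

# two triangles joined by a single bridge edge c-d
bridged_triangles <- function() {
  multiplex_network(tibble::tibble(
    layer = "L1",
    from = c("a", "a", "b", "d", "d", "e", "c"),
    to   = c("b", "c", "c", "e", "f", "f", "d")
  ))
}

# exhaustive-partition modularity oracle for tiny multiplex graphs
exhaustive_max_modularity <- function(net, gamma) {
  parts <- enumerate_partitions(length(net$nodes))
  max(vapply(parts, function(m) {
    multiplex_modularity(net, stats::setNames(m, net$nodes), gamma)
  }, 1.0))
}

# adjusted Rand index (independent implementation for recovery checks)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(as.vector(tab))
  e1 <- sum_comb(rowSums(tab))
  e2 <- sum_comb(colSums(tab))
  expected <- e1 * e2 / choose(n, 2)
  maxidx <- (e1 + e2) / 2
  if (maxidx == expected) return(1)
  (idx - expected) / (maxidx - expected)
}

# small planted multiplex + sweep, fast enough for unit tests
small_scenario <- function() {
  cached("small_scenario", function() {
    sim <- simulate_multiplex(
      n_genes = 80, n_modules = 2, submodules_per_module = 2, n_layers = 2,
      p_fine = 0.4, p_coarse = 0.06, p_background = 0.005,
      layer_dropout = 0, seed = 7
    )
    prof <- resolution_sweep(sim$network, 1:10, seed = 70)
    list(sim = sim, profile = prof, traj = build_trajectories(prof))
  })
}

# the default planted scenario used by the acceptance suite
default_scenario <- function() {
  cached("default_scenario", function() {
    sim <- simulate_multiplex(seed = 101)
    prof <- resolution_sweep(sim$network, seed = 1010)
    traj <- build_trajectories(prof)
    co <- simulate_cohort(sim$truth, seed = 102)
    co <- suppressMessages(restrict_to_network(co, rownames(traj)))
    list(sim = sim, profile = prof, traj = traj, cohort = co)
  })
}

# random resolution profile (arbitrary labels) for property tests
random_profile <- function(n_genes, T_, seed) {
  withr::with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    parts <- lapply(seq_len(T_), function(t) {
      memb <- sample.int(max(2, n_genes %/% 3), n_genes, replace = TRUE)
      memb <- as.integer(factor(memb, levels = unique(memb)))
      structure(list(membership = stats::setNames(memb, genes),
                     gamma = t, quality = NA_real_, seed = seed),
                class = "partition")
    })
    structure(list(grid = as.numeric(seq_len(T_)), partitions = parts,
                   seed = seed, nodes = genes),
              class = "resolution_profile")
  })
}
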