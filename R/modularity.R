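#' Multiplex modularity under a shared partition
#'
#' The quality of a single partition applied jointly to every layer of a
#' multiplex network: the sum over layers of the Newman-Girvan modularity of
#' that layer, with the resolution parameter `gamma` multiplying the null
#' (configuration-model) term identically in every layer,
#' \deqn{Q(c;\gamma)=\sum_s \frac{1}{2m_s}\sum_{ij}
#'   \left[A^{(s)}_{ij}-\gamma\frac{k^{(s)}_i k^{(s)}_j}{2m_s}\right]
#'   \delta(c_i,c_j).}
#' Layers are summed, not averaged; nodes absent from a layer have degree 0
#' there and contribute nothing to that layer's terms.
#'
#' @param net A `multiplex` network; every layer must have at least one edge.
#' @param membership Community assignment: an integer/character vector named
#'   by node, or unnamed in the order of `net$nodes`, covering every node.
#' @param gamma Resolution parameter, `>= 0`. Larger values favor more,
#'   smaller communities.
#' @param weighted If `FALSE` (default) every edge counts 1 regardless of its
#'   stored weight.
#' @return The modularity value (dimensionless).
#' @examples
#' tri2 <- multiplex_network(tibble::tibble(
#'   layer = "L1",
#'   from = c("a", "a", "b", "d", "d", "e"),
#'   to   = c("b", "c", "c", "e", "f", "f")
#' ))
#' multiplex_modularity(tri2, c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2), 1)
#' @export
multiplex_modularity <- function(net, membership, gamma, weighted = FALSE) {
  stopifnot(inherits(net, "multiplex"), is.numeric(gamma), length(gamma) == 1,
            gamma >= 0)
  if (nrow(net$edges) == 0) stop("network has no edges", call. = FALSE)
  memb <- align_membership(membership, net$nodes)
  lay <- as_layer_graphs(net, weighted = weighted)
  n <- length(net$nodes)
  Q <- 0
  for (g in lay) {
    m <- sum(g$w)
    k <- numeric(n)
    tab <- rowsum(c(g$w, g$w), c(g$i, g$j))
    k[as.integer(rownames(tab))] <- tab[, 1]
    within <- memb[g$i] == memb[g$j]
    w_in <- rowsum_by(g$w[within], memb[g$i][within])
    s_tot <- rowsum_by(k, memb)
    Q <- Q + sum(w_in) / m - gamma * sum((s_tot / (2 * m))^2)
  }
  Q
}

# membership vector -> integer codes aligned to `nodes` order
align_membership <- function(membership, nodes) {
  if (!is.null(names(membership))) {
    missing <- setdiff(nodes, names(membership))
    if (length(missing)) {
      stop("membership missing for node(s): ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    stop("membership must cover every node", call. = FALSE)
  }
  as.integer(factor(membership))
}

# grouped sums of a numeric vector (dense result, arbitrary integer groups)
rowsum_by <- function(x, g) {
  if (!length(x)) return(numeric(0))
  tab <- rowsum(x, g)
  tab[, 1]
}

# per-layer integer edge arrays (i < j) over node indices
as_layer_graphs <- function(net, weighted = FALSE) {
  idx <- stats::setNames(seq_along(net$nodes), net$nodes)
  lapply(split(net$edges, net$edges$layer), function(e) {
    list(
      i = unname(idx[e$from]),
      j = unname(idx[e$to]),
      w = if (weighted) e$weight else rep(1, nrow(e))
    )
  })
}

#' Louvain community detection on a multiplex network
#'
#' Greedy maximization of [multiplex_modularity()]: seeded random node visit
#' order; each node moves to the neighboring community with the largest
#' positive modularity gain (ties broken by the smallest community id); once
#' no single move improves the quality by more than `1e-12`, communities are
#' contracted to super-nodes in every layer simultaneously and the procedure
#' repeats until the partition is stable. The result is deterministic given
#' `seed`.
#'
#' @inheritParams multiplex_modularity
#' @param seed Integer seed controlling the node visit order.
#' @return An object of class `partition`: list with `membership` (named
#'   integer vector, community ids renumbered by first appearance in node
#'   order), `gamma`, `quality` (the multiplex modularity of the membership),
#'   `seed`, and `trace` (quality after each local-move pass, non-decreasing).
#' @export
louvain_multiplex <- function(net, gamma, seed = 1L, weighted = FALSE) {
  stopifnot(inherits(net, "multiplex"), gamma >= 0)
  if (nrow(net$edges) == 0) stop("network has no edges", call. = FALSE)
  n0 <- length(net$nodes)
  lay <- as_layer_graphs(net, weighted = weighted)
  L <- length(lay)
  selfw <- matrix(0, n0, L)
  assign0 <- seq_len(n0) # original node -> current supernode
  trace <- numeric(0)
  withr::with_seed(as.integer(seed), {
    repeat {
      n <- nrow(selfw)
      res <- louvain_local_move(lay, selfw, gamma)
      trace <- c(trace, res$trace)
      comm <- res$comm
      nc <- length(unique(comm))
      if (nc == n) break
      comm <- as.integer(factor(comm, levels = unique(comm)))
      assign0 <- comm[assign0]
      agg <- contract_layers(lay, selfw, comm, nc)
      lay <- agg$lay
      selfw <- agg$selfw
      if (nc == 1) break
    }
  })
  memb <- as.integer(factor(assign0, levels = unique(assign0)))
  names(memb) <- net$nodes
  structure(
    list(
      membership = memb, gamma = gamma,
      quality = multiplex_modularity(net, memb, gamma, weighted = weighted),
      seed = as.integer(seed), trace = trace
    ),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat("A partition: ", length(unique(x$membership)), " communities over ",
      length(x$membership), " nodes (gamma = ", format(x$gamma),
      ", Q = ", format(x$quality, digits = 6), ")\n", sep = "")
  invisible(x)
}

# One level of seeded greedy local moves on the current supergraph.
# `lay` holds i<j edge arrays (no self-edges); `selfw` the per-node internal
# weight per layer carried over from contraction.
louvain_local_move <- function(lay, selfw, gamma) {
  n <- nrow(selfw)
  L <- length(lay)
  m <- numeric(L)
  K <- matrix(0, n, L)
  csr <- vector("list", L)
  for (s in seq_len(L)) {
    e <- lay[[s]]
    m[s] <- sum(e$w) + sum(selfw[, s])
    k <- numeric(n)
    if (length(e$i)) {
      tab <- rowsum(c(e$w, e$w), c(e$i, e$j))
      k[as.integer(rownames(tab))] <- tab[, 1]
    }
    K[, s] <- k + 2 * selfw[, s]
    ii <- c(e$i, e$j); jj <- c(e$j, e$i); ww <- c(e$w, e$w)
    ord <- order(ii)
    cnt <- tabulate(ii, nbins = n)
    csr[[s]] <- list(ptr = c(0L, cumsum(cnt)), j = jj[ord], w = ww[ord])
  }
  inv2m2 <- gamma / (2 * m^2)
  comm <- seq_len(n)
  Stot <- K # singleton initialization: one community per node
  trace <- numeric(0)
  repeat {
    moved <- 0L
    for (v in sample.int(n)) {
      kv <- K[v, ]
      a <- comm[v]
      # edge gains to candidate communities, summed over layers
      cand <- a
      gain <- 0
      for (s in seq_len(L)) {
        p <- csr[[s]]$ptr
        if (p[v + 1L] == p[v]) next
        rng <- (p[v] + 1L):p[v + 1L]
        cc <- comm[csr[[s]]$j[rng]]
        gv <- rowsum_by(csr[[s]]$w[rng] / m[s], cc)
        ids <- as.integer(names(gv))
        pos <- match(ids, cand)
        new <- is.na(pos)
        if (any(new)) {
          cand <- c(cand, ids[new])
          gain <- c(gain, unname(gv[new]))
          pos[new] <- length(cand) - rev(seq_len(sum(new))) + 1L
        }
        old <- !new
        if (any(old)) gain[pos[old]] <- gain[pos[old]] + unname(gv[old])
      }
      # remove v from its community, then score candidates
      Stot[a, ] <- Stot[a, ] - kv
      null_term <- as.numeric(Stot[cand, , drop = FALSE] %*% (kv * inv2m2))
      score <- gain - null_term
      ord <- order(cand)
      best <- ord[which.max(score[ord])] # ties -> smallest community id
      stay <- score[match(a, cand)]
      if (cand[best] != a && score[best] > stay + 1e-12) {
        comm[v] <- cand[best]
        Stot[cand[best], ] <- Stot[cand[best], ] + kv
        moved <- moved + 1L
      } else {
        Stot[a, ] <- Stot[a, ] + kv
      }
    }
    trace <- c(trace, supergraph_quality(lay, selfw, comm, gamma, m))
    if (moved == 0L) break
  }
  list(comm = comm, trace = trace)
}

# modularity of the current supergraph partition (selfw = internal weights)
supergraph_quality <- function(lay, selfw, comm, gamma, m) {
  Q <- 0
  for (s in seq_along(lay)) {
    e <- lay[[s]]
    within <- e$w[comm[e$i] == comm[e$j]]
    w_in <- sum(within) + sum(selfw[, s])
    k <- numeric(nrow(selfw))
    if (length(e$i)) {
      tab <- rowsum(c(e$w, e$w), c(e$i, e$j))
      k[as.integer(rownames(tab))] <- tab[, 1]
    }
    k <- k + 2 * selfw[, s]
    s_tot <- rowsum_by(k, comm)
    Q <- Q + w_in / m[s] - gamma * sum((s_tot / (2 * m[s]))^2)
  }
  Q
}

# contract communities into supernodes across all layers
contract_layers <- function(lay, selfw, comm, nc) {
  L <- length(lay)
  new_selfw <- matrix(0, nc, L)
  new_lay <- vector("list", L)
  names(new_lay) <- names(lay)
  for (s in seq_len(L)) {
    e <- lay[[s]]
    ci <- comm[e$i]; cj <- comm[e$j]
    inside <- ci == cj
    int_w <- rowsum_by(e$w[inside], ci[inside])
    if (length(int_w)) {
      new_selfw[as.integer(names(int_w)), s] <- int_w
    }
    carried <- rowsum_by(selfw[, s], comm)
    new_selfw[as.integer(names(carried)), s] <-
      new_selfw[as.integer(names(carried)), s] + carried
    lo <- pmin(ci, cj)[!inside]; hi <- pmax(ci, cj)[!inside]
    if (length(lo)) {
      key <- (lo - 1) * nc + hi
      agg <- rowsum_by(e$w[!inside], key)
      k2 <- as.numeric(names(agg))
      new_lay[[s]] <- list(
        i = as.integer((k2 - 1) %/% nc + 1),
        j = as.integer((k2 - 1) %% nc + 1),
        w = unname(agg)
      )
    } else {
      new_lay[[s]] <- list(i = integer(0), j = integer(0), w = numeric(0))
    }
  }
  list(lay = new_lay, selfw = new_selfw)
}

#' Sweep the modularity resolution over a grid
#'
#' Runs [louvain_multiplex()] once per resolution value, with per-value seeds
#' derived from `seed` (`seed + index`), and canonicalizes every partition
#' (communities renumbered by first-node appearance). The ordered collection
#' of partitions is the substrate for per-gene community trajectories.
#'
#' @inheritParams louvain_multiplex
#' @param grid Strictly increasing vector of resolution values, all `>= 0`.
#'   Defaults to `1:20`.
#' @return An object of class `resolution_profile`: list with `grid`,
#'   `partitions` (list of `partition`), `seed` and `nodes`.
#' @export
resolution_sweep <- function(net, grid = 1:20, seed = 1L, weighted = FALSE) {
  stopifnot(inherits(net, "multiplex"))
  if (length(grid) == 0) stop("empty resolution grid", call. = FALSE)
  if (any(grid < 0) || any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing and non-negative", call. = FALSE)
  }
  parts <- purrr::map(seq_along(grid), function(t) {
    louvain_multiplex(net, grid[t], seed = as.integer(seed) + t, weighted = weighted)
  })
  structure(
    list(grid = as.numeric(grid), partitions = parts,
         seed = as.integer(seed), nodes = net$nodes),
    class = "resolution_profile"
  )
}

#' @export
print.resolution_profile <- function(x, ...) {
  ncom <- vapply(x$partitions, function(p) length(unique(p$membership)), 1L)
  cat("A resolution profile: ", length(x$grid), " resolutions over ",
      length(x$nodes), " nodes; communities ", min(ncom), "-", max(ncom),
      "\n", sep = "")
  invisible(x)
}

#' @method tidy resolution_profile
#' @export
tidy.resolution_profile <- function(x, ...) {
  tibble::tibble(
    gamma = rep(x$grid, each = length(x$nodes)),
    node = rep(x$nodes, length(x$grid)),
    community = unlist(lapply(x$partitions, function(p) unname(p$membership)))
  )
}

#' @method glance resolution_profile
#' @export
glance.resolution_profile <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_resolutions = length(x$grid),
    gamma_min = min(x$grid),
    gamma_max = max(x$grid),
    seed = x$seed
  )
}

#' Write a partition as TSV plus a JSON sidecar
#' @param part A `partition`.
#' @param path TSV output path (`node`, `community`); `<path>.json` receives
#'   gamma, quality and seed.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "partition"))
  readr::write_tsv(
    tibble::tibble(node = names(part$membership),
                   community = unname(part$membership)),
    path
  )
  jsonlite::write_json(
    list(gamma = part$gamma, quality = part$quality, seed = part$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Enumerate all set partitions of n items
#'
#' Exhaustive enumeration via restricted growth strings, intended as a
#' brute-force oracle for community detection on tiny graphs (Bell numbers
#' grow fast; `n <= 10` is practical).
#'
#' @param n Number of items (`1 <= n <= 12`).
#' @return List of integer membership vectors of length `n` (canonical: first
#'   item is always in community 1).
#' @export
enumerate_partitions <- function(n) {
  stopifnot(n >= 1, n <= 12)
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(maxid + 1L)) {
      rec(c(prefix, c), max(maxid, c))
    }
  }
  rec(1L, 1L)
  out
}
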