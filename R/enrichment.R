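#' Network enrichment analysis test (NEAT) within one layer
#'
#' Tests whether the number of layer edges linking gene set A to gene set B
#' exceeds the expectation of a degree-preserving null. With `m` the layer's
#' edge count, `dA` and `dB` the summed layer degrees of A and B, the number
#' of A-B cross-links follows `Hypergeometric(2m, dB, dA)` under the null
#' (each of A's `dA` endpoint slots falls on one of the layer's `2m` slots,
#' `dB` of which belong to B); the expected value is `dA * dB / (2m)` and the
#' reported p is the upper tail `P(X >= n_AB)`.
#'
#' @param net A `multiplex` network.
#' @param layer Layer name.
#' @param setA,setB Gene sets (character vectors); intersected with the node
#'   universe. An overlap of B with A is removed from B with a warning
#'   (or an error when `strict = TRUE`).
#' @param strict Error on overlapping A and B instead of trimming B.
#' @return Tibble with one row: `n_ab` (observed cross-links), `mu`
#'   (expectation), `p` (upper-tail), `d_a`, `d_b`, `m`.
#' @examples
#' net <- multiplex_network(tibble::tibble(
#'   layer = "L", from = c("a", "b", "c"), to = c("x", "x", "y")
#' ))
#' neat_test(net, "L", c("a", "b"), "x") # p = 1/15
#' @export
neat_test <- function(net, layer, setA, setB, strict = FALSE) {
  stopifnot(inherits(net, "multiplex"))
  edges <- layer_edges(net, layer)
  m <- nrow(edges)
  if (m < 1) stop("layer has no edges", call. = FALSE)
  A <- intersect(unique(setA), net$nodes)
  B <- intersect(unique(setB), net$nodes)
  if (length(A) == 0 || length(B) == 0) {
    stop("gene set empty after intersection with the node universe", call. = FALSE)
  }
  overlap <- intersect(A, B)
  if (length(overlap)) {
    if (strict) stop("sets A and B overlap", call. = FALSE)
    warning(length(overlap), " gene(s) shared by A and B removed from B",
            call. = FALSE)
    B <- setdiff(B, A)
    if (length(B) == 0) stop("set B empty after removing the overlap with A",
                             call. = FALSE)
  }
  deg <- table(c(edges$from, edges$to))
  d_a <- sum(deg[A], na.rm = TRUE)
  d_b <- sum(deg[B], na.rm = TRUE)
  if (d_b == 0) stop("set B has zero degree in layer ", layer, call. = FALSE)
  if (d_a == 0) stop("set A has zero degree in layer ", layer, call. = FALSE)
  n_ab <- sum((edges$from %in% A & edges$to %in% B) |
                (edges$from %in% B & edges$to %in% A))
  mu <- d_a * d_b / (2 * m)
  p <- stats::phyper(n_ab - 1, d_b, 2 * m - d_b, d_a, lower.tail = FALSE)
  tibble::tibble(n_ab = as.integer(n_ab), mu = mu, p = p,
                 d_a = as.integer(d_a), d_b = as.integer(d_b), m = as.integer(m))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment, order-preserving.
#'
#' @param pvalues Numeric vector of raw p values in (0, 1].
#' @return Adjusted p values, same order, each `>=` its raw value.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-patient, per-layer link enrichment of minimal gene sets
#'
#' Runs [neat_test()] for every combination of patient, layer and entity:
#' A is the patient's selected minimal gene set, B the entity's gene set
#' from the entity map, tested within the entity's layer. Raw p values are
#' BH-adjusted per patient within each layer (across that layer's entities).
#' Untestable combinations (zero-degree or empty sets) are skipped.
#'
#' @param net A `multiplex` network.
#' @param selected_sets Named list patient -> selected genes.
#' @param entity_map Tibble (`layer`, `entity`, `gene`), see
#'   [load_entity_map()].
#' @return Tibble of enrichment records: `patient`, `layer`, `entity`,
#'   `n_ab`, `mu`, `p`, `p_adj`.
#' @export
enrich_cohort <- function(net, selected_sets, entity_map) {
  stopifnot(inherits(net, "multiplex"))
  combos <- dplyr::distinct(entity_map[, c("layer", "entity")])
  rows <- list()
  for (pid in names(selected_sets)) {
    A <- selected_sets[[pid]]
    if (length(A) == 0) next
    for (i in seq_len(nrow(combos))) {
      lyr <- combos$layer[i]
      ent <- combos$entity[i]
      B <- entity_genes(entity_map, lyr, ent)
      rec <- tryCatch(
        suppressWarnings(neat_test(net, lyr, A, B)),
        error = function(e) NULL
      )
      if (is.null(rec)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        patient = pid, layer = lyr, entity = ent,
        n_ab = rec$n_ab, mu = rec$mu, p = rec$p
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(tibble::tibble(
    patient = character(), layer = character(), entity = character(),
    n_ab = integer(), mu = numeric(), p = numeric(), p_adj = numeric()
  ))
  out |>
    dplyr::group_by(.data$patient, .data$layer) |>
    dplyr::mutate(p_adj = bh_adjust(.data$p)) |>
    dplyr::ungroup()
}

#' Consensus and unique enrichments per patient cluster
#'
#' An entity is CONSENSUS in a cluster when its adjusted p is `<= alpha` for
#' every patient of that cluster (within the entity's layer); it is UNIQUE
#' to the cluster when it is consensus there and in no other cluster.
#' Patients lacking a record for an entity count as not enriched.
#'
#' @param records Enrichment records from [enrich_cohort()].
#' @param clusters Named cluster labels covering the records' patients.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Tibble (`cluster`, `layer`, `entity`, `consensus`, `unique`),
#'   consensus rows only.
#' @export
consensus_enrichment <- function(records, clusters, alpha = 0.05) {
  if (nrow(records) == 0) stop("no enrichment records", call. = FALSE)
  missing <- setdiff(unique(records$patient), names(clusters))
  if (length(missing)) {
    stop("no cluster label for patient(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  sizes <- table(clusters[unique(records$patient)])
  if (any(sizes == 0)) stop("cluster with zero tested patients", call. = FALSE)
  recs <- dplyr::mutate(records,
                        cluster = as.character(clusters[.data$patient]),
                        hit = .data$p_adj <= alpha)
  per <- recs |>
    dplyr::group_by(.data$cluster, .data$layer, .data$entity) |>
    dplyr::summarise(
      n_hit = sum(.data$hit), n_patients = dplyr::n_distinct(.data$patient),
      .groups = "drop"
    ) |>
    dplyr::mutate(cluster_size = as.integer(sizes[.data$cluster]),
                  consensus = .data$n_hit == .data$cluster_size &
                    .data$n_patients == .data$cluster_size)
  cons <- dplyr::filter(per, .data$consensus)
  cons <- cons |>
    dplyr::group_by(.data$layer, .data$entity) |>
    dplyr::mutate(unique = dplyr::n() == 1) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", "layer", "entity", "consensus", "unique")
  dplyr::arrange(cons, .data$cluster, .data$layer, .data$entity)
}
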