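#' Construct a multiplex network
#'
#' A multiplex network is a set of named undirected layers sharing one node
#' universe (genes). Edges are unordered node pairs with an optional positive
#' weight and an optional annotation label (an entity id such as a drug,
#' pathway or disease responsible for the edge).
#'
#' Self-loops are dropped with a warning; duplicate unordered pairs within a
#' layer are collapsed by summing their weights (the first non-missing
#' annotation is kept).
#'
#' @param edges A data frame with columns `layer`, `from`, `to` and optional
#'   `weight` (positive numeric, default 1) and `entity` (character).
#' @param nodes Optional character vector extending the node universe beyond
#'   the union of edge endpoints (isolated nodes are allowed).
#' @return An object of class `multiplex`: a list with `nodes` (character
#'   vector) and `edges` (a tibble with columns `layer`, `from`, `to`,
#'   `weight`, `entity`, with `from < to` within each pair).
#' @examples
#' net <- multiplex_network(tibble::tibble(
#'   layer = c("ppi", "ppi", "pathway"),
#'   from  = c("a", "b", "a"),
#'   to    = c("b", "c", "c")
#' ))
#' layer_names(net)
#' @export
multiplex_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  required <- c("layer", "from", "to")
  if (!all(required %in% names(edges))) {
    stop("`edges` must have columns layer, from, to", call. = FALSE)
  }
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (!"entity" %in% names(edges)) edges$entity <- NA_character_
  edges <- dplyr::mutate(
    edges,
    layer = as.character(.data$layer),
    from = as.character(.data$from),
    to = as.character(.data$to),
    weight = dplyr::coalesce(as.numeric(.data$weight), 1),
    entity = as.character(.data$entity)
  )
  if (anyNA(edges$layer) || anyNA(edges$from) || anyNA(edges$to)) {
    stop("layer, from and to must not contain missing values", call. = FALSE)
  }
  if (any(!is.finite(edges$weight)) || any(edges$weight <= 0)) {
    stop("edge weights must be positive and finite", call. = FALSE)
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical unordered pair: from < to
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges |>
    dplyr::group_by(.data$layer, .data$from, .data$to) |>
    dplyr::summarise(
      weight = sum(.data$weight),
      entity = dplyr::first(stats::na.omit(.data$entity), default = NA_character_),
      .groups = "drop"
    )
  universe <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  structure(
    list(nodes = universe, edges = edges[order(edges$layer, edges$from, edges$to), ]),
    class = "multiplex"
  )
}

#' @export
print.multiplex <- function(x, ...) {
  counts <- dplyr::count(x$edges, .data$layer)
  cat("A multiplex network: ", length(x$nodes), " nodes, ",
      nrow(counts), " layer(s)\n", sep = "")
  for (i in seq_len(nrow(counts))) {
    cat("  ", counts$layer[i], ": ", counts$n[i], " edges\n", sep = "")
  }
  invisible(x)
}

#' Layer names of a multiplex network
#' @param net A `multiplex` object.
#' @return Character vector of layer names, in sorted order.
#' @export
layer_names <- function(net) {
  stopifnot(inherits(net, "multiplex"))
  sort(unique(net$edges$layer))
}

#' Edges of one layer
#' @param net A `multiplex` object.
#' @param layer Layer name.
#' @return Tibble of the layer's edges (`from`, `to`, `weight`, `entity`).
#' @export
layer_edges <- function(net, layer) {
  stopifnot(inherits(net, "multiplex"))
  if (!layer %in% net$edges$layer) {
    stop("unknown layer: ", layer, call. = FALSE)
  }
  dplyr::select(
    dplyr::filter(net$edges, .data$layer == !!layer),
    -"layer"
  )
}

#' @method as_tibble multiplex
#' @export
as_tibble.multiplex <- function(x, ...) x$edges

#' Read a multiplex network from edge-list files
#'
#' Accepts either a single TSV with columns `layer`, `source`, `target`
#' (optionally `weight`, `annotation`), or several per-layer TSVs with columns
#' `source`, `target` (optionally `weight`, `annotation`), one file per layer.
#' A header row is detected and skipped if the first field is `layer` (single
#' file) or `source` (per-layer files). A fourth numeric column is read as the
#' weight; a non-numeric fourth column is read as the annotation.
#'
#' @param path Path to the combined TSV, or a character vector of per-layer
#'   TSV paths.
#' @param layer_names Layer names when `path` has several files; defaults to
#'   the file base names.
#' @param nodes_path Optional path to a one-column file listing additional
#'   nodes (the node universe is their union with all edge endpoints).
#' @return A validated [multiplex_network()] object.
#' @export
load_multiplex <- function(path, layer_names = NULL, nodes_path = NULL) {
  stopifnot(length(path) >= 1)
  for (p in path) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (length(path) == 1 && is.null(layer_names)) {
    edges <- read_edge_file(path, with_layer = TRUE)
  } else {
    if (is.null(layer_names)) {
      layer_names <- sub("\\.[^.]*$", "", basename(path))
    }
    stopifnot(length(layer_names) == length(path))
    edges <- purrr::map2_dfr(path, layer_names, function(p, nm) {
      dplyr::mutate(read_edge_file(p, with_layer = FALSE), layer = nm)
    })
  }
  extra <- NULL
  if (!is.null(nodes_path)) {
    extra <- readr::read_lines(nodes_path)
    extra <- extra[nzchar(extra)]
  }
  multiplex_network(edges, nodes = extra)
}

# Parse one edge-list TSV; errors mention 1-based line numbers.
read_edge_file <- function(path, with_layer) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0) stop("empty edge list: ", path, call. = FALSE)
  min_cols <- if (with_layer) 3L else 2L
  if (ncol(raw) < min_cols) {
    stop("malformed edge list ", path, ": expected >= ", min_cols,
         " tab-separated columns", call. = FALSE)
  }
  first <- tolower(raw[[1]][1])
  skipped_header <- identical(first, if (with_layer) "layer" else "source")
  if (skipped_header) raw <- raw[-1, , drop = FALSE]
  core <- if (with_layer) {
    tibble::tibble(layer = raw[[1]], from = raw[[2]], to = raw[[3]])
  } else {
    tibble::tibble(from = raw[[1]], to = raw[[2]])
  }
  bad <- which(is.na(core$from) | is.na(core$to) |
                 !nzchar(core$from) | !nzchar(core$to) |
                 (if (with_layer) is.na(core$layer) else FALSE))
  if (length(bad)) {
    stop("malformed row(s) in ", path, " at line(s): ",
         paste(utils::head(bad + skipped_header, 5), collapse = ", "),
         call. = FALSE)
  }
  if (ncol(raw) >= min_cols + 1L) {
    col4 <- raw[[min_cols + 1L]]
    num4 <- suppressWarnings(as.numeric(col4))
    if (all(is.na(col4) | !is.na(num4))) {
      core$weight <- ifelse(is.na(num4), 1, num4)
      if (ncol(raw) >= min_cols + 2L) core$entity <- raw[[min_cols + 2L]]
    } else {
      core$entity <- col4
    }
  }
  core
}

#' Write a multiplex network as a combined TSV edge list
#'
#' The file has header `layer`, `source`, `target`, `weight`, `annotation`,
#' UTF-8, tab-separated; [load_multiplex()] reads it back unchanged.
#'
#' @param net A `multiplex` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multiplex <- function(net, path) {
  stopifnot(inherits(net, "multiplex"))
  out <- dplyr::transmute(
    net$edges,
    layer = .data$layer, source = .data$from, target = .data$to,
    weight = .data$weight, annotation = .data$entity
  )
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Read a per-layer entity map
#'
#' An entity map links named entities (drugs, pathways, diseases, metabolites)
#' to the genes they touch within one layer. Expected columns: `layer`,
#' `entity`, `gene` (TSV, header optional).
#'
#' @param path TSV path.
#' @return Tibble with columns `layer`, `entity`, `gene` (class `entity_map`).
#' @export
load_entity_map <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (ncol(raw) < 3) stop("entity map needs columns layer, entity, gene", call. = FALSE)
  if (identical(tolower(raw[[1]][1]), "layer")) raw <- raw[-1, , drop = FALSE]
  out <- tibble::tibble(layer = raw[[1]], entity = raw[[2]], gene = raw[[3]])
  out <- dplyr::distinct(out)
  class(out) <- c("entity_map", class(out))
  out
}

#' Genes mapped to one entity in one layer
#' @param map An entity map tibble (`layer`, `entity`, `gene`).
#' @param layer,entity Layer and entity ids.
#' @return Character vector of gene ids.
#' @export
entity_genes <- function(map, layer, entity) {
  hit <- map$layer == layer & map$entity == entity
  unique(map$gene[hit])
}
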