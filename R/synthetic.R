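#' Simulate a multiplex network with planted nested communities
#'
#' Generates `n_layers` independent layers over one node universe with two
#' nested scales of planted structure: genes are partitioned into modules,
#' each split into submodules. Within each layer, node pairs are connected
#' independently with probability `p_fine` (same submodule), `p_coarse`
#' (same module, different submodules) or `p_background` (different
#' modules). To create layer heterogeneity, each submodule is silenced per
#' layer with probability `layer_dropout`: its within-submodule pairs are
#' then sampled at `p_coarse` instead of `p_fine`.
#'
#' The defaults emulate the regime the pipeline is designed for: a sweep of
#' the default resolution grid resolves the whole graph, then the modules,
#' then the submodules, and finally fragments the submodules into small
#' persistent gene groups — the substrate of the (theta, lambda) selection.
#'
#' @param n_genes Number of genes (default 300).
#' @param n_modules Coarse modules (default 4).
#' @param submodules_per_module Fine submodules per module (default 3).
#' @param n_layers Layers (default 3).
#' @param p_fine,p_coarse,p_background Edge probabilities,
#'   `p_fine > p_coarse > p_background >= 0` (defaults 0.3 / 0.05 / 0.003).
#' @param layer_dropout Per-layer probability of silencing a submodule
#'   (default 0.1).
#' @param seed Integer seed; the network is deterministic given the seed.
#' @return List with `network` (a `multiplex`) and `truth` (class
#'   `planted_truth`): tibble gene / module / submodule, plus the generator
#'   parameters and the per-layer silenced submodules.
#' @export
simulate_multiplex <- function(n_genes = 300L, n_modules = 4L,
                               submodules_per_module = 3L, n_layers = 3L,
                               p_fine = 0.3, p_coarse = 0.05,
                               p_background = 0.003, layer_dropout = 0.1,
                               seed = 1L) {
  probs <- c(p_fine, p_coarse, p_background, layer_dropout)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!(p_fine > p_coarse && p_coarse >= p_background)) {
    stop("need p_fine > p_coarse >= p_background", call. = FALSE)
  }
  stopifnot(n_layers >= 1)
  genes <- sprintf("g%04d", seq_len(n_genes))
  n_sub <- n_modules * submodules_per_module
  submodule <- rep(seq_len(n_sub), length.out = n_genes)
  submodule <- sort(submodule)
  module <- (submodule - 1L) %/% submodules_per_module + 1L
  truth <- tibble::tibble(gene = genes, module = module, submodule = submodule)
  pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  same_sub <- submodule[i] == submodule[j]
  same_mod <- module[i] == module[j]
  silenced <- matrix(FALSE, n_layers, n_sub)
  edge_rows <- vector("list", n_layers)
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(n_layers)) {
      silenced[s, ] <- stats::runif(n_sub) < layer_dropout
      p_pair <- ifelse(
        same_sub & !silenced[s, submodule[i]], p_fine,
        ifelse(same_mod, p_coarse, p_background)
      )
      hit <- stats::runif(length(p_pair)) < p_pair
      edge_rows[[s]] <- tibble::tibble(
        layer = sprintf("layer%d", s),
        from = genes[i[hit]], to = genes[j[hit]]
      )
    }
  })
  net <- multiplex_network(dplyr::bind_rows(edge_rows), nodes = genes)
  truth <- structure(
    list(
      assignment = truth,
      silenced = silenced,
      params = list(
        n_genes = n_genes, n_modules = n_modules,
        submodules_per_module = submodules_per_module, n_layers = n_layers,
        p_fine = p_fine, p_coarse = p_coarse, p_background = p_background,
        layer_dropout = layer_dropout, seed = as.integer(seed)
      )
    ),
    class = "planted_truth"
  )
  list(network = net, truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  p <- x$params
  cat("Planted truth: ", p$n_genes, " genes, ", p$n_modules, " modules x ",
      p$submodules_per_module, " submodules, ", p$n_layers, " layers\n",
      sep = "")
  invisible(x)
}

#' Simulate a cohort with subgroup-specific signature modules
#'
#' Each subgroup owns a disjoint set of signature submodules; a patient's
#' altered genes are its subgroup's signature genes (each kept independently
#' with probability `1 - signature_dropout`) plus `n_background_genes` drawn
#' uniformly, without replacement, from the genes of non-signature
#' submodules.
#'
#' @param truth A `planted_truth` from [simulate_multiplex()].
#' @param n_subgroups Number of subgroups (default 4).
#' @param patients_per_subgroup Patients per subgroup (default 8).
#' @param signature_dropout Per-gene dropout within the signature
#'   (default 0.1).
#' @param n_background_genes Background genes per patient (default 40).
#' @param signatures Optional named list subgroup -> submodule ids; the
#'   default assigns `floor(n_submodules / (n_subgroups + 1))`-free split:
#'   two submodules per subgroup when 12 submodules serve 4 subgroups,
#'   leaving the rest as background-only.
#' @param seed Integer seed.
#' @return A labeled [cohort()] (labels `S1`, `S2`, ...), with the signature
#'   assignment in attribute `signatures`.
#' @export
simulate_cohort <- function(truth, n_subgroups = 4L, patients_per_subgroup = 8L,
                            signature_dropout = 0.1, n_background_genes = 40L,
                            signatures = NULL, seed = 1L) {
  stopifnot(inherits(truth, "planted_truth"))
  stopifnot(signature_dropout >= 0, signature_dropout <= 1)
  asg <- truth$assignment
  n_sub <- max(asg$submodule)
  if (is.null(signatures)) {
    per <- max(1L, (n_sub - n_subgroups) %/% n_subgroups) # keep some background
    per <- min(per, n_sub %/% n_subgroups)
    signatures <- lapply(seq_len(n_subgroups), function(g) {
      ((g - 1L) * per + 1L):(g * per)
    })
    names(signatures) <- sprintf("S%d", seq_len(n_subgroups))
  }
  if (anyDuplicated(unlist(signatures))) {
    stop("signature submodules must be disjoint across subgroups", call. = FALSE)
  }
  sig_subs <- unlist(signatures)
  background_pool <- asg$gene[!asg$submodule %in% sig_subs]
  if (n_background_genes > length(background_pool)) {
    stop("not enough non-signature genes for the background draw", call. = FALSE)
  }
  if (signature_dropout >= 1 && n_background_genes == 0) {
    stop("dropout 1 with no background genes yields empty patients", call. = FALSE)
  }
  patients <- list()
  labels <- character(0)
  withr::with_seed(as.integer(seed), {
    for (g in seq_along(signatures)) {
      sub <- names(signatures)[g]
      sig_genes <- asg$gene[asg$submodule %in% signatures[[g]]]
      for (p in seq_len(patients_per_subgroup)) {
        kept <- sig_genes[stats::runif(length(sig_genes)) >= signature_dropout]
        bg <- if (n_background_genes > 0) {
          sample(background_pool, n_background_genes)
        } else character(0)
        pid <- sprintf("P%s_%02d", sub, p)
        patients[[pid]] <- union(kept, bg)
        labels[pid] <- sub
      }
    }
  })
  out <- cohort(patients, labels)
  attr(out, "signatures") <- signatures
  out
}
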