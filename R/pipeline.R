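#' Assemble a pipeline run configuration
#'
#' Collects paths, grids, seeds and decision toggles for [run_pipeline()].
#' Any entry can be omitted; stage-appropriate defaults apply. Paths are
#' validated when the stage that consumes them runs.
#'
#' @param out_dir Output directory (created if missing).
#' @param network,cohort,labels,entity_map Optional input paths.
#' @param resolution_grid Resolution grid for the sweep (default `1:20`).
#' @param theta_grid,lambda_grid Selection grids (defaults `0:3`, `2:10`).
#' @param theta,lambda Fixed selection parameters for the `stratify` and
#'   `shuffle` stages (defaults 0 and 6).
#' @param kmax Maximum cluster count (default 8).
#' @param smin Minimum group size (default 2).
#' @param seed Master seed (mandatory for stochastic commands).
#' @param n_shuffles,n_bootstrap,n_monte_carlo Replicate counts (defaults
#'   10000, 1000, 999).
#' @param alpha Adjusted-p threshold for enrichment (default 0.05).
#' @param weighted Use stored edge weights in modularity (default `FALSE`).
#' @param count_terminal Count terminal community deaths (default `FALSE`).
#' @param linkage Trajectory dendrogram linkage (default "average").
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = "commtraj_out", network = NULL, cohort = NULL,
                       labels = NULL, entity_map = NULL,
                       resolution_grid = 1:20, theta_grid = 0:3,
                       lambda_grid = 2:10, theta = 0L, lambda = 6L,
                       kmax = 8L, smin = 2L, seed = 1L,
                       n_shuffles = 10000L, n_bootstrap = 1000L,
                       n_monte_carlo = 999L, alpha = 0.05, weighted = FALSE,
                       count_terminal = FALSE, linkage = "average") {
  cfg <- list(
    out_dir = out_dir, network = network, cohort = cohort, labels = labels,
    entity_map = entity_map, resolution_grid = resolution_grid,
    theta_grid = theta_grid, lambda_grid = lambda_grid,
    theta = as.integer(theta), lambda = as.integer(lambda), kmax = kmax,
    smin = smin, seed = as.integer(seed), n_shuffles = n_shuffles,
    n_bootstrap = n_bootstrap, n_monte_carlo = n_monte_carlo, alpha = alpha,
    weighted = weighted, count_terminal = count_terminal, linkage = linkage
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#' @param path Config file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, raw)
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's exported functions. Each command
#' writes its artifacts under `config$out_dir` together with a JSON manifest
#' recording the config snapshot, the seeds used, input checksums and the
#' package version, so reruns with the same config reproduce outputs
#' exactly.
#'
#' Commands: `simulate` (synthetic network + cohort), `sweep` (resolution
#' sweep + trajectory matrix), `trajectories` (Hamming distances, events,
#' dendrogram), `optimize` (parameter scan), `stratify` (selection +
#' clustering at fixed theta/lambda), `classify` (held-out assignment),
#' `shuffle`, `exclude`, `significance`, `enrich`.
#'
#' @param config A [run_config()] (or path readable by [load_config()]).
#' @param command Stage name, see above.
#' @return Invisible list of the stage's main in-memory results; artifacts
#'   are written under `config$out_dir`.
#' @export
run_pipeline <- function(config, command) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  commands <- c("simulate", "sweep", "trajectories", "stratify", "optimize",
                "classify", "shuffle", "exclude", "significance", "enrich")
  if (!command %in% commands) {
    stop("unknown command '", command, "'; expected one of: ",
         paste(commands, collapse = ", "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- switch(
    command,
    simulate = stage_simulate(config),
    sweep = stage_sweep(config),
    trajectories = stage_trajectories(config),
    optimize = stage_optimize(config),
    stratify = stage_stratify(config),
    classify = stage_classify(config),
    shuffle = stage_shuffle(config),
    exclude = stage_exclude(config),
    significance = stage_significance(config),
    enrich = stage_enrich(config)
  )
  write_manifest(config, command)
  invisible(out)
}

path_in <- function(config, name) file.path(config$out_dir, name)

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact ", path, "; run the '", producer,
         "' command first", call. = FALSE)
  }
  path
}

pipeline_network <- function(config) {
  p <- config$network %||% require_artifact(path_in(config, "network.tsv"), "simulate")
  load_multiplex(p)
}

pipeline_cohort <- function(config) {
  gp <- config$cohort %||% require_artifact(path_in(config, "cohort.tsv"), "simulate")
  lp <- config$labels %||% {
    cand <- path_in(config, "labels.csv")
    if (file.exists(cand)) cand else NULL
  }
  load_cohort(gp, lp)
}

pipeline_trajectories <- function(config) {
  read_trajectories(require_artifact(path_in(config, "trajectories.tsv"), "sweep"))
}

stage_simulate <- function(config) {
  sim <- simulate_multiplex(seed = config$seed)
  co <- simulate_cohort(sim$truth, seed = config$seed + 1L)
  write_multiplex(sim$network, path_in(config, "network.tsv"))
  write_cohort(co, path_in(config, "cohort.tsv"), path_in(config, "labels.csv"))
  jsonlite::write_json(
    list(params = sim$truth$params,
         assignment = as.data.frame(sim$truth$assignment)),
    path_in(config, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  list(network = sim$network, cohort = co, truth = sim$truth)
}

stage_sweep <- function(config) {
  net <- pipeline_network(config)
  prof <- resolution_sweep(net, config$resolution_grid, seed = config$seed,
                           weighted = config$weighted)
  traj <- build_trajectories(prof)
  write_trajectories(traj, path_in(config, "trajectories.tsv"))
  readr::write_tsv(tidy.resolution_profile(prof), path_in(config, "profile.tsv"))
  list(profile = prof, trajectories = traj)
}

stage_trajectories <- function(config) {
  net <- pipeline_network(config)
  prof <- resolution_sweep(net, config$resolution_grid, seed = config$seed,
                           weighted = config$weighted)
  traj <- build_trajectories(prof)
  d <- trajectory_distances(traj)
  ev <- community_events(prof, count_terminal = config$count_terminal)
  tree <- trajectory_dendrogram(d, linkage = config$linkage)
  readr::write_tsv(
    dplyr::bind_cols(tibble::tibble(gene = rownames(d)),
                     tibble::as_tibble(as.data.frame(d))),
    path_in(config, "distances.tsv")
  )
  write_events(ev, path_in(config, "events.json"))
  write_newick(tree, path_in(config, "dendrogram.nwk"))
  list(distances = d, events = ev, tree = tree)
}

restricted_cohort <- function(config, traj) {
  co <- pipeline_cohort(config)
  suppressMessages(restrict_to_network(co, rownames(traj)))
}

stage_optimize <- function(config) {
  traj <- pipeline_trajectories(config)
  co <- restricted_cohort(config, traj)
  scan <- optimize_parameters(co, traj, config$theta_grid, config$lambda_grid,
                              config$kmax, config$smin)
  readr::write_tsv(scan$results, path_in(config, "scan.tsv"))
  utils::write.csv(
    data.frame(patient = names(scan$clustering$labels),
               cluster = unname(scan$clustering$labels)),
    path_in(config, "clusters.csv"), row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(theta = scan$best$theta, lambda = scan$best$lambda,
         smin = scan$best$smin,
         accuracy = scan$best_score$accuracy, mcc = scan$best_score$mcc,
         k = scan$best_score$k),
    path_in(config, "best_params.json"), auto_unbox = TRUE, digits = NA
  )
  saveRDS_free_selected(scan$selected_sets, path_in(config, "selected.tsv"))
  scan
}

# selected sets as long TSV (text-only artifact)
saveRDS_free_selected <- function(selected_sets, path) {
  readr::write_tsv(tibble::tibble(
    patient = rep(names(selected_sets), lengths(selected_sets)),
    gene = unlist(selected_sets, use.names = FALSE)
  ), path)
}

read_selected <- function(path) {
  df <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  split(df$gene, df$patient)
}

stage_stratify <- function(config) {
  traj <- pipeline_trajectories(config)
  co <- restricted_cohort(config, traj)
  params <- selection_params(config$theta, config$lambda, config$smin)
  sel <- select_cohort_genes(co, traj, params)
  sim <- patient_similarity(sel)
  cl <- cluster_cohort(sim, kmax = config$kmax)
  saveRDS_free_selected(sel, path_in(config, "selected.tsv"))
  utils::write.csv(
    data.frame(patient = names(cl$labels), cluster = unname(cl$labels)),
    path_in(config, "clusters.csv"), row.names = FALSE, quote = FALSE
  )
  list(selected = sel, similarity = sim, clustering = cl)
}

stage_classify <- function(config) {
  traj <- pipeline_trajectories(config)
  co <- restricted_cohort(config, traj)
  scan <- optimize_parameters(co, traj, config$theta_grid, config$lambda_grid,
                              config$kmax, config$smin)
  heldout <- setdiff(patient_ids(co), names(co$labels))
  res <- lapply(heldout, function(pid) {
    classify_heldout(co$patients[[pid]], scan, traj)
  })
  names(res) <- heldout
  rank_tbl <- purrr::imap_dfr(res, function(r, pid) {
    dplyr::mutate(r$ranking, heldout = pid, .before = 1)
  })
  readr::write_tsv(rank_tbl, path_in(config, "heldout_ranking.tsv"))
  res
}

stage_shuffle <- function(config) {
  traj <- pipeline_trajectories(config)
  co <- restricted_cohort(config, traj)
  params <- selection_params(config$theta, config$lambda, config$smin)
  null <- shuffle_analysis(co, traj, params, config$n_shuffles,
                           config$kmax, config$seed)
  readr::write_tsv(tidy.shuffle_null(null), path_in(config, "shuffle.tsv"))
  jsonlite::write_json(
    as.list(glance.shuffle_null(null)),
    path_in(config, "shuffle_summary.json"), auto_unbox = TRUE, digits = NA
  )
  null
}

stage_exclude <- function(config) {
  traj <- pipeline_trajectories(config)
  co <- restricted_cohort(config, traj)
  trace <- iterative_exclusion(co, traj, config$theta_grid,
                               config$lambda_grid, config$kmax, config$smin)
  readr::write_tsv(tibble::as_tibble(trace), path_in(config, "exclusion.tsv"))
  trace
}

stage_significance <- function(config) {
  sel <- read_selected(require_artifact(path_in(config, "selected.tsv"),
                                        "optimize"))
  m <- selection_incidence(sel)
  au <- au_pvalues(m, B = config$n_bootstrap, seed = config$seed)
  mc <- monte_carlo_pvalues(m, tree = attr(au, "tree"),
                            M = config$n_monte_carlo, seed = config$seed + 1L)
  combined <- dplyr::left_join(
    tibble::as_tibble(au),
    dplyr::select(tibble::as_tibble(mc), "members", "statistic",
                  "p_empirical", "p_gaussian"),
    by = "members"
  )
  write_node_significance(au, path_in(config, "significance.json"))
  readr::write_tsv(combined, path_in(config, "significance.tsv"))
  list(au = au, monte_carlo = mc)
}

stage_enrich <- function(config) {
  net <- pipeline_network(config)
  if (is.null(config$entity_map)) stop("entity_map path required", call. = FALSE)
  emap <- load_entity_map(config$entity_map)
  sel <- read_selected(require_artifact(path_in(config, "selected.tsv"),
                                        "optimize"))
  records <- enrich_cohort(net, sel, emap)
  readr::write_tsv(records, path_in(config, "enrichment.tsv"))
  clusters_path <- require_artifact(path_in(config, "clusters.csv"), "optimize")
  cl <- utils::read.csv(clusters_path)
  clusters <- stats::setNames(cl$cluster, cl$patient)
  cons <- consensus_enrichment(records, clusters, config$alpha)
  readr::write_tsv(cons, path_in(config, "consensus.tsv"))
  list(records = records, consensus = cons)
}

write_manifest <- function(config, command) {
  inputs <- purrr::compact(config[c("network", "cohort", "labels", "entity_map")])
  checksums <- if (length(inputs)) {
    as.list(tools::md5sum(unlist(inputs)))
  } else list()
  jsonlite::write_json(
    list(
      command = command,
      config = config[setdiff(names(config), "out_dir")],
      input_checksums = checksums,
      package_version = as.character(utils::packageVersion("commtraj")),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    file.path(config$out_dir, paste0("manifest_", command, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}
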