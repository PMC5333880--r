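#' Run the full invariant / MCT / clustering / knockout workflow
#'
#' Orchestrates the whole analysis in the standard order: read or generate
#' the input, compute minimal t- and p-invariants (when a net is given) or
#' load a support matrix directly, partition transitions into MCT sets,
#' evaluate the clustering grid, extract the chosen clustering, rank
#' structural knockouts, and (optionally) run reference + knockout
#' simulations. Every artifact is written to the output directory and a run
#' manifest records parameters and seeds, so a rerun with the same config is
#' bit-identical.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized entries (all but one input and `out_dir` optional):
#'   \describe{
#'     \item{net / net_format}{input net file and dialect (see [read_net()])}
#'     \item{support}{input support matrix CSV (alternative to `net`)}
#'     \item{use_fixture}{`TRUE` to analyse the packaged angiogenesis
#'       support matrix}
#'     \item{out_dir}{output directory (created if missing)}
#'     \item{metrics, linkages, k_range}{clustering grid (defaults: binary +
#'       correlation, upgma + complete, 2..13)}
#'     \item{chosen}{list(metric, linkage, k) for the membership output
#'       (default: the grid row with the highest score among rows with the
#'       fewest singleton clusters)}
#'     \item{simulation}{list(enabled, steps, repetitions,
#'       firing_probability, seed, disable) — `disable` is a list of
#'       transition-id vectors, one knockout run each; needs a net input}
#'   }
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out_dir
  if (is.null(out)) stop("config must name an `out_dir`")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(package = "petrinv",
                   version = as.character(utils::packageVersion("petrinv")),
                   config = config, stages = list())

  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[petrinv] stage %-12s %.2fs", name,
                    manifest$stages[[name]]$seconds))
    val
  }

  net <- NULL
  if (!is.null(config$net)) {
    net <- stage("read_net", read_net(config$net, config$net_format))
    res$structure <- structural_report(net)
  }

  if (!is.null(net)) {
    res$t_invariants <- stage("invariants", minimal_t_invariants(net))
    res$p_invariants <- minimal_p_invariants(net)
    support <- build_support_matrix(res$t_invariants)
    jsonlite::write_json(
      list(t_invariants = apply(res$t_invariants, 1, identity, simplify = FALSE),
           p_invariants = nrow(res$p_invariants)),
      file.path(out, "invariants.json"), auto_unbox = TRUE)
  } else if (isTRUE(config$use_fixture)) {
    support <- stage("fixture", load_angiogenesis_fixture()$support)
  } else if (!is.null(config$support)) {
    support <- stage("read_support", read_support_csv(config$support))
  } else {
    stop("config must name a `net`, a `support` CSV, or set use_fixture: true")
  }
  res$support <- support
  write_support_csv(support, file.path(out, "support.csv"))

  res$coverage <- check_coverage(support)
  res$mct <- stage("mct", compute_mct_sets(support))
  if (!is.null(net)) res$mct <- mct_connectivity(res$mct, net)
  jsonlite::write_json(
    list(sets = res$mct$sets, trivial = res$mct$trivial,
         connected = res$mct$connected, uncovered = res$mct$uncovered,
         covered = res$coverage$covered),
    file.path(out, "mct.json"), auto_unbox = FALSE, pretty = TRUE)

  metrics <- config$metrics %||% c("binary", "correlation")
  linkages <- config$linkages %||% c("upgma", "complete")
  k_range <- config$k_range %||% 2:13
  k_range <- k_range[k_range <= nrow(support)]
  res$grid <- stage("cluster_grid",
                    evaluate_grid(support, metrics, linkages, k_range))
  utils::write.csv(res$grid, file.path(out, "clustering_grid.csv"),
                   row.names = FALSE)

  chosen <- config$chosen
  if (is.null(chosen)) {
    g <- res$grid[res$grid$singletons == min(res$grid$singletons), ]
    g <- g[which.max(g$mss), ]
    chosen <- list(metric = g$metric, linkage = g$linkage, k = g$k)
  }
  d <- distance_matrix(support, chosen$metric)
  cl <- cut_dendrogram(agglomerate(d, chosen$linkage), chosen$k)
  res$clusters <- split(names(cl), cl)
  res$mss <- mean_split_silhouette(cl, d)
  jsonlite::write_json(
    list(metric = chosen$metric, linkage = chosen$linkage, k = chosen$k,
         mss_global = res$mss$global,
         mss_per_cluster = as.list(round(res$mss$per_cluster, 4)),
         clusters = res$clusters),
    file.path(out, "clusters.json"), auto_unbox = TRUE, pretty = TRUE)

  units <- knock_units(res$mct)
  res$knockout <- stage("knockout", structural_knockout_table(support, units))
  utils::write.csv(res$knockout, file.path(out, "knockout_structural.csv"),
                   row.names = FALSE)

  sim <- config$simulation
  if (!is.null(sim) && isTRUE(sim$enabled)) {
    if (is.null(net)) stop("simulation requires a `net` input")
    base <- simulation_params(steps = sim$steps %||% 10000,
                              repetitions = sim$repetitions %||% 4000,
                              firing_probability = sim$firing_probability %||% 0.5,
                              seed = sim$seed %||% 1)
    res$reference <- stage("sim_reference", run_simulation(net, base))
    write_sim_json(res$reference, file.path(out, "simulation_reference.json"))
    res$knock_sims <- list()
    for (dset in sim$disable %||% list()) {
      kp <- base; kp$disabled <- as.character(unlist(dset))
      nm <- paste(kp$disabled, collapse = "_")
      pkg <- run_simulation(net, kp)
      res$knock_sims[[nm]] <- compare_simulation_packages(res$reference, pkg)
      utils::write.csv(res$knock_sims[[nm]],
                       file.path(out, paste0("knockout_sim_", nm, ".csv")),
                       row.names = FALSE)
    }
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

write_sim_json <- function(pkg, path) {
  jsonlite::write_json(list(params = unclass(pkg$params),
                            transitions = pkg$transitions,
                            places = pkg$places),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
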