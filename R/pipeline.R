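#' Experiment configuration
#'
#' Bundles everything needed to reproduce one node-removal experiment: the
#' network ensemble, the models to run, per-model parameter grids and
#' simulation settings, the classifier settings, and the master seed.  All
#' per-cell seeds are derived deterministically from the master seed and the
#' (network, removed node, cell) indices, so results are independent of
#' execution order or any parallel chunking of the work.
#'
#' @param networks list of `icto_network` objects; names (or indices) become
#'   network ids.
#' @param models character vector among `"theta"`, `"bistable"`,
#'   `"physiological"`.
#' @param preset preset name passed to [sim_preset()] for any model without
#'   an explicit grid/config.
#' @param resolution optional override of the preset grid resolution.
#' @param grids,configs,classifiers optional named lists (by model) of
#'   [parameter_grid()], [sim_config()] and [ictal_classifier()] objects.
#' @param params optional named list (by model) of `model_params`.
#' @param seed master seed.
#' @param out_dir optional output directory: per-(network, model) NI tables
#'   and the experiment manifest are written there and reused on rerun.
#' @export
experiment_config <- function(networks, models = c("theta", "bistable"),
                              preset = "mini", resolution = NULL,
                              grids = NULL, configs = NULL,
                              classifiers = NULL, params = NULL,
                              seed = 1, out_dir = NULL) {
  if (length(networks) == 0) stop("no networks supplied")
  if (length(models) == 0) stop("empty model list")
  bad <- setdiff(models, c("theta", "bistable", "physiological"))
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  if (is.null(names(networks)))
    names(networks) <- sprintf("net%03d", seq_along(networks))
  for (m in models) {
    pre <- sim_preset(m, preset, seed = seed)
    res <- if (is.null(resolution)) pre$resolution else as.integer(resolution)
    if (is.null(grids[[m]])) grids[[m]] <- parameter_grid(m, resolution = res)
    if (is.null(configs[[m]])) configs[[m]] <- pre$config
    configs[[m]]$seed <- as.numeric(seed)
    if (is.null(classifiers[[m]])) classifiers[[m]] <- ictal_classifier(m)
    if (is.null(params[[m]]))
      params[[m]] <- switch(m, theta = theta_params(),
                            bistable = bistable_params(),
                            physiological = physiological_params())
  }
  structure(list(networks = networks, models = models, grids = grids,
                 configs = configs, classifiers = classifiers,
                 params = params, seed = seed, preset = preset,
                 out_dir = out_dir),
            class = "experiment_config")
}

cache_key <- function(cfg, net_name, model) {
  g <- cfg$grids[[model]]; sc <- cfg$configs[[model]]
  paste0(net_name, "_", model, "_s", format(cfg$seed), "_r", g$resolution,
         "_p", signif(min(g$p), 6), "-", signif(max(g$p), 6),
         "_a", signif(min(g$alpha), 6), "-", signif(max(g$alpha), 6),
         "_dt", format(sc$dt), "_T", format(sc$t_total),
         "_B", format(sc$t_burn))
}

#' Run a node-removal comparison experiment
#'
#' For every (network, model): computes the NI distribution (full BNI map
#' plus one map per node removal).  Then computes the weighted Kendall tau
#' for every network and model pair, ensemble summaries, and — when at
#' least `2 * n_bins` networks are available — the heterogeneity binning
#' and degree-spread correlations of [heterogeneity_analysis()].
#'
#' When `out_dir` is set, each (network, model) NI table is written as a
#' tidy CSV keyed by its full parameterization and reused on rerun
#' (resumption skips completed work); summary tables and a JSON manifest
#' recording the seed and all problem sizes are written alongside.
#'
#' @param cfg an [experiment_config()].
#' @param n_bins,filter forwarded to [heterogeneity_analysis()].
#' @param verbose print progress.
#' @return list of class `experiment_result`: `ni_table`, `stats_table`,
#'   `comparison` (a `comparison_result` or `NULL`), `manifest`.
#' @export
run_experiment <- function(cfg, n_bins = 4L, filter = 0.05,
                           verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  use_cache <- !is.null(cfg$out_dir)
  if (use_cache) dir.create(cfg$out_dir, recursive = TRUE,
                            showWarnings = FALSE)
  rows <- list()
  for (k in seq_along(cfg$networks)) {
    net <- cfg$networks[[k]]
    net_name <- names(cfg$networks)[k]
    for (m in cfg$models) {
      fp <- if (use_cache)
        file.path(cfg$out_dir, paste0("ni_", cache_key(cfg, net_name, m),
                                      ".csv"))
      if (use_cache && file.exists(fp)) {
        tab <- read.csv(fp)
      } else {
        if (verbose) message("NI: ", net_name, " / ", m)
        nd <- compute_ni(net, cfg$params[[m]], cfg$grids[[m]],
                         cfg$configs[[m]], cfg$classifiers[[m]],
                         net_id = k)
        tab <- data.frame(network_id = net_name, model = m,
                          node = nd$node, ni = nd$ni,
                          bni0 = attr(nd, "bni0"))
        if (use_cache) write.csv(tab, fp, row.names = FALSE)
      }
      rows[[length(rows) + 1]] <- tab
    }
  }
  ni_table <- do.call(rbind, rows)
  stats_table <- do.call(rbind, lapply(seq_along(cfg$networks), function(k) {
    st <- network_stats(cfg$networks[[k]])
    data.frame(network_id = names(cfg$networks)[k], n_edges = st$n_edges,
               outdegree_mean = st$outdegree_mean,
               normalized_sd = st$normalized_sd)
  }))
  comparison <- NULL
  if (length(cfg$models) >= 2) {
    comparison <- tryCatch(
      heterogeneity_analysis(ni_table, stats_table, n_bins = n_bins,
                             filter = filter),
      error = function(e) {
        # binning needs enough heterogeneous networks; keep pair taus only
        heterogeneity_analysis_taus(ni_table)
      })
  }
  manifest <- list(
    seed = cfg$seed, preset = cfg$preset, models = cfg$models,
    n_networks = length(cfg$networks),
    resolution = vapply(cfg$models,
                        function(m) cfg$grids[[m]]$resolution, integer(1)),
    dt = vapply(cfg$models, function(m) cfg$configs[[m]]$dt, numeric(1)),
    t_total = vapply(cfg$models, function(m) cfg$configs[[m]]$t_total,
                     numeric(1)),
    t_burn = vapply(cfg$models, function(m) cfg$configs[[m]]$t_burn,
                    numeric(1)))
  if (use_cache) {
    write.csv(ni_table, file.path(cfg$out_dir, "ni_table.csv"),
              row.names = FALSE)
    write.csv(stats_table, file.path(cfg$out_dir, "network_stats.csv"),
              row.names = FALSE)
    if (!is.null(comparison) && !is.null(comparison$pair_summary))
      write.csv(comparison$pair_summary,
                file.path(cfg$out_dir, "pair_summary.csv"),
                row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(ni_table = ni_table, stats_table = stats_table,
                 comparison = comparison, manifest = manifest),
            class = "experiment_result")
}

# tau-only fallback when the heterogeneity binning is infeasible
heterogeneity_analysis_taus <- function(ni_table) {
  models <- sort(unique(ni_table$model))
  nets <- unique(ni_table$network_id)
  pairs <- utils::combn(models, 2, simplify = FALSE)
  tau_df <- do.call(rbind, lapply(pairs, function(pp) {
    do.call(rbind, lapply(nets, function(id) {
      a <- ni_table[ni_table$network_id == id & ni_table$model == pp[1], ]
      b <- ni_table[ni_table$network_id == id & ni_table$model == pp[2], ]
      a <- a[order(a$node), ]; b <- b[order(b$node), ]
      wk <- weighted_kendall(a$ni, b$ni)
      data.frame(network_id = id, model_a = pp[1], model_b = pp[2],
                 tau = wk$tau, undefined = wk$undefined)
    }))
  }))
  pair_summary <- do.call(rbind, lapply(pairs, function(pp) {
    sub <- tau_df[tau_df$model_a == pp[1] & tau_df$model_b == pp[2], ]
    ok <- sub$tau[!sub$undefined]
    data.frame(model_a = pp[1], model_b = pp[2], mean_tau = mean(ok),
               sem_tau = sd(ok) / sqrt(length(ok)),
               n_networks = length(ok), n_undefined = sum(sub$undefined))
  }))
  structure(list(heterogeneity = NULL, tau = tau_df,
                 pair_summary = pair_summary, bins = NULL, spearman = NULL),
            class = "comparison_result")
}
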