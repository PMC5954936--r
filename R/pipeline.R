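#' Default pipeline configuration
#'
#' Three profiles: `"demo"` (two groups of three 6-node synthetic subjects
#' with reduced surrogate/null/permutation counts — finishes in well under a
#' minute), `"test"` (intermediate), and `"full"` (the complete analysis
#' settings: order 8, 1000 surrogates, 10,000 small-world nulls, 50,000
#' permutations, 24 ROIs).
#'
#' @param profile Configuration profile.
#' @param seed Master seed; every stochastic stage receives a derived,
#'   explicitly logged seed.
#' @return Nested configuration list.
#' @export
default_config <- function(profile = c("demo", "test", "full"), seed = 1) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    seed = seed,
    synth = list(
      n_nodes = 6, order = 8, edge_density = 0.2, fs = 100,
      n_per_group = 3, planted_edges = data.frame(
        source = 1, target = 2, effect = 0.3),
      within_noise_sd = 0.02,
      n_trials = 9, epoch_window_ms = c(-2000, 5000),
      dipoles_per_roi = 3, n_sensors = 16, smoothness = 0.9, snr_db = 20),
    sourcemodel = list(lambda_grid_size = 20, depth_weight = FALSE),
    dtf = list(order = 8, bands = c("alpha", "beta"),
               n_surrogates = 50, alpha_level = 0.05),
    graph = list(sw_n_random = 50, cc_variant = "binary_undirected"),
    stats = list(n_permutations = 500, alpha_level = 0.05),
    intervals = c("early", "late"))
  if (profile == "test") {
    base$dtf$n_surrogates <- 200
    base$graph$sw_n_random <- 200
    base$stats$n_permutations <- 2000
  }
  if (profile == "full") {
    base$synth$n_nodes <- 24
    base$synth$n_per_group <- 10
    base$synth$dipoles_per_roi <- 10
    base$synth$n_sensors <- 64
    base$dtf$n_surrogates <- 1000
    base$graph$sw_n_random <- 10000
    base$stats$n_permutations <- 50000
    base$sourcemodel$lambda_grid_size <- 40
  }
  base
}

# deterministic polynomial hash (mod 2^31 - 1) of the serialized config,
# for provenance stamps
config_hash <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full synthetic-cohort connectivity pipeline
#'
#' Executes, in order: synthetic-cohort generation (base MVAR system,
#' subject systems with planted group effects, lead field, schedule) ->
#' scalp projection at the configured SNR -> epoch interval split ->
#' per-epoch minimum-norm inversion with L-curve regularization -> ROI
#' averaging -> per-subject band-resolved DTF with surrogate thresholding ->
#' graph summaries -> between-group edge statistics and property
#' comparisons. Every output table is written under `out_dir` along with a
#' provenance log (stage seeds, draw counts, config hash). Identical
#' configurations produce byte-identical outputs.
#'
#' @param config List from [default_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`roi_series`,
#'   `networks`, `graph_tables`, `nbs`, `property_tests`, `provenance`).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("dtfnet_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  sy <- config$synth
  stage_seeds <- derive_seeds(config$seed, 6L)
  names(stage_seeds) <- c("system", "cohort", "lead_field", "projection",
                          "surrogates", "statistics")
  provenance <- list(config_hash = hash, profile = config$profile,
                     master_seed = config$seed,
                     stage_seeds = as.list(stage_seeds), stages = list())
  log_stage <- function(name, ...) {
    provenance$stages[[length(provenance$stages) + 1L]] <<-
      c(list(stage = name), list(...))
  }

  # --- synthesis -----------------------------------------------------------
  win <- sy$epoch_window_ms
  n_samples <- round(diff(win) * sy$fs / 1000)
  base_sys <- generate_mvar_system(sy$n_nodes, sy$order, sy$edge_density,
                                   seed = stage_seeds[["system"]], fs = sy$fs)
  cohort <- generate_cohort(base_sys, sy$n_per_group, sy$planted_edges,
                            sy$within_noise_sd, seed = stage_seeds[["cohort"]],
                            n_samples = n_samples, n_trials = sy$n_trials)
  n_rois <- sy$n_nodes
  roi_model <- if (n_rois == 24) 24 else
    rep(sprintf("ROI%02d", seq_len(n_rois)), each = sy$dipoles_per_roi)
  lf <- generate_lead_field(sy$n_sensors, n_rois * sy$dipoles_per_roi,
                            roi_model = if (n_rois == 24) 24 else roi_model,
                            smoothness = sy$smoothness,
                            seed = stage_seeds[["lead_field"]])
  schedule <- generate_schedule(seed = stage_seeds[["system"]])
  log_stage("synth", n_subjects = 2L * sy$n_per_group,
            n_edges_truth = sum(base_sys$causal_mask))

  # --- per-subject chain ---------------------------------------------------
  subjects <- data.frame(
    id = c(sprintf("A%02d", seq_len(sy$n_per_group)),
           sprintf("B%02d", seq_len(sy$n_per_group))),
    group = rep(c("A", "B"), each = sy$n_per_group),
    stringsAsFactors = FALSE)
  proj_seeds <- derive_seeds(stage_seeds[["projection"]], nrow(subjects))
  surr_seeds <- derive_seeds(stage_seeds[["surrogates"]], nrow(subjects))
  grid_n <- config$sourcemodel$lambda_grid_size
  grid <- lambda_grid(lf, grid_n)

  networks <- list()       # networks[[interval]][[band]][[subject]]
  roi_store <- list()
  graph_rows <- list()
  for (si in seq_len(nrow(subjects))) {
    grp <- subjects$group[si]
    idx <- (si - 1L) %% sy$n_per_group + 1L
    sources <- cohort$sources[[grp]][[idx]]
    scalp <- project_to_scalp(sources, lf, snr_db = sy$snr_db,
                              seed = proj_seeds[si], fs = sy$fs)
    scalp <- replace_epoch_data(scalp, scalp$data, window = win)
    ints <- split_intervals(scalp)
    for (interval in config$intervals) {
      ep <- ints[[interval]]
      n_tr <- dim(ep$data)[1]
      roi_arr <- NULL
      for (tr in seq_len(n_tr)) {
        epoch <- matrix(ep$data[tr, , ], dim(ep$data)[2], dim(ep$data)[3])
        lam <- select_lambda_lcurve(lf, epoch, grid,
                                    config$sourcemodel$depth_weight)
        est <- mne_solve(lf, epoch, as.numeric(lam),
                         config$sourcemodel$depth_weight)
        roi <- extract_roi_series(est, lf, fs = sy$fs, interval_tag = interval)
        if (is.null(roi_arr))
          roi_arr <- array(0, dim = c(n_tr, nrow(roi$series), ncol(roi$series)))
        roi_arr[tr, , ] <- roi$series
      }
      attr(roi_arr, "fs") <- sy$fs
      roi_store[[paste(subjects$id[si], interval, sep = "_")]] <- roi_arr
      for (band in config$dtf$bands) {
        net <- surrogate_threshold(roi_arr, config$dtf$order, band,
                                   config$dtf$n_surrogates,
                                   config$dtf$alpha_level,
                                   seed = surr_seeds[si], fs = sy$fs)
        networks[[interval]][[band]][[subjects$id[si]]] <- net
        gs <- graph_summary(net, config$graph$sw_n_random,
                            seed = surr_seeds[si],
                            cc_variant = config$graph$cc_variant)
        graph_rows[[length(graph_rows) + 1L]] <- data.frame(
          subject = subjects$id[si], group = grp, interval = interval,
          band = band, n_edges = gs$n_edges, density = gs$density,
          cc = gs$cc, cpl = gs$cpl, sw = gs$sw,
          stringsAsFactors = FALSE)
      }
    }
  }
  graph_table <- do.call(rbind, graph_rows)
  log_stage("networks", n_networks = nrow(graph_table),
            n_surrogates = config$dtf$n_surrogates)

  # --- group statistics ----------------------------------------------------
  stat_seeds <- derive_seeds(stage_seeds[["statistics"]],
                             length(config$intervals) * length(config$dtf$bands))
  nbs_rows <- list(); prop_rows <- list()
  ci <- 0L
  is_a <- subjects$group == "A"
  for (interval in config$intervals) for (band in config$dtf$bands) {
    ci <- ci + 1L
    nets <- networks[[interval]][[band]]
    res <- nbs_fdr(nets[subjects$id[is_a]], nets[subjects$id[!is_a]],
                   config$stats$alpha_level, config$stats$n_permutations,
                   seed = stat_seeds[ci])
    sig <- which(res$fdr_mask, arr.ind = TRUE)
    if (nrow(sig))
      nbs_rows[[length(nbs_rows) + 1L]] <- data.frame(
        interval = interval, band = band,
        source = sig[, 2], target = sig[, 1],
        t = res$t_stats[sig], p = res$perm_p[sig],
        direction = ifelse(res$direction[sig] > 0, "A>B", "B>A"),
        stringsAsFactors = FALSE)
    gsub_tab <- graph_table[graph_table$interval == interval &
                              graph_table$band == band, ]
    for (metric in c("density", "cc", "cpl", "sw")) {
      va <- gsub_tab[[metric]][gsub_tab$group == "A"]
      vb <- gsub_tab[[metric]][gsub_tab$group == "B"]
      if (sum(is.finite(va)) < 3 || sum(is.finite(vb)) < 3) next
      pc <- compare_property(va[is.finite(va)], vb[is.finite(vb)])
      prop_rows[[length(prop_rows) + 1L]] <- data.frame(
        interval = interval, band = band, metric = metric,
        test = pc$test_used, statistic = pc$statistic, p = pc$p_value,
        mean_a = pc$summary$mean[1], mean_b = pc$summary$mean[2],
        stringsAsFactors = FALSE)
    }
  }
  nbs_table <- if (length(nbs_rows)) do.call(rbind, nbs_rows) else
    data.frame(interval = character(0), band = character(0),
               source = integer(0), target = integer(0), t = numeric(0),
               p = numeric(0), direction = character(0))
  prop_table <- do.call(rbind, prop_rows)
  log_stage("statistics", n_permutations = config$stats$n_permutations,
            n_significant_edges = nrow(nbs_table))

  # --- outputs -------------------------------------------------------------
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 15))
    df
  }
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  write_schedule(schedule, file.path(out_dir, "schedule.csv"))
  write_edge_list(1 * base_sys$causal_mask,
                  file.path(out_dir, "ground_truth_edges.csv"))
  utils::write.csv(fmt(graph_table), file.path(out_dir, "graph_summaries.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(nbs_table), file.path(out_dir, "nbs_edges.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(fmt(prop_table),
                   file.path(out_dir, "property_comparisons.csv"),
                   row.names = FALSE, quote = FALSE)
  for (interval in config$intervals) for (band in config$dtf$bands) {
    for (id in subjects$id) {
      net <- networks[[interval]][[band]][[id]]
      write_edge_list(net, file.path(out_dir, sprintf(
        "network_%s_%s_%s.csv", id, interval, band)))
    }
    write_graphml(networks[[interval]][[band]][[subjects$id[1]]],
                  file.path(out_dir, sprintf("network_%s_%s_%s.graphml",
                                             subjects$id[1], interval, band)))
  }
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(out_dir = out_dir, roi_series = roi_store,
                 networks = networks, graph_table = graph_table,
                 nbs = nbs_table, property_tests = prop_table,
                 provenance = provenance, lead_field = lf,
                 cohort = cohort, schedule = schedule))
}
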