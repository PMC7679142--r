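#' Export a TE network to files
#'
#' Writes a directed edge-list CSV (`source, target, te_bits, p_value,
#' p_conservative, n_pairs, significant`), a JSON node table with
#' importances, and a GraphML rendering of the graph.
#'
#' @param net a `te_network`.
#' @param path output path prefix; files `<path>_edges.csv`,
#'   `<path>_nodes.json` and `<path>.graphml` are written.
#' @param view "full" (default) or "significant".
#' @return invisibly, the character vector of files written.
#' @export
export_network <- function(net, path, view = c("full", "significant")) {
  stopifnot(inherits(net, "te_network"))
  view <- match.arg(view)
  if (view == "significant") net <- significant_edges(net)
  f_edges <- paste0(path, "_edges.csv")
  f_nodes <- paste0(path, "_nodes.json")
  f_graphml <- paste0(path, ".graphml")
  utils::write.csv(net$edges, f_edges, row.names = FALSE)
  jsonlite::write_json(list(nodes = net$nodes,
                            window_spec = net$window_spec,
                            alpha = net$alpha,
                            n_bins_used = net$n_bins_used,
                            seed = net$seed),
                       f_nodes, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  g <- igraph::graph_from_data_frame(
    if (nrow(net$edges) > 0) net$edges else
      data.frame(source = character(0), target = character(0)),
    directed = TRUE,
    vertices = net$nodes)
  igraph::write_graph(g, f_graphml, format = "graphml")
  invisible(c(f_edges, f_nodes, f_graphml))
}

#' Import a TE network written by [export_network()]
#'
#' Reads the edge-list CSV and node JSON back into a `te_network`.
#'
#' @param path the path prefix used at export time.
#' @return a `te_network`.
#' @export
import_network <- function(path) {
  edges <- utils::read.csv(paste0(path, "_edges.csv"),
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, "_nodes.json"),
                              simplifyVector = TRUE)
  nodes <- as.data.frame(meta$nodes)
  if (is.null(nodes$importance)) nodes$importance <- NA_real_
  nodes$importance <- as.numeric(nodes$importance)
  if (nrow(edges) > 0) edges$significant <- as.logical(edges$significant)
  structure(list(edges = edges, nodes = nodes,
                 window_spec = meta$window_spec, alpha = meta$alpha,
                 n_bins_used = meta$n_bins_used, seed = meta$seed),
            class = "te_network")
}

#' Default pipeline configuration
#'
#' Flat key-value configuration driving [run_pipeline()]. All values are
#' scalars so the config round-trips through a plain `key = value` text
#' file (see [read_config()] / [write_config()]).
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    # synthetic session
    session_length = 600, n_trials_per_cs = 6, stage = "recall",
    neurons_aIC = 30, neurons_pIC = 25, neurons_CE_SST = 15,
    neurons_CE_PKCd = 15, neurons_CEm = 10,
    baseline_rate = 0.2, behavior_correct_prob = 0.8,
    coupling_source = "aIC", coupling_target = "CE_SST",
    coupling_excess_prob = 0.3, coupling_lag_bins = 1,
    lfp_fs = 250, osc_freq = 33, osc_amplitude = 8, osc_kappa = 4,
    # analysis
    pre_window_bins = 10, post_us_bins = 8,
    freeze_threshold = 10, freeze_min_dur = 1, freeze_window = 1,
    ca_cutoff_hz = 0.5, ca_mad_mult = 3, ca_tau_off = 0.2,
    decode_repeats = 10, decode_folds = 5, decode_hidden = 16,
    rf_n_total = 40, rf_repeats = 10,
    te_n_draw = 60, te_n_surr = 100, te_alpha = 0.05,
    sfc_window = 0.2,
    seed = 1)
}

#' Read a flat key-value config file
#'
#' Lines are `key = value`; `#` starts a comment; values are parsed as
#' numeric when possible. Keys absent from the file keep their
#' [default_config()] values; unknown keys error.
#'
#' @param path file path.
#' @return named list (full config).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Write a config as a flat key-value file
#' @param cfg named list (e.g. from [default_config()]).
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  writeLines(paste(names(cfg), unlist(cfg), sep = " = "), path)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic session
#'
#' Stages: simulate, bin, behavior, calcium, decode, te, sfc, report.
#' Every stage derives its seed from the master seed via [derive_seed()],
#' writes its artifacts under `out_dir` (CSV event tables, JSON timeline
#' and results, CSV continuous signals, GraphML/CSV networks), and the run
#' ends with a manifest listing every artifact with its content hash.
#'
#' @param config a config list, or the path of a key-value config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional master seed overriding the config's.
#' @param quiet suppress stage progress messages.
#' @return object of class `analysis_manifest` (also written as
#'   `manifest.json`): list with `config`, `seed`, `stage_seeds`,
#'   `artifacts` (data.frame file/md5), and headline `results`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else
    utils::modifyList(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[entrain] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  results <- list()

  say("stage simulate (seed ", derive_seed(cfg$seed, 1), ")")
  session <- stage("simulate", {
    sc <- synth_config(
      n_neurons_per_region = c(aIC = cfg$neurons_aIC, pIC = cfg$neurons_pIC,
                               CE_SST = cfg$neurons_CE_SST,
                               CE_PKCd = cfg$neurons_CE_PKCd,
                               CEm = cfg$neurons_CEm),
      baseline_rate = cfg$baseline_rate,
      coupling = data.frame(source = cfg$coupling_source,
                            target = cfg$coupling_target,
                            excess_prob = cfg$coupling_excess_prob,
                            lag_bins = cfg$coupling_lag_bins),
      # the oscillation is present in both IC LFPs; aIC spikes are
      # phase-locked to it, so aIC-spike/pIC-LFP coherence is planted
      lfp_osc = data.frame(region = c("aIC", "pIC"),
                           freq = cfg$osc_freq,
                           amplitude = cfg$osc_amplitude,
                           kappa = c(cfg$osc_kappa, 0)),
      behavior_correct_prob = cfg$behavior_correct_prob,
      session_length = cfg$session_length,
      n_trials_per_cs = cfg$n_trials_per_cs,
      stage = cfg$stage, lfp_fs = cfg$lfp_fs,
      seed = derive_seed(cfg$seed, 1))
    generate_session(sc)
  })
  stage("simulate", {
    ev <- do.call(rbind, lapply(session$trains, function(tr)
      if (length(tr$times) == 0) NULL else
        data.frame(neuron_id = tr$neuron_id, region = tr$region,
                   stage = tr$stage, time_s = tr$times)))
    utils::write.csv(ev, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(cs_trials = session$timeline$cs_trials,
                              us_events = session$timeline$us_events,
                              behavior_episodes =
                                session$timeline$behavior_episodes),
                         file.path(out_dir, "timeline.json"),
                         dataframe = "rows", digits = NA)
    utils::write.csv(data.frame(sample = session$lfp$pIC$samples),
                     file.path(out_dir, "lfp_pIC.csv"), row.names = FALSE)
  })

  say("stage bin")
  binned1 <- stage("bin", bin_events(session$trains, bin_width = 1, t0 = 0,
                                     t_end = cfg$session_length))
  binned05 <- stage("bin", bin_events(session$trains, bin_width = 0.5,
                                      t0 = 0, t_end = cfg$session_length))
  peth <- stage("bin", make_peth(binned05, session$timeline))
  stage("bin", utils::write.csv(
    data.frame(rel_time = peth$rel_time,
               mean_z = apply(peth$z, 3, mean, na.rm = TRUE)),
    file.path(out_dir, "peth_mean.csv"), row.names = FALSE))

  say("stage behavior")
  results$behavior <- stage("behavior", {
    frz <- score_freezing(session$motion, threshold = cfg$freeze_threshold,
                          min_dur = cfg$freeze_min_dur,
                          window = cfg$freeze_window)
    eps <- classify_episodes(session$timeline$behavior_episodes,
                             session$timeline)
    cs <- classify_cs_trials(session$timeline, eps)
    utils::write.csv(cs, file.path(out_dir, "cs_trials.csv"),
                     row.names = FALSE)
    list(n_freezing_episodes = nrow(frz),
         fraction_correct_trials = mean(cs$correct))
  })

  say("stage calcium")
  results$calcium <- stage("calcium", {
    if (length(session$calcium) == 0) list(n_events = 0) else {
      ev <- detect_events(lowpass(session$calcium[[1]],
                                  cutoff = cfg$ca_cutoff_hz),
                          mad_mult = cfg$ca_mad_mult,
                          tau_off = cfg$ca_tau_off)
      utils::write.csv(data.frame(time_s = ev$times, peak_dff = ev$peaks),
                       file.path(out_dir, "calcium_events.csv"),
                       row.names = FALSE)
      list(n_events = length(ev$times))
    }
  })

  say("stage decode")
  results$decode <- stage("decode", {
    ds <- build_labels(binned1, session$timeline, task = "CS",
                       pre_window_bins = cfg$pre_window_bins)
    d <- decode_single_region(ds, repeats = cfg$decode_repeats,
                              folds = cfg$decode_folds,
                              hidden = cfg$decode_hidden,
                              seed = derive_seed(cfg$seed, 5))
    mr <- decode_multi_region(ds, n_total = cfg$rf_n_total,
                              repeats = cfg$rf_repeats,
                              folds = cfg$decode_folds,
                              seed = derive_seed(cfg$seed, 6))
    jsonlite::write_json(list(da_cs = d$da, da_rf = mr$result$da,
                              importance =
                                as.list(mr$importance$region_mean)),
                         file.path(out_dir, "decoding.json"),
                         digits = NA, auto_unbox = TRUE)
    list(da_cs = d$da, da_rf = mr$result$da, importance = mr$importance)
  })

  say("stage te")
  net <- stage("te", build_te_network(
    binned1, session$timeline, window_spec = "cs",
    n_draw = cfg$te_n_draw, n_surr = cfg$te_n_surr, alpha = cfg$te_alpha,
    importance = results$decode$importance,
    seed = derive_seed(cfg$seed, 7)))
  stage("te", export_network(net, file.path(out_dir, "te_network")))
  results$te <- list(
    n_significant = sum(net$edges$significant),
    planted_edge_p = net$edges$p_value[
      net$edges$source == cfg$coupling_source &
        net$edges$target == cfg$coupling_target])

  say("stage sfc")
  results$sfc <- stage("sfc", {
    cs_iv <- data.frame(start = session$timeline$cs_trials$onset,
                        end = session$timeline$cs_trials$onset +
                          session$timeline$cs_trials$duration)
    pre_iv <- data.frame(start = cs_iv$start - 10, end = cs_iv$start)
    aic <- session$trains[vapply(session$trains,
                                 function(t) t$region == "aIC",
                                 logical(1))]
    spk <- sort(unlist(lapply(aic, function(t) t$times)))
    sta_cs <- spike_triggered_average(session$lfp$pIC, spk,
                                      window = cfg$sfc_window,
                                      condition_mask = cs_iv,
                                      condition = "CS")
    sta_pre <- spike_triggered_average(session$lfp$pIC, spk,
                                       window = cfg$sfc_window,
                                       condition_mask = pre_iv,
                                       condition = "preCS")
    sfc_cs <- spike_field_coherence(sta_cs)
    sfc_pre <- spike_field_coherence(sta_pre)
    cmp <- compare_sfc(sfc_pre, sfc_cs)
    utils::write.csv(data.frame(freq = cmp$freq, sfc_pre = sfc_pre$sfc,
                                sfc_cs = sfc_cs$sfc,
                                difference = cmp$difference),
                     file.path(out_dir, "sfc.csv"), row.names = FALSE)
    list(peak_freq_cs = cmp$peak$peak_freq[2],
         peak_sfc_cs = cmp$peak$peak_sfc[2],
         peak_sfc_pre = cmp$peak$peak_sfc[1])
  })

  say("stage report")
  manifest <- stage("report", {
    files <- sort(list.files(out_dir, full.names = TRUE))
    files <- files[!basename(files) %in% "manifest.json"]
    artifacts <- data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)))
    flat <- list(config = cfg, seed = cfg$seed,
                 stage_seeds = stats::setNames(
                   vapply(1:7, function(k) derive_seed(cfg$seed, k), 1L),
                   c("simulate", "bin", "behavior", "calcium", "decode",
                     "rf", "te")),
                 artifacts = artifacts,
                 results = list(
                   fraction_correct_trials =
                     results$behavior$fraction_correct_trials,
                   n_freezing_episodes =
                     results$behavior$n_freezing_episodes,
                   n_calcium_events = results$calcium$n_events,
                   da_cs = results$decode$da_cs,
                   da_rf = results$decode$da_rf,
                   te_significant_edges = results$te$n_significant,
                   te_planted_edge_p = results$te$planted_edge_p,
                   sfc_peak_freq_cs = results$sfc$peak_freq_cs))
    jsonlite::write_json(flat, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
    structure(flat, class = "analysis_manifest")
  })
  say("done: ", nrow(manifest$artifacts), " artifacts in ", out_dir)
  invisible(manifest)
}

#' @export
print.analysis_manifest <- function(x, ...) {
  cat("Analysis manifest: seed", x$seed, "-", nrow(x$artifacts),
      "artifacts\n")
  print(x$artifacts)
  cat("Headline results:\n")
  utils::str(x$results, give.head = FALSE)
  invisible(x)
}
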