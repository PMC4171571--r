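# FNV-1a hash of a string, as hex; used to fingerprint run configs.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

default_run_config <- function() {
  list(
    preset = "act_chi",
    control_preset = "lb",
    stages = c("simulate", "motility", "population"),
    seed = 1,
    n_cells = 50, duration = 96, dt = 1 / 6,
    bin_edges = seq(0, 96, 2), fit_window = c(0, 2), window_len = 10,
    min_step = 1,
    timepoints = c(24, 48, 72, 96), n_events = 2000, n_replicates = 3,
    gate_quantile = 0.999,
    n_nuclei = 100, noise_sd = 2,
    qpcr = list(D0 = 0.01, k = 50, Fb = 200, s = 1, n_cycles = 40,
                noise_sd = 5, n_rep = 3)
  )
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic data
#' generated under a named condition preset, writes every result table
#' as CSV plus a JSON summary, and returns a manifest (config hash,
#' seeds, versions, output row counts). Identical configs and seeds
#' produce byte-identical tables.
#'
#' Stages: `simulate` (tracks + events), `motility` (velocities, bins,
#' ensemble MSD, diffusivity timecourse, turning-angle test),
#' `population` (gating, fractions, condition-vs-control tests when more
#' than one condition is simulated), `qia` (synthetic scene,
#' segmentation, records, correlations), `qpcr` (replicate curves, MAK2
#' fits, normalization).
#'
#' @param config named list overriding the defaults (see
#'   `streakcell:::default_run_config()`); may also be a YAML file path.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir = "streakcell_run") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::yaml.load_file(config)
  cfg <- utils::modifyList(default_run_config(), config)
  known <- c("simulate", "motility", "population", "qia", "qpcr")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  presets <- default_presets()
  for (p in c(cfg$preset, cfg$control_preset))
    if (!p %in% names(presets)) stop(sprintf("unknown preset '%s'", p))
  if (!"simulate" %in% cfg$stages) {
    inputs <- c(motility = "tracks.csv", population = "events.csv")
    for (st in intersect(names(inputs), cfg$stages))
      if (!file.exists(file.path(out_dir, inputs[[st]])))
        stop(sprintf("stage '%s' missing its input %s; run producer 'simulate'",
                     st, inputs[[st]]))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  preset <- presets[[cfg$preset]]
  outputs <- list()
  summary <- list(preset = cfg$preset, seed = cfg$seed)
  emit <- function(name, df) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(as.data.frame(df), path, row.names = FALSE)
    outputs[[name]] <<- nrow(df)
  }

  tracks <- NULL; events <- NULL
  if ("simulate" %in% cfg$stages) {
    tracks <- simulate_trajectories(preset, cfg$n_cells, cfg$duration,
                                    cfg$dt, seed = cfg$seed)
    emit("tracks", tracks)
    events <- simulate_event_population(preset, cfg$timepoints,
                                        cfg$n_events, cfg$n_replicates,
                                        seed = cfg$seed)
    emit("events", events)
  }
  if ("motility" %in% cfg$stages) {
    # always work from the written table so cached single-stage runs are
    # bit-identical to full runs
    tracks <- read_tracks(file.path(out_dir, "tracks.csv"), dt = cfg$dt)
    v <- instant_velocities(tracks, dt = cfg$dt)
    emit("velocities", v)
    b <- bin_velocities_by_start(v, cfg$bin_edges)
    emit("velocity_bins", b$summary)
    em <- ensemble_msd(tracks, max_lag = min(12, cfg$duration / 2),
                       dt = cfg$dt)
    emit("msd_ensemble", as.data.frame(em))
    dtc <- diffusivity_timecourse(tracks, window_len = cfg$window_len,
                                  fit_window = cfg$fit_window, dt = cfg$dt)
    emit("diffusivity_timecourse", dtc)
    ang <- turning_angles(tracks, min_step = cfg$min_step, dt = cfg$dt)
    if (length(ang) >= 8) {
      kt <- ks_uniformity_test(ang)
      summary$turning_angle_test <- list(ks_stat = kt$ks_stat,
                                         p_value = kt$p_value, n = kt$n)
    }
    summary$peak_bin_mean_velocity_umh <-
      max(b$summary$mean_v, na.rm = TRUE)
  }
  if ("population" %in% cfg$stages) {
    events <- read_events(file.path(out_dir, "events.csv"))
    control <- simulate_event_population(presets[[cfg$control_preset]],
                                         cfg$timepoints, cfg$n_events,
                                         cfg$n_replicates, seed = cfg$seed)
    gate <- threshold_from_control(gate_events(control)$intensity_afu,
                                   cfg$gate_quantile)
    fr <- fraction_positive_timecourse(gate_events(events), gate)
    emit("fractions_replicates", fr$replicates)
    emit("fractions_summary", fr$summary)
    summary$gate_afu <- gate
  }
  if ("qia" %in% cfg$stages) {
    scene <- synthesize_image_series(cfg$n_nuclei,
                                     channel_model_concordance(),
                                     noise_sd = cfg$noise_sd,
                                     seed = cfg$seed, n_frames = 2)
    write_image_scene(scene, file.path(out_dir, "scene.tif"))
    rec <- quantify_scene(scene, condition = cfg$preset)
    emit("qia_records", rec)
    corr <- pairwise_correlation_timecourse(rec, list(c("gfp", "antibody")))
    emit("qia_correlations", corr)
    summary$qia_pearson_r <- stats::cor(rec$mean_gfp, rec$mean_antibody)
  }
  if ("qpcr" %in% cfg$stages) {
    q <- cfg$qpcr
    target <- simulate_qpcr_replicates(
      mak2_params(q$D0, q$k, q$Fb, q$s), q$n_cycles, q$noise_sd, q$n_rep,
      seed = cfg$seed, gene = "target", sample = "s1")
    refc <- simulate_qpcr_replicates(
      mak2_params(q$D0 * 5, q$k, q$Fb, q$s), q$n_cycles, q$noise_sd,
      q$n_rep, seed = cfg$seed + 1, gene = "gapdh", sample = "s1")
    curves <- rbind(target, refc)
    emit("qpcr_curves", curves)
    res <- quantify_qpcr(curves, reference_gene = "gapdh")
    emit("qpcr_results", res)
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE,
                       digits = NA)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  manifest <- list(
    config = cfg,
    config_hash = fnv1a(as.character(cfg_json)),
    package_version = as.character(utils::packageVersion("streakcell")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Declarative table of reproduction targets: how each headline quantity
# is recomputed from scratch and the value it is checked against.
target_table <- function() {
  data.frame(
    id = paste0("t", 1:8),
    description = c(
      "plateau reporter-positive % (act_chi, mean of 48 h and 72 h)",
      "reporter-positive % at 72 h (act)",
      "reporter-positive % at 48 h (chi)",
      "peak 2-h-binned mean instant velocity, um/h (act_chi)",
      "KS p-value, pooled turning angles vs uniform (act_chi)",
      "median instant velocity, um/h (csa, motility blocked)",
      "per-nucleus reporter/protein Pearson r (concordance images)",
      "MSD plateau-onset time, h (act_chi ensemble)"
    ),
    target = c(33, 10, 25, 60, 1e-5, 36, 0.773, 3),
    tolerance = c(5, 5, 5, 6, NA, NA, 0.05, 1),
    cmp = c("eq", "eq", "eq", "eq", "le", "le", "eq", "eq"),
    stringsAsFactors = FALSE
  )
}

# Positive-fraction pipeline for one preset at the stated scale.
positive_fractions <- function(preset_name, seed,
                               timepoints = c(24, 48, 72, 96),
                               n_events = 10000, n_replicates = 3,
                               gate_quantile = 0.999) {
  ev <- simulate_event_population(get_preset(preset_name), timepoints,
                                  n_events, n_replicates, seed = seed)
  ctl <- simulate_event_population(get_preset("lb"), timepoints, n_events,
                                   n_replicates, seed = seed)
  gate <- threshold_from_control(gate_events(ctl)$intensity_afu,
                                 gate_quantile)
  fraction_positive_timecourse(gate_events(ev), gate)
}

#' Recompute every headline target from scratch
#'
#' Reruns the full pipeline for each reproduction target at its stated
#' problem size — simulating events, trajectories or images under the
#' shipped default presets, running the corresponding analysis, and
#' measuring the published quantity — and reports measured value, target
#' value, tolerance and pass/fail. Failures are reported, never raised.
#'
#' @param seed integer master seed (every source of randomness derives
#'   from it).
#' @return Data frame with columns `id`, `description`, `n`, `value`,
#'   `target`, `tolerance`, `cmp`, `pass`.
#' @export
reproduce_targets <- function(seed = 1) {
  tt <- target_table()
  value <- numeric(8); n <- numeric(8)

  fr1 <- positive_fractions("act_chi", seed)$summary
  value[1] <- mean(fr1$mean_pct[fr1$timepoint_h %in% c(48, 72)])
  n[1] <- 30000
  fr2 <- positive_fractions("act", seed)$summary
  value[2] <- fr2$mean_pct[fr2$timepoint_h == 72]
  n[2] <- 30000
  fr3 <- positive_fractions("chi", seed)$summary
  value[3] <- fr3$mean_pct[fr3$timepoint_h == 48]
  n[3] <- 30000

  tr4 <- simulate_trajectories(get_preset("act_chi"), 200, 96, 1 / 6,
                               seed = seed)
  v4 <- instant_velocities(tr4)
  b4 <- bin_velocities_by_start(v4, seq(0, 96, 2))
  value[4] <- max(b4$summary$mean_v, na.rm = TRUE)
  n[4] <- 200

  tr5 <- simulate_trajectories(get_preset("act_chi"), 100, 60, 1 / 6,
                               seed = seed)
  ang <- turning_angles(tr5, min_step = 1)
  kt <- ks_uniformity_test(ang)
  value[5] <- kt$p_value
  n[5] <- kt$n

  tr6 <- simulate_trajectories(get_preset("csa"), 100, 96, 1 / 6,
                               seed = seed)
  v6 <- instant_velocities(tr6)
  value[6] <- stats::median(v6$v_umh)
  n[6] <- nrow(v6)

  scene <- synthesize_image_series(500, channel_model_concordance(),
                                   noise_sd = 2, seed = seed,
                                   n_frames = 5, width = 360, height = 360)
  rec <- quantify_scene(scene)
  value[7] <- stats::cor(rec$mean_gfp, rec$mean_antibody)
  n[7] <- nrow(rec)

  tr8 <- simulate_trajectories(get_preset("act_chi"), 200, 60, 1 / 6,
                               seed = seed)
  em8 <- ensemble_msd(tr8, max_lag = 12)
  value[8] <- msd_plateau_onset(em8)$t_plateau
  n[8] <- 200

  tt$n <- n
  tt$value <- value
  tt$pass <- ifelse(tt$cmp == "le", value <= tt$target,
                    abs(value - tt$target) <= tt$tolerance)
  tt[c("id", "description", "n", "value", "target", "tolerance", "cmp",
       "pass")]
}
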