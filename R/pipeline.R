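# End-to-end runs: simulate -> classify / score -> report. All outputs are
# plain delimited text plus one deterministic JSON report, so two runs with
# the same seed produce byte-identical files.

#' Three-arm intravital scenario presets
#'
#' Synthetic emulation of the three intravital imaging arms of a
#' neutrophil experiment: a control-like arm with few, mostly sessile
#' tracks; an exposure-like arm (allergen plus particulate co-challenge)
#' with many neutrophil tracks dominated by adherent/tethering behavior;
#' and a nociceptor-ablated-like arm with fewer tracks but a larger motile
#' fraction, hence higher per-track total displacement. The per-arm counts
#' are the scenario definition, not estimates of the study's cell numbers.
#'
#' @param seed Base integer seed; arms use `seed`, `seed + 1`, `seed + 2`.
#' @return Named list of [movie_scenario()] objects
#'   (`control,ova_fpm,ablated`).
#' @export
arm_presets <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    control = movie_scenario("control",
      counts = c(adherent = 6, crawling = 2, patrolling = 2, tethering = 2),
      seed = seed),
    ova_fpm = movie_scenario("ova_fpm",
      counts = c(adherent = 20, crawling = 6, patrolling = 8, tethering = 10),
      seed = seed + 1L),
    ablated = movie_scenario("ablated",
      counts = c(adherent = 4, crawling = 8, patrolling = 8, tethering = 2),
      seed = seed + 2L)
  )
}

#' Run the track half of the pipeline
#'
#' Simulates every scenario, computes metrics, classifies behaviors and
#' summarizes each field of view, writing `tracks.csv`, `labels.csv`,
#' `classified.csv` and `fov_summary.csv` to `out_dir`.
#'
#' @param scenarios Named list of [movie_scenario()] objects (default
#'   [arm_presets()]).
#' @param thresholds A [classifier_thresholds()] object.
#' @param modes Mode parameter list (default [default_mode_presets()]).
#' @param out_dir Output directory (created if absent).
#' @return Invisible list with `tracks`, `labels`, `classified`,
#'   `fov_summary`.
#' @export
run_track_pipeline <- function(scenarios = arm_presets(),
                               thresholds = classifier_thresholds(),
                               modes = default_mode_presets(),
                               out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sims <- lapply(scenarios, simulate_movie, modes = modes)
  tracks <- as_track_table(do.call(rbind, lapply(sims, `[[`, "tracks")))
  labels <- do.call(rbind, lapply(sims, `[[`, "labels"))
  rownames(labels) <- NULL
  classified <- classify_tracks(tracks, thresholds, quiet = TRUE)
  fov_summary <- summarize_fovs(classified)
  write_tracks(tracks, file.path(out_dir, "tracks.csv"))
  utils::write.table(labels, file.path(out_dir, "labels.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(classified, file.path(out_dir, "classified.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  utils::write.table(fov_summary, file.path(out_dir, "fov_summary.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(list(tracks = tracks, labels = labels, classified = classified,
                 fov_summary = fov_summary))
}

#' Run the calcium half of the pipeline
#'
#' Simulates a trace batch, scores it against its protocol, calls
#' KCl-gated responders, computes per-dish responder fractions for the
#' given stimulus and normalizes them to vehicle controls, writing
#' `traces.csv`, `truth.csv`, `scores.csv` and `dish_fractions.csv`.
#'
#' @param scenario A [trace_scenario()] object.
#' @param threshold Responder amplitude threshold (default 1.2).
#' @param stimulus Stimulus label whose responder fractions are tabulated;
#'   defaults to the first non-KCl window of the protocol.
#' @param vehicle_label Control condition label for normalization; set to
#'   `NA` to skip normalization.
#' @param out_dir Output directory (created if absent).
#' @return Invisible list with `traces`, `truth`, `scores`,
#'   `dish_fractions`.
#' @export
run_calcium_pipeline <- function(scenario = trace_scenario(),
                                 threshold = 1.2,
                                 stimulus = NULL,
                                 vehicle_label = "vehicle",
                                 out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_batch(scenario)
  scores <- score_traces(sim$traces, scenario$protocol)
  scores <- call_responders(scores, threshold = threshold)
  if (is.null(stimulus)) {
    non_gate <- Filter(function(w) w$name != "KCl", scenario$protocol$windows)
    if (!length(non_gate)) stop("protocol has no non-KCl stimulus to tabulate")
    stimulus <- window_label(non_gate[[1]])
  }
  fractions <- responder_fractions(scores, stimulus)
  if (!is.na(vehicle_label) && vehicle_label %in% fractions$condition) {
    fractions <- normalize_to_vehicle(fractions, vehicle_label)
  }
  write_traces(sim$traces, file.path(out_dir, "traces.csv"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(scores, file.path(out_dir, "scores.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fractions, file.path(out_dir, "dish_fractions.csv"),
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(list(traces = sim$traces, truth = sim$truth, scores = scores,
                 dish_fractions = fractions))
}

# stable number formatting for the JSON report
.round_list <- function(x, digits = 10) {
  rapply(x, function(v) if (is.numeric(v)) round(v, digits) else v,
         how = "replace")
}

#' Build and write the run report
#'
#' Reads pipeline outputs from `in_dir` and writes `report.json` (stable
#' key order, deterministic bytes) plus delimited summary tables to
#' `out_dir`. Track outputs yield per-arm track counts, median net/total
#' displacements and behavior frequencies; calcium outputs yield per-dish
#' responder fractions, per-condition mean +/- SEM, and a nested
#' (dish-level) one-way ANOVA with Bonferroni post-hoc when at least two
#' conditions have two or more dishes.
#'
#' @param in_dir Directory holding outputs of [run_track_pipeline()]
#'   and/or [run_calcium_pipeline()].
#' @param out_dir Output directory (default `in_dir`).
#' @param seed Seed to echo into the report (provenance only).
#' @return Invisible report list (the structure written to
#'   `report.json`).
#' @export
report <- function(in_dir, out_dir = in_dir, seed = NA) {
  track_file <- file.path(in_dir, "classified.csv")
  fov_file <- file.path(in_dir, "fov_summary.csv")
  scores_file <- file.path(in_dir, "scores.csv")
  frac_file <- file.path(in_dir, "dish_fractions.csv")
  have_track <- file.exists(track_file) && file.exists(fov_file)
  have_calcium <- file.exists(scores_file) && file.exists(frac_file)
  if (!have_track && !have_calcium) {
    stop("missing inputs in '", in_dir, "': expected ",
         "classified.csv + fov_summary.csv (tracks) and/or ",
         "scores.csv + dish_fractions.csv (calcium)")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- list(
    software = "vitaltrace",
    version = as.character(utils::packageVersion("vitaltrace")),
    seed = if (is.na(seed)) NULL else as.integer(seed)
  )
  if (have_track) {
    cls <- utils::read.csv(track_file, stringsAsFactors = FALSE)
    fov <- utils::read.csv(fov_file, stringsAsFactors = FALSE)
    arms <- split(cls, factor(cls$fov_id, levels = unique(cls$fov_id)))
    rep$tracks <- list(
      n_tracks = lapply(arms, nrow),
      median_total_um = lapply(arms, function(a) stats::median(a$total_um)),
      median_net_um = lapply(arms, function(a) stats::median(a$net_um)),
      mean_net_um = lapply(arms, function(a) mean(a$net_um)),
      sem_net_um = lapply(arms, function(a) sem(a$net_um)),
      behavior_frequencies = lapply(split(fov, fov$fov_id), function(f) {
        as.list(f[1, grep("^freq_", names(f))])
      })
    )
  }
  if (have_calcium) {
    scores <- utils::read.csv(scores_file, stringsAsFactors = FALSE)
    fr <- utils::read.csv(frac_file, stringsAsFactors = FALSE)
    gs <- group_summary(fr$fraction, fr$condition)
    rep$calcium <- list(
      n_cells = length(unique(paste(scores$batch_id, scores$dish_id,
                                    scores$cell_id))),
      n_dishes = nrow(fr),
      fraction_by_condition = lapply(split(gs, gs$group), function(g) {
        list(n_dishes = g$n, mean = g$mean, sem = g$sem)
      })
    )
    tab <- table(fr$condition)
    if (length(tab) >= 2 && all(tab >= 2)) {
      aov_res <- one_way_anova(fr$fraction, fr$condition)
      ph <- pairwise_posthoc(fr$fraction, fr$condition, "bonferroni")
      rep$calcium$anova <- aov_res
      rep$calcium$posthoc_bonferroni <- lapply(seq_len(nrow(ph)), function(i) {
        list(group1 = ph$group1[i], group2 = ph$group2[i], p_adj = ph$p_adj[i])
      })
    }
  }
  jsonlite::write_json(.round_list(rep), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(rep)
}

#' Run the full pipeline: simulate, classify, score, report
#'
#' Convenience wrapper running [run_track_pipeline()] on the three-arm
#' presets and [run_calcium_pipeline()] on a default scenario, then
#' [report()], all under one seed. Two invocations with the same seed
#' produce byte-identical output files.
#'
#' @param out_dir Output directory.
#' @param seed Base integer seed.
#' @param track_scenarios,calcium_scenario Optional overrides of the
#'   default scenarios.
#' @return Invisible report list.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         track_scenarios = NULL,
                         calcium_scenario = NULL) {
  seed <- as.integer(seed)
  if (is.null(track_scenarios)) track_scenarios <- arm_presets(seed)
  if (is.null(calcium_scenario)) {
    calcium_scenario <- trace_scenario(
      responder_fraction = c(vehicle = 0.3, artemin = 0.6),
      seed = seed + 10L)
  }
  run_track_pipeline(track_scenarios, out_dir = out_dir)
  run_calcium_pipeline(calcium_scenario, out_dir = out_dir)
  report(out_dir, seed = seed)
}
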