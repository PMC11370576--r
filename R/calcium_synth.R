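# Seeded synthetic Fura-2 F340/F380 traces with known responder labels:
# a flat baseline with Gaussian noise, plus, for each stimulus a cell
# truly responds to, a transient rising through the stimulation window and
# decaying exponentially afterwards.

#' Trace-generation scenario
#'
#' Describes a synthetic calcium-imaging batch: stimulation protocol,
#' nesting (conditions x dishes x cells), true responder fractions and
#' effect sizes, noise level and sampling interval. Defaults emulate a
#' plausible Fura-2 recording: baseline ratio 0.8, noise SD 0.03 ratio
#' units, 20-s transient decay, one sample every 3 s. KCl responses are
#' drawn independently at a high rate (0.95) with a larger amplitude,
#' since depolarization recruits essentially all viable neurons.
#'
#' @param protocol A [stimulation_protocol()] object.
#' @param conditions Character vector of condition labels.
#' @param n_dishes Dishes per condition.
#' @param cells_per_dish Cells per dish.
#' @param responder_fraction True responder probability for non-gate
#'   stimuli: a single number, or a named vector by condition.
#' @param true_amplitude True peak/baseline factor of a response (>= 1).
#' @param kcl_rate Probability a cell is KCl-responsive (default 0.95).
#' @param kcl_amplitude Peak/baseline factor of the KCl response.
#' @param decay_tau_s Exponential decay time constant of transients (s).
#' @param baseline_level Baseline F340/F380 ratio.
#' @param noise_sd Gaussian noise SD, ratio units.
#' @param sample_interval_s Sampling interval, seconds (3 or 4 typical).
#' @param duration_s Recording length; defaults to 60 s past the last
#'   window end.
#' @param batch_id Batch identifier.
#' @param seed Integer seed.
#' @return List of class `trace_scenario`.
#' @export
trace_scenario <- function(protocol = protocol_sensitization(),
                           conditions = c("vehicle", "artemin"),
                           n_dishes = 4,
                           cells_per_dish = 25,
                           responder_fraction = 0.3,
                           true_amplitude = 1.5,
                           kcl_rate = 0.95,
                           kcl_amplitude = 2.0,
                           decay_tau_s = 20,
                           baseline_level = 0.8,
                           noise_sd = 0.03,
                           sample_interval_s = 3,
                           duration_s = NULL,
                           batch_id = "batch1",
                           seed = 1L) {
  stopifnot(inherits(protocol, "stimulation_protocol"),
            all(responder_fraction >= 0), all(responder_fraction <= 1),
            true_amplitude >= 1, kcl_rate >= 0, kcl_rate <= 1,
            kcl_amplitude >= 1, decay_tau_s > 0, baseline_level > 0,
            noise_sd >= 0, sample_interval_s > 0,
            n_dishes >= 1, cells_per_dish >= 1)
  last_end <- max(vapply(protocol$windows, `[[`, numeric(1), "end_s"))
  if (is.null(duration_s)) duration_s <- last_end + 60
  stopifnot(duration_s >= last_end)
  structure(list(protocol = protocol, conditions = conditions,
                 n_dishes = n_dishes, cells_per_dish = cells_per_dish,
                 responder_fraction = responder_fraction,
                 true_amplitude = true_amplitude, kcl_rate = kcl_rate,
                 kcl_amplitude = kcl_amplitude, decay_tau_s = decay_tau_s,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 sample_interval_s = sample_interval_s,
                 duration_s = duration_s, batch_id = batch_id,
                 seed = as.integer(seed)),
            class = "trace_scenario")
}

# responder probability for a given condition
.condition_fraction <- function(scenario, condition) {
  rf <- scenario$responder_fraction
  if (length(rf) == 1 && is.null(names(rf))) return(unname(rf))
  if (!condition %in% names(rf)) {
    stop("no responder_fraction for condition '", condition, "'")
  }
  unname(rf[[condition]])
}

# transient shape: linear rise from window start to peak 1 at window end,
# then exponential decay with time constant tau; support truncated at six
# time constants so stimuli separated by more than 6*tau see an exactly
# clean baseline
.transient <- function(t, start_s, end_s, tau) {
  rise <- (t - start_s) / (end_s - start_s)
  up <- t >= start_s & t <= end_s
  down <- t > end_s & t <= end_s + 6 * tau
  out <- numeric(length(t))
  out[up] <- rise[up]
  out[down] <- exp(-(t[down] - end_s) / tau)
  out
}

#' Simulate one cell's calcium trace
#'
#' Builds one noisy F340/F380 series: baseline plus one transient per
#' stimulus the cell truly responds to. A responding cell's ratio rises
#' linearly through the stimulation window to `baseline * amplitude` at
#' window end, then decays exponentially with `decay_tau_s` (the decay is
#' truncated at six time constants, so windows further apart than that see
#' an exactly clean baseline; closer windows are contaminated by the tail,
#' as in real recordings). Windows of a concentration series (shared
#' stimulus name) share one respond/ignore label. With `noise_sd = 0` the
#' sampled peak equals the generated peak exactly whenever the window end
#' lies on the sampling grid.
#'
#' @param responds Named logical vector: for each distinct stimulus name
#'   of the protocol, whether this cell responds.
#' @param scenario A [trace_scenario()] object.
#' @return Data frame `t_s,ratio` (one cell; no identifier columns).
#' @export
simulate_trace <- function(responds, scenario) {
  stopifnot(inherits(scenario, "trace_scenario"))
  p <- scenario$protocol
  stim_names <- unique(vapply(p$windows, `[[`, character(1), "name"))
  stopifnot(all(stim_names %in% names(responds)))
  t <- seq(0, scenario$duration_s, by = scenario$sample_interval_s)
  base <- scenario$baseline_level
  signal <- rep(base, length(t))
  for (w in p$windows) {
    if (!isTRUE(responds[[w$name]])) next
    amp <- if (w$name == "KCl") scenario$kcl_amplitude else scenario$true_amplitude
    bump <- base * (amp - 1) * .transient(t, w$start_s, w$end_s,
                                          scenario$decay_tau_s)
    signal <- pmax(signal, base + bump)
  }
  if (scenario$noise_sd > 0) {
    signal <- signal + stats::rnorm(length(t), 0, scenario$noise_sd)
  }
  data.frame(t_s = t, ratio = pmax(signal, 1e-6))
}

#' Simulate a full batch of dishes with ground-truth labels
#'
#' Generates every condition x dish x cell of the scenario. Responder
#' labels are drawn per distinct stimulus name: non-gate stimuli at the
#' condition's `responder_fraction`, KCl at `kcl_rate`. The scenario seed
#' spawns one substream per cell so cell counts can change without
#' perturbing earlier cells.
#'
#' @param scenario A [trace_scenario()] object.
#' @return List with `traces` (a trace table) and `truth` (one row per
#'   cell: identifiers, condition and one logical `responds_<name>` column
#'   per stimulus).
#' @export
simulate_batch <- function(scenario) {
  stopifnot(inherits(scenario, "trace_scenario"))
  p <- scenario$protocol
  stim_names <- unique(vapply(p$windows, `[[`, character(1), "name"))
  n_cells <- length(scenario$conditions) * scenario$n_dishes *
    scenario$cells_per_dish
  set.seed(scenario$seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_cells, replace = TRUE)
  traces <- vector("list", n_cells)
  truth <- vector("list", n_cells)
  k <- 0L
  for (cond in scenario$conditions) {
    frac <- .condition_fraction(scenario, cond)
    for (d in seq_len(scenario$n_dishes)) {
      dish_id <- sprintf("%s_dish%02d", cond, d)
      for (ci in seq_len(scenario$cells_per_dish)) {
        k <- k + 1L
        set.seed(sub_seeds[k])
        responds <- vapply(stim_names, function(nm) {
          rate <- if (nm == "KCl") scenario$kcl_rate else frac
          stats::runif(1) < rate
        }, logical(1))
        tr <- simulate_trace(responds, scenario)
        cell_id <- sprintf("cell%03d", ci)
        traces[[k]] <- data.frame(batch_id = scenario$batch_id,
                                  dish_id = dish_id, cell_id = cell_id,
                                  condition = cond, t_s = tr$t_s,
                                  ratio = tr$ratio)
        tr_row <- data.frame(batch_id = scenario$batch_id, dish_id = dish_id,
                             cell_id = cell_id, condition = cond)
        for (nm in stim_names) {
          tr_row[[paste0("responds_", gsub("[^A-Za-z0-9]+", "_", nm))]] <-
            responds[[nm]]
        }
        truth[[k]] <- tr_row
      }
    }
  }
  list(traces = as_trace_table(do.call(rbind, traces)),
       truth = do.call(rbind, truth))
}
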