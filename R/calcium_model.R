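# Ratiometric (Fura-2 F340/F380) calcium trace scoring: 15-s maximum
# compression, stimulation-window response amplitudes against a 30-s
# pre-stimulus baseline, KCl-gated responder calling, per-dish averaging
# and batch-wise vehicle normalization.

TRACE_COLUMNS <- c("batch_id", "dish_id", "cell_id", "condition", "t_s", "ratio")

#' Read a calcium trace table
#'
#' Reads a delimited text table of F340/F380 ratio time series with header
#' `batch_id,dish_id,cell_id,condition,t_s,ratio`, one row per sampled
#' timepoint per cell.
#'
#' @param file Path to a delimited text file.
#' @param sep Field separator (default comma).
#' @return A validated trace table (`data.frame`, class `trace_table`).
#' @export
read_traces <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  as_trace_table(df)
}

#' Validate a calcium trace table
#'
#' Checks columns, positive finite ratios and strictly increasing
#' timestamps within each cell, then sorts samples by time within cell.
#'
#' @param df Data frame with the trace-table columns.
#' @return `df` sorted, class `trace_table` prepended.
#' @export
as_trace_table <- function(df) {
  missing_cols <- setdiff(TRACE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("trace table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[TRACE_COLUMNS]
  for (col in c("t_s", "ratio")) {
    if (!is.numeric(df[[col]]) || anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      stop("column '", col, "' must be finite numeric")
    }
  }
  if (any(df$ratio <= 0)) stop("F340/F380 ratios must be positive")
  if (any(df$t_s < 0)) stop("timestamps must be non-negative")
  df <- df[order(df$batch_id, df$dish_id, df$cell_id, df$t_s), , drop = FALSE]
  rownames(df) <- NULL
  key <- .cell_key(df)
  dup <- stats::ave(df$t_s, key, FUN = function(t) anyDuplicated(t) > 0)
  if (any(dup > 0)) stop("duplicate timestamps within a cell's trace")
  class(df) <- unique(c("trace_table", class(df)))
  df
}

.cell_key <- function(df) {
  paste(df$batch_id, df$dish_id, df$cell_id, sep = "\r")
}

#' Write a calcium trace table
#'
#' @param traces A trace table.
#' @param file Output path.
#' @param sep Field separator.
#' @export
write_traces <- function(traces, file, sep = ",") {
  traces <- as_trace_table(as.data.frame(traces))
  utils::write.table(traces, file, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Stimulus window
#'
#' One perfusion window of a stimulation protocol: agonist name,
#' concentration label and start/end seconds.
#'
#' @param name Stimulus name (e.g. `"AITC"`, `"capsaicin"`, `"KCl"`).
#' @param concentration Free-text concentration label (e.g. `"10 uM"`).
#' @param start_s,end_s Window boundaries, seconds; `0 <= start < end`.
#' @return List of class `stimulus_window`.
#' @export
stimulus_window <- function(name, concentration = "", start_s, end_s) {
  stopifnot(is.character(name), nzchar(name),
            is.numeric(start_s), is.numeric(end_s),
            start_s >= 0, start_s < end_s)
  structure(list(name = name, concentration = as.character(concentration),
                 start_s = start_s, end_s = end_s),
            class = "stimulus_window")
}

#' Stimulation protocol
#'
#' An ordered, non-overlapping list of stimulus windows plus the scoring
#' parameters: the pre-stimulus baseline length and how far past a window
#' end the peak search may extend (calcium peaks can lag washout; the pad
#' is always capped at the next window's onset).
#'
#' Repeated windows with the same stimulus name form an ascending
#' concentration series: every window of the series is scored against the
#' single baseline preceding the series' first window, because later
#' windows have no clean local baseline.
#'
#' @param windows List of [stimulus_window()] objects, time-ordered.
#' @param baseline_window_s Baseline length before stimulation onset,
#'   seconds (default 30).
#' @param peak_search_pad_s Seconds past window end searched for the peak
#'   (default 30; capped at the next window onset).
#' @return List of class `stimulation_protocol`.
#' @export
stimulation_protocol <- function(windows, baseline_window_s = 30,
                                 peak_search_pad_s = 30) {
  stopifnot(length(windows) >= 1,
            all(vapply(windows, inherits, logical(1), "stimulus_window")),
            baseline_window_s > 0, peak_search_pad_s >= 0)
  starts <- vapply(windows, `[[`, numeric(1), "start_s")
  ends <- vapply(windows, `[[`, numeric(1), "end_s")
  if (is.unsorted(starts, strictly = TRUE)) {
    stop("stimulus windows must be in increasing time order")
  }
  if (any(ends[-length(ends)] > starts[-1])) {
    stop("stimulus windows must not overlap")
  }
  structure(list(windows = windows, baseline_window_s = baseline_window_s,
                 peak_search_pad_s = peak_search_pad_s),
            class = "stimulation_protocol")
}

#' Read a stimulation protocol from a YAML config
#'
#' Expected layout: a `windows` list of `{name, concentration, start_s,
#' end_s}` mappings plus optional scalars `baseline_window_s` and
#' `peak_search_pad_s`.
#'
#' @param file Path to a YAML file.
#' @return A [stimulation_protocol()] object.
#' @export
read_protocol <- function(file) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg$windows)) stop("protocol config needs a 'windows' list")
  windows <- lapply(cfg$windows, function(wi) {
    stimulus_window(wi$name, concentration = wi$concentration %||% "",
                    start_s = wi$start_s, end_s = wi$end_s)
  })
  stimulation_protocol(
    windows,
    baseline_window_s = cfg$baseline_window_s %||% 30,
    peak_search_pad_s = cfg$peak_search_pad_s %||% 30
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sequential AITC dose-series protocol
#'
#' The ascending TRPA1-agonist series used for cultured vagal sensory
#' neurons: AITC at 10 uM (60-90 s), 30 uM (90-120 s) and 100 uM
#' (120-150 s), then KCl 40 mM (420-435 s) as the pan-neuronal
#' depolarizing viability control.
#'
#' @return A [stimulation_protocol()] object.
#' @export
protocol_aitc_series <- function() {
  stimulation_protocol(list(
    stimulus_window("AITC", "10 uM", 60, 90),
    stimulus_window("AITC", "30 uM", 90, 120),
    stimulus_window("AITC", "100 uM", 120, 150),
    stimulus_window("KCl", "40 mM", 420, 435)
  ))
}

#' Single AITC / capsaicin / KCl protocol
#'
#' The sensitization assay protocol: AITC 300 uM (240-270 s), capsaicin
#' 300 nM (320-335 s), KCl 40 mM (720-735 s).
#'
#' @return A [stimulation_protocol()] object.
#' @export
protocol_sensitization <- function() {
  stimulation_protocol(list(
    stimulus_window("AITC", "300 uM", 240, 270),
    stimulus_window("capsaicin", "300 nM", 320, 335),
    stimulus_window("KCl", "40 mM", 720, 735)
  ))
}

# label used to identify a window in score tables; disambiguates a
# concentration series
window_label <- function(w) {
  if (nzchar(w$concentration)) paste(w$name, w$concentration) else w$name
}

#' Compress a trace to per-bin maxima
#'
#' Compresses a ratio time series by taking the maximum ratio in each
#' half-open time bin `[k*bin_s, (k+1)*bin_s)`. The compressed sample is
#' stamped at the bin start; empty bins are omitted. Applied to a whole
#' trace table, each cell's trace is compressed independently. The
#' operation is idempotent: compressing a compressed trace with the same
#' bin width returns it unchanged.
#'
#' @param traces A trace table (one or many cells).
#' @param bin_s Bin width in seconds (default 15).
#' @return A compressed trace table.
#' @export
compress_max <- function(traces, bin_s = 15) {
  stopifnot(bin_s > 0)
  traces <- as_trace_table(as.data.frame(traces))
  bin <- floor(traces$t_s / bin_s) * bin_s
  key <- paste(.cell_key(traces), format(bin, scientific = FALSE), sep = "\r")
  idx <- vapply(split(seq_len(nrow(traces)), factor(key, levels = unique(key))),
                function(i) i[which.max(traces$ratio[i])], integer(1))
  out <- traces[idx, , drop = FALSE]
  out$t_s <- bin[idx]
  as_trace_table(out)
}

# samples of one cell within [from, to]; 'right_open' drops t == to
.in_window <- function(trace, from, to, right_open = FALSE) {
  sel <- trace$t_s >= from & (if (right_open) trace$t_s < to else trace$t_s <= to)
  trace[sel, , drop = FALSE]
}

# baseline start for a window: first window of the same stimulus name
# (concentration series share the pre-series baseline)
.baseline_anchor <- function(window, protocol) {
  for (w in protocol$windows) {
    if (w$name == window$name) return(w$start_s)
  }
  window$start_s
}

# end of the peak-search interval for a window
.peak_end <- function(window, protocol) {
  later <- vapply(protocol$windows, `[[`, numeric(1), "start_s")
  later <- later[later > window$start_s]
  cap <- if (length(later)) min(later) else Inf
  min(window$end_s + protocol$peak_search_pad_s, max(cap, window$end_s))
}

#' Response amplitude of one cell for one stimulus window
#'
#' Scores one stimulation: baseline = mean ratio over the
#' `baseline_window_s` seconds preceding the (series) stimulation onset;
#' peak = maximum ratio from window start to window end plus the peak
#' search pad (capped at the next window onset); amplitude = peak /
#' baseline. By default scoring runs on the 15-s maximum-compressed trace;
#' set `compress = FALSE` to score the raw trace.
#'
#' @param trace One cell's trace (rows of a trace table for a single cell).
#' @param window A [stimulus_window()] of the protocol.
#' @param protocol The [stimulation_protocol()] containing `window`.
#' @param compress Compress with [compress_max()] before scoring (default
#'   TRUE).
#' @param bin_s Compression bin width.
#' @return One-row data frame: `stimulus`, `baseline_ratio`, `peak_ratio`,
#'   `amplitude`.
#' @export
response_amplitude <- function(trace, window, protocol,
                               compress = TRUE, bin_s = 15) {
  stopifnot(inherits(window, "stimulus_window"),
            inherits(protocol, "stimulation_protocol"))
  trace <- as.data.frame(trace)
  anchor <- .baseline_anchor(window, protocol)
  base_from <- anchor - protocol$baseline_window_s
  if (base_from < 0) {
    stop("coverage error: baseline window starts before t = 0")
  }
  if (min(trace$t_s) > base_from || max(trace$t_s) < window$end_s) {
    stop("coverage error: trace does not span the baseline and stimulus ",
         "windows of '", window_label(window), "'")
  }
  if (compress) trace <- compress_max(trace, bin_s = bin_s)
  base_samples <- .in_window(trace, base_from, anchor, right_open = TRUE)
  if (nrow(base_samples) == 0) {
    stop("coverage error: no samples in the baseline window of '",
         window_label(window), "'")
  }
  peak_samples <- .in_window(trace, window$start_s, .peak_end(window, protocol))
  if (nrow(peak_samples) == 0) {
    stop("coverage error: no samples in the stimulus window of '",
         window_label(window), "'")
  }
  baseline <- mean(base_samples$ratio)
  peak <- max(peak_samples$ratio)
  data.frame(stimulus = window_label(window),
             baseline_ratio = baseline, peak_ratio = peak,
             amplitude = peak / baseline)
}

#' Score every cell of a trace table against a protocol
#'
#' Computes [response_amplitude()] for every (cell, stimulus window) pair.
#'
#' @param traces A trace table.
#' @param protocol A [stimulation_protocol()] object.
#' @inheritParams response_amplitude
#' @return Data frame `batch_id,dish_id,cell_id,condition,stimulus,
#'   baseline_ratio,peak_ratio,amplitude`, one row per cell per window.
#' @export
score_traces <- function(traces, protocol, compress = TRUE, bin_s = 15) {
  traces <- as_trace_table(as.data.frame(traces))
  if (compress) {
    traces <- compress_max(traces, bin_s = bin_s)
    compress <- FALSE  # already compressed once; scoring below is direct
  }
  key <- .cell_key(traces)
  cells <- split(traces, factor(key, levels = unique(key)))
  rows <- lapply(cells, function(tr) {
    meta <- tr[1, c("batch_id", "dish_id", "cell_id", "condition")]
    scores <- do.call(rbind, lapply(protocol$windows, function(w) {
      response_amplitude(tr, w, protocol, compress = FALSE)
    }))
    cbind(meta[rep(1, nrow(scores)), , drop = FALSE], scores)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call responders and apply the KCl viability gate
#'
#' A cell is a responder to a stimulus iff its amplitude is at least
#' `threshold`. Cells are included in denominators (flag `included`) iff
#' they respond to the depolarizing gate stimulus (KCl by default): a cell
#' that does not depolarize to KCl is not a viable neuron and is dropped
#' from all response fractions.
#'
#' The responder threshold defaults to 1.2 (a 20 percent rise of the
#' F340/F380 ratio over baseline); it is a scoring choice, not a measured
#' constant, and conclusions should be checked for sensitivity to it.
#'
#' @param scores Output of [score_traces()].
#' @param threshold Amplitude (peak/baseline) at or above which a cell is
#'   a responder (default 1.2).
#' @param gate_stimulus Name of the viability gate stimulus (default
#'   `"KCl"`); matched against window stimulus names. Set to `NA` to
#'   disable gating (all cells included).
#' @return `scores` with logical columns `responder` and `included`.
#' @export
call_responders <- function(scores, threshold = 1.2, gate_stimulus = "KCl") {
  stopifnot(is.numeric(threshold), threshold > 0)
  scores$responder <- scores$amplitude >= threshold
  if (is.na(gate_stimulus)) {
    scores$included <- TRUE
    return(scores)
  }
  is_gate <- startsWith(scores$stimulus, gate_stimulus)
  if (!any(is_gate)) {
    stop("config error: no '", gate_stimulus,
         "' window in the scored protocol; cannot apply the viability gate")
  }
  key <- .cell_key(scores)
  gate_ok <- tapply(scores$responder & is_gate, key, any)
  scores$included <- as.vector(gate_ok[key])
  scores
}

#' Per-dish mean amplitude over responsive neurons
#'
#' For each dish, the arithmetic mean amplitude of the neurons that
#' responded to the given stimulus (responders only, included cells only).
#' Dishes with zero responders carry no average; they are excluded with a
#' warning listing them.
#'
#' @param scores Output of [call_responders()].
#' @param stimulus Stimulus label to average (a `stimulus` value of the
#'   score table).
#' @return Data frame `batch_id,dish_id,condition,n_responders,
#'   mean_amplitude`, one row per dish with at least one responder.
#' @export
per_dish_average <- function(scores, stimulus) {
  stopifnot("responder" %in% names(scores))
  s <- scores[scores$stimulus == stimulus & scores$included, , drop = FALSE]
  if (nrow(s) == 0) stop("no included cells scored for stimulus '", stimulus, "'")
  dish_key <- paste(s$batch_id, s$dish_id, sep = "\r")
  parts <- split(s, factor(dish_key, levels = unique(dish_key)))
  rows <- lapply(parts, function(d) {
    resp <- d[d$responder, , drop = FALSE]
    data.frame(batch_id = d$batch_id[1], dish_id = d$dish_id[1],
               condition = d$condition[1], n_responders = nrow(resp),
               mean_amplitude = if (nrow(resp)) mean(resp$amplitude) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dropped <- out$n_responders == 0
  if (any(dropped)) {
    warning(sum(dropped), " dish(es) with zero '", stimulus,
            "' responders excluded: ",
            paste(out$dish_id[dropped], collapse = ", "))
    out <- out[!dropped, , drop = FALSE]
  }
  out
}

#' Per-dish responder fractions
#'
#' Fraction of included (gate-responsive) cells in each dish that respond
#' to the given stimulus.
#'
#' @inheritParams per_dish_average
#' @return Data frame `batch_id,dish_id,condition,n_cells,n_responders,
#'   fraction`.
#' @export
responder_fractions <- function(scores, stimulus) {
  stopifnot(all(c("responder", "included") %in% names(scores)))
  s <- scores[scores$stimulus == stimulus & scores$included, , drop = FALSE]
  if (nrow(s) == 0) stop("no included cells scored for stimulus '", stimulus, "'")
  dish_key <- paste(s$batch_id, s$dish_id, sep = "\r")
  parts <- split(s, factor(dish_key, levels = unique(dish_key)))
  rows <- lapply(parts, function(d) {
    data.frame(batch_id = d$batch_id[1], dish_id = d$dish_id[1],
               condition = d$condition[1], n_cells = nrow(d),
               n_responders = sum(d$responder),
               fraction = mean(d$responder))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize per-dish responder fractions to vehicle controls per batch
#'
#' Divides each dish's responder fraction by the mean fraction of the
#' vehicle-treated dishes of the same batch, so treatment effects are
#' expressed as fold change over control within each experimental batch.
#'
#' @param fractions Output of [responder_fractions()] (needs `batch_id`,
#'   `condition`, `fraction`).
#' @param vehicle_label Condition label of the control dishes (default
#'   `"vehicle"`).
#' @return `fractions` with an extra `normalized_fraction` column.
#' @export
normalize_to_vehicle <- function(fractions, vehicle_label = "vehicle") {
  stopifnot(all(c("batch_id", "condition", "fraction") %in% names(fractions)))
  out <- fractions
  out$normalized_fraction <- NA_real_
  for (b in unique(out$batch_id)) {
    in_batch <- out$batch_id == b
    veh <- out$fraction[in_batch & out$condition == vehicle_label]
    if (length(veh) == 0) {
      stop("normalization error: batch '", b, "' has no '", vehicle_label,
           "' dish")
    }
    if (mean(veh) == 0) {
      stop("normalization error: batch '", b, "' vehicle mean fraction is 0")
    }
    out$normalized_fraction[in_batch] <- out$fraction[in_batch] / mean(veh)
  }
  out
}
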