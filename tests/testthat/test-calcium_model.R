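test_that("compress_max takes per-bin maxima with half-open bins and is idempotent", {
  tr <- as_cell_trace(seq(0, 27, by = 3), c(1, 2, 3, 2, 1, 5, 4, 4, 4, 4))
  cm <- compress_max(tr, 15)
  expect_equal(cm$t_s, c(0, 15))
  expect_equal(cm$ratio, c(3, 5))  # 15 s sample falls in the second bin

  # 3-s and 4-s sampling bin counts follow [k*bin, (k+1)*bin)
  t4 <- as_cell_trace(c(0, 4, 8, 12, 16), rep(1, 5))
  expect_equal(compress_max(t4, 15)$t_s, c(0, 15))  # 4 + 1 samples
  t3 <- as_cell_trace(seq(0, 30, by = 3), rep(1, 11))
  expect_equal(compress_max(t3, 15)$t_s, c(0, 15, 30))  # 5 + 5 + 1

  # constant trace compresses to a constant; double compression = identity
  const <- as_cell_trace(seq(0, 100, by = 3), rep(0.8, 34))
  cc <- compress_max(const, 15)
  expect_true(all(cc$ratio == 0.8))
  expect_equal(compress_max(cc, 15), cc)

  set.seed(4)
  noisy <- as_cell_trace(seq(0, 300, by = 3), runif(101, 0.5, 2))
  once <- compress_max(noisy, 15)
  expect_equal(compress_max(once, 15), once)
})

test_that("response amplitude is peak over window divided by pre-stimulus baseline mean", {
  proto <- stimulation_protocol(list(stimulus_window("AITC", "300 uM", 60, 90)))
  t <- seq(0, 150, by = 3)
  ratio <- rep(1, length(t))
  ratio[t >= 60 & t <= 90] <- 1.5
  tr <- as_cell_trace(t, ratio)
  sc <- response_amplitude(tr, proto$windows[[1]], proto)
  expect_equal(sc$baseline_ratio, 1)
  expect_equal(sc$peak_ratio, 1.5)
  expect_equal(sc$amplitude, 1.5)

  # flat trace has amplitude exactly 1 at any level
  flat <- as_cell_trace(t, rep(0.73, length(t)))
  expect_equal(response_amplitude(flat, proto$windows[[1]], proto)$amplitude, 1)

  # scale invariance: multiplying a trace by c leaves the amplitude unchanged
  for (c_mult in c(0.1, 10)) {
    scaled <- tr
    scaled$ratio <- scaled$ratio * c_mult
    expect_equal(response_amplitude(scaled, proto$windows[[1]], proto)$amplitude,
                 sc$amplitude, tolerance = 1e-12)
  }

  # insufficient coverage of the baseline window errors
  late <- as_cell_trace(seq(50, 150, by = 3), rep(1, 34))
  expect_error(response_amplitude(late, proto$windows[[1]], proto), "coverage")
})

test_that("peak search pad is capped at the next stimulus onset", {
  proto <- stimulation_protocol(list(
    stimulus_window("AITC", "10 uM", 60, 90),
    stimulus_window("KCl", "40 mM", 100, 115)
  ), peak_search_pad_s = 30)
  t <- seq(0, 160, by = 1)
  ratio <- rep(1, length(t))
  ratio[t == 95] <- 1.4   # between windows, within the capped pad
  ratio[t == 105] <- 3.0  # belongs to the KCl window, not AITC
  tr <- as_cell_trace(t, ratio)
  sc <- response_amplitude(tr, proto$windows[[1]], proto, compress = FALSE)
  expect_equal(sc$peak_ratio, 1.4)
})

test_that("concentration-series windows share the pre-series baseline", {
  proto <- protocol_aitc_series()
  t <- seq(0, 450, by = 3)
  ratio <- rep(2, length(t))
  ratio[t >= 60] <- 1  # baseline period [30, 60) has ratio 2; all else 1
  ratio[t == 90] <- 3; ratio[t == 120] <- 4; ratio[t == 150] <- 5
  tr <- as_cell_trace(t, ratio)
  scores <- do.call(rbind, lapply(proto$windows[1:3], function(w) {
    response_amplitude(tr, w, proto, compress = FALSE)
  }))
  expect_equal(scores$baseline_ratio, rep(2, 3))
  expect_equal(scores$amplitude, c(3, 4, 5) / 2)
})

test_that("responder calling applies the KCl viability gate", {
  scores <- data.frame(
    batch_id = "b1", dish_id = "d1",
    cell_id = rep(c("c1", "c2", "c3"), each = 2),
    condition = "vehicle",
    stimulus = rep(c("AITC 300 uM", "KCl 40 mM"), 3),
    baseline_ratio = 1,
    peak_ratio = c(1.5, 2.0, 1.5, 1.05, 1.1, 2.0),
    amplitude = c(1.5, 2.0, 1.5, 1.05, 1.1, 2.0)
  )
  called <- call_responders(scores, threshold = 1.2)
  c1 <- called[called$cell_id == "c1", ]
  expect_true(all(c1$included) && c1$responder[c1$stimulus == "AITC 300 uM"])
  # AITC responder but KCl-negative: excluded regardless
  expect_false(any(called$included[called$cell_id == "c2"]))
  # KCl responder, AITC non-responder: included, not a responder
  c3 <- called[called$cell_id == "c3", ]
  expect_true(all(c3$included))
  expect_false(c3$responder[c3$stimulus == "AITC 300 uM"])

  expect_error(call_responders(scores[scores$stimulus != "KCl 40 mM", ]),
               "config error")
  ungated <- call_responders(scores[scores$stimulus != "KCl 40 mM", ],
                             gate_stimulus = NA)
  expect_true(all(ungated$included))

  fr <- responder_fractions(called, "AITC 300 uM")
  expect_equal(fr$n_cells, 2)       # c2 gated out
  expect_equal(fr$fraction, 0.5)    # c1 yes, c3 no
})

test_that("per-dish averages cover responders only and drop empty dishes", {
  scores <- data.frame(
    batch_id = "b1",
    dish_id = c("d1", "d1", "d2", "d3"),
    cell_id = c("c1", "c2", "c3", "c4"),
    condition = "vehicle", stimulus = "AITC",
    baseline_ratio = 1, peak_ratio = c(1.2, 1.4, 1.7, 1.0),
    amplitude = c(1.2, 1.4, 1.7, 1.0),
    responder = c(TRUE, TRUE, TRUE, FALSE), included = TRUE
  )
  expect_warning(avg <- per_dish_average(scores, "AITC"), "zero")
  expect_equal(avg$dish_id, c("d1", "d2"))
  expect_equal(avg$mean_amplitude, c(1.3, 1.7))
})

test_that("vehicle normalization is per batch and errors without controls", {
  fr <- data.frame(
    batch_id = rep(c("b1", "b2"), each = 3),
    dish_id = paste0("d", 1:6),
    condition = rep(c("vehicle", "vehicle", "artemin"), 2),
    n_cells = 10, n_responders = 3,
    fraction = c(0.2, 0.2, 0.3, 0.1, 0.3, 0.5)
  )
  nm <- normalize_to_vehicle(fr)
  expect_equal(nm$normalized_fraction, c(1, 1, 1.5, 0.5, 1.5, 2.5))
  # mean vehicle normalized fraction is 1 within each batch by construction
  veh <- nm[nm$condition == "vehicle", ]
  expect_equal(as.numeric(tapply(veh$normalized_fraction, veh$batch_id, mean)),
               c(1, 1))
  expect_error(normalize_to_vehicle(fr[fr$condition != "vehicle", ]),
               "no 'vehicle' dish")
  zero <- fr
  zero$fraction[zero$condition == "vehicle" & zero$batch_id == "b1"] <- 0
  expect_error(normalize_to_vehicle(zero), "mean fraction is 0")
})

test_that("protocol constructors validate windows and YAML round-trips", {
  expect_error(stimulation_protocol(list(
    stimulus_window("A", "", 0, 50), stimulus_window("B", "", 40, 60))),
    "overlap")
  expect_error(stimulus_window("A", "", 90, 60))

  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "baseline_window_s: 30",
    "peak_search_pad_s: 20",
    "windows:",
    "  - {name: AITC, concentration: 300 uM, start_s: 240, end_s: 270}",
    "  - {name: KCl, concentration: 40 mM, start_s: 720, end_s: 735}"
  ), f)
  p <- read_protocol(f)
  expect_s3_class(p, "stimulation_protocol")
  expect_equal(p$peak_search_pad_s, 20)
  expect_equal(p$windows[[1]]$start_s, 240)
})
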