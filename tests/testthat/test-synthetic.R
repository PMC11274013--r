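test_that("rendered events have the drawn spectral content", {
  tone <- class_template("tone", f0_range = c(2000, 2000),
                         duration_range = c(0.5, 0.5),
                         amplitude_range = c(1, 1))
  ev <- render_event(tone, seed = 1)
  pg <- stats::spec.pgram(stats::ts(ev$samples, frequency = 22050),
                          plot = FALSE, taper = 0)
  expect_equal(pg$freq[which.max(pg$spec)], 2000, tolerance = 22050 / length(ev$samples))

  # chirp: instantaneous frequency (from the analytic signal) increases
  ch <- class_template("chirp_up", f0_range = c(1000, 2000),
                       duration_range = c(0.5, 0.5), amplitude_range = c(1, 1))
  ev2 <- render_event(ch, seed = 2)
  x <- ev2$samples
  n <- length(x)
  X <- stats::fft(x)
  h <- rep(0, n); h[1] <- 1; h[2:(n %/% 2)] <- 2; h[n %/% 2 + 1] <- 1
  analytic <- stats::fft(X * h, inverse = TRUE) / n
  phase <- signal::unwrap(Arg(analytic))
  inst_f <- diff(phase) * 22050 / (2 * pi)
  core <- inst_f[500:(n - 500)] # ignore ramps
  sm <- stats::filter(core, rep(1 / 101, 101), sides = 2)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) > -1)) # monotone up to smoothing jitter
  expect_lt(sm[1], 1400)
  expect_gt(sm[length(sm)], 1600)

  # degenerate amplitude renders silence
  silent <- class_template("tone", amplitude_range = c(0, 0))
  expect_true(all(render_event(silent, seed = 3)$samples == 0))

  # too short for the onset/offset ramps
  tiny <- class_template("tone", duration_range = c(0.005, 0.005))
  expect_error(render_event(tiny, seed = 4), "ramp")
})

test_that("pulse trains and noise bands render sensibly", {
  pt <- class_template("pulse_train", f0_range = c(1000, 1000),
                       duration_range = c(0.5, 0.5),
                       pulse_rate_range = c(20, 20))
  ev <- render_event(pt, seed = 5)
  expect_gt(mean(ev$samples == 0), 0.3) # gated carrier has silent gaps

  nb <- class_template("noise_band", f0_range = c(3000, 3000),
                       duration_range = c(0.5, 0.5), bandwidth = 400)
  ev2 <- render_event(nb, seed = 6)
  pg <- stats::spec.pgram(stats::ts(ev2$samples, frequency = 22050),
                          plot = FALSE, taper = 0)
  in_band <- pg$freq > 2700 & pg$freq < 3300
  expect_gt(sum(pg$spec[in_band]) / sum(pg$spec), 0.95)
})

test_that("scenes are reproducible, disjoint and correctly annotated", {
  cfg <- scene_config(duration_s = 15, events_per_class = 3, seed = 42)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$waveform$samples, s2$waveform$samples)
  expect_identical(s1$events, s2$events)

  ev <- s1$events
  expect_equal(nrow(ev), 6) # 2 classes x 3 events
  expect_true(all(ev$onset_s >= 0 & ev$offset_s <= 15))
  ord <- order(ev$onset_s)
  expect_true(all(ev$onset_s[ord][-1] >= ev$offset_s[ord][-nrow(ev)]))

  # durations respect the template ranges
  for (cl in names(cfg$classes)) {
    dr <- cfg$classes[[cl]]$duration_range
    durs <- ev$offset_s[ev$label == cl] - ev$onset_s[ev$label == cl]
    expect_true(all(durs >= dr[1] - 1e-6 & durs <= dr[2] + 1e-6))
  }
})

test_that("generated scenes hit the requested signal-to-noise ratio", {
  ns <- asNamespace("fewshotSED")
  for (snr in c(10, 20)) {
    sc <- generate_scene(scene_config(duration_s = 20, events_per_class = 5,
                                      snr_db = snr, seed = 7))
    expect_lt(abs(ns$scene_snr(sc$waveform, sc$events) - snr), 1)
  }
})

test_that("UNK relabeling spares the first five shots of each class", {
  cfg <- scene_config(duration_s = 40, events_per_class = 8,
                      unk_fraction = 0.3, seed = 9)
  sc <- generate_scene(cfg)
  expect_gt(sum(sc$events$status == "UNK"), 0)
  for (cl in unique(sc$events$label)) {
    sub <- sc$events[sc$events$label == cl, ]
    expect_true(all(sub$status[order(sub$onset_s)][1:5] == "POS"))
  }
})

test_that("infeasible packing is refused", {
  expect_error(scene_config(duration_s = 2, events_per_class = 10), "density")
})

test_that("generate_dataset writes the development-set layout", {
  d <- withr::local_tempdir()
  cls <- benchmark_classes()
  tr <- lapply(1:2, function(i) scene_config(duration_s = 15,
                                             events_per_class = 3, seed = i))
  vl <- list(scene_config(duration_s = 20, classes = cls["A"],
                          events_per_class = 6, seed = 5))
  mf <- generate_dataset(d, tr, vl, seed = 1)
  expect_equal(nrow(mf), 3)
  expect_length(list.files(file.path(d, "Training_Set"), pattern = "wav$"), 2)
  expect_length(list.files(file.path(d, "Validation_Set"), pattern = "wav$"), 1)

  # CSV file names match their WAVs, and rows round-trip through the reader
  for (csv in list.files(d, pattern = "csv$", recursive = TRUE,
                         full.names = TRUE)) {
    if (basename(csv) == "manifest.csv") next
    ann <- read_annotations(csv, keep = c("POS", "NEG", "UNK"))
    expect_equal(unique(ann$audiofilename),
                 sub("\\.csv$", ".wav", basename(csv)))
    expect_true(all(ann$offset_s > ann$onset_s))
  }

  # validation files satisfy the first-5-shots protocol
  vcsv <- list.files(file.path(d, "Validation_Set"), pattern = "csv$",
                     full.names = TRUE)
  vann <- read_annotations(vcsv)
  expect_gte(sum(vann$status == "POS"), 5)
  expect_equal(unique(vann$label), "A")
})
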