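test_that("WAV files round-trip through write_wav/load_audio", {
  f <- withr::local_tempfile(fileext = ".wav")
  set.seed(1)
  x <- runif(22050, -0.5, 0.5)
  write_wav(x, 22050, f)
  w <- load_audio(f, 22050)
  expect_s3_class(w, "waveform")
  expect_equal(w$rate, 22050)
  expect_lt(max(abs(w$samples - x)), 1 / 32768) # within 16-bit quantization

  # 24-bit and float round trips
  for (bits in c(24, 32)) {
    write_wav(x, 22050, f, bits = bits)
    expect_lt(max(abs(load_audio(f)$samples - x)), 1 / 2^23)
  }

  # stereo is averaged to mono
  write_wav(rbind(x, -x), 22050, f)
  expect_lt(max(abs(load_audio(f)$samples)), 1 / 32768 + 1e-9)
})

test_that("resampling preserves silence and tone frequency", {
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(numeric(44100), 44100, f)
  w <- load_audio(f, 22050)
  expect_length(w$samples, 22050)
  expect_true(all(w$samples == 0))

  tone <- sin(2 * pi * 440 * (0:44099) / 44100)
  write_wav(tone, 44100, f)
  w <- load_audio(f, 22050)
  pg <- stats::spec.pgram(stats::ts(w$samples, frequency = 22050),
                          plot = FALSE, taper = 0)
  expect_equal(pg$freq[which.max(pg$spec)], 440, tolerance = 2)
})

test_that("corrupt or empty audio is rejected", {
  expect_error(load_audio(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".wav")
  writeLines("not a wav", f)
  expect_error(load_audio(f), "RIFF")
})

test_that("Mel frame counts follow the framing arithmetic", {
  cfg <- mel_config()
  s <- mel_spectrogram(numeric(22050), cfg)
  expect_equal(nrow(s$values), 22050 %/% 256 + 1) # 87
  expect_equal(ncol(s$values), 128)

  set.seed(42)
  for (i in 1:20) {
    n <- sample(1100:40000, 1)
    x <- rnorm(n, sd = 0.1)
    expect_equal(nrow(mel_spectrogram(x, cfg)$values), n %/% 256 + 1)
    cfg_nc <- mel_config(center = FALSE)
    expect_equal(nrow(mel_spectrogram(x, cfg_nc)$values),
                 (n - 1024) %/% 256 + 1)
  }
  expect_error(mel_spectrogram(numeric(1000), cfg), "shorter")
})

test_that("doubling the hop halves the frame count", {
  x <- rnorm(30000, sd = 0.1)
  n1 <- nrow(mel_spectrogram(x, mel_config(hop_mel = 256))$values)
  n2 <- nrow(mel_spectrogram(x, mel_config(hop_mel = 512))$values)
  expect_lte(abs(n1 / 2 - n2), 1)
})

test_that("Mel energies are floored at eps and silence hits the floor", {
  cfg <- mel_config()
  s <- mel_spectrogram(numeric(22050), cfg)
  expect_true(all(s$values == cfg$eps))
  s2 <- mel_spectrogram(rnorm(22050, sd = 0.1), cfg)
  expect_true(all(s2$values >= cfg$eps))
  expect_true(all(is.finite(s2$values)))
})

test_that("a pure tone peaks in the Mel band nearest its frequency", {
  cfg <- mel_config()
  tone <- sin(2 * pi * 1000 * (0:22049) / 22050)
  s <- mel_spectrogram(tone, cfg)
  centers <- attr(s, "band_center_hz")
  expect_equal(which.max(colSums(s$values)), which.min(abs(centers - 1000)))
  # per-frame argmax too (interior frames, away from edge padding)
  argmaxes <- apply(s$values[10:70, ], 1, which.max)
  expect_true(all(argmaxes == which.min(abs(centers - 1000))))
})

test_that("PCEN matches its closed form and converges on constant input", {
  # single frame: M = E, so value = (E/(eps+E)^a + d)^r - d^r exactly
  cfg <- pcen_config()
  E <- matrix(c(0.5, 2, 7, 100), 1, 4)
  out <- pcen(E, cfg)
  expect_equal(as.numeric(out),
               (E / (cfg$eps + E)^cfg$gain_alpha + cfg$bias_delta)^cfg$root_r -
                 cfg$bias_delta^cfg$root_r,
               ignore_attr = TRUE)

  # constant input, alpha = 1, delta = 0, r = 1: steady state E/(eps + E)
  cfg1 <- pcen_config(gain_alpha = 1, bias_delta = 0, root_r = 1, eps = 1e-6)
  E <- matrix(3, 400, 2)
  out <- pcen(E, cfg1)
  expect_equal(out[400, 1], 3 / (1e-6 + 3), tolerance = 1e-9)
})

test_that("PCEN with alpha = 1 is scale invariant in steady state", {
  cfg <- pcen_config(gain_alpha = 1)
  set.seed(3)
  E <- matrix(abs(rnorm(300 * 8, 5, 0.5)), 300, 8)
  a <- pcen(E, cfg)
  b <- pcen(10 * E, cfg)
  burn <- 200:300
  expect_lt(max(abs(a[burn, ] - b[burn, ]) / abs(a[burn, ])), 1e-3)
})

test_that("PCEN rejects invalid input", {
  expect_error(pcen(matrix(c(1, NA), 1, 2)), "finite")
  expect_error(pcen(matrix(-1, 2, 2)), "non-negative")
})

test_that("frame_time maps indices to half-open frame starts", {
  s <- mel_spectrogram(rnorm(30000, sd = 0.1), mel_config())
  expect_equal(frame_time(s, 0), 0)
  expect_equal(frame_time(s, 100), 100 * 256 / 22050)
  i <- 0:(nrow(s$values) - 2)
  expect_equal(frame_time(s, i + 1) - frame_time(s, i),
               rep(s$frame_hop_s, length(i)))
  expect_error(frame_time(s, -1), "range")
  expect_error(frame_time(s, nrow(s$values)), "range")
})

test_that("patch assembly tiles short events and respects the grid", {
  cfg <- mel_config()
  s <- mel_spectrogram(rnorm(22050 * 2, sd = 0.1), cfg)
  p <- make_patches(s, cfg)
  plen <- ceiling(cfg$seg_len_s / s$frame_hop_s)
  expect_equal(dim(p$patches)[2], plen)
  expect_equal(p$info$start_s[1], 0)
  expect_equal(diff(p$info$first_frame[1:2]),
               max(1, round(cfg$seg_hop_s / s$frame_hop_s)))

  # an event shorter than one patch is tiled to patch length
  ns <- asNamespace("fewshotSED")
  short <- ns$patches_for_interval(s, cfg, 0.5, 0.51)
  expect_length(short, 1)
  expect_equal(nrow(short[[1]]), plen)
})
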