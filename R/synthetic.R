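#' Vocalization class template
#'
#' Parametric stand-ins for call types (tonal whistles, up/down sweeps,
#' pulse trains, band-limited noise bursts). Event parameters are drawn
#' uniformly from the template ranges at render time.
#'
#' @param kind One of `"tone"`, `"chirp_up"`, `"chirp_down"`,
#'   `"pulse_train"`, `"noise_band"`.
#' @param f0_range Fundamental / center frequency range in Hz (for
#'   chirps: sweep endpoints). Must stay below Nyquist.
#' @param duration_range Event duration range in seconds.
#' @param amplitude_range Peak amplitude range (dimensionless).
#' @param pulse_rate_range Pulse repetition rate in Hz (`pulse_train`).
#' @param bandwidth Noise bandwidth in Hz (`noise_band`).
#' @return A `class_template` list.
#' @export
class_template <- function(kind = c("tone", "chirp_up", "chirp_down",
                                    "pulse_train", "noise_band"),
                           f0_range = c(1500, 2500),
                           duration_range = c(0.15, 0.4),
                           amplitude_range = c(0.5, 1),
                           pulse_rate_range = c(10, 30),
                           bandwidth = 400) {
  kind <- match.arg(kind)
  if (any(f0_range <= 0) || diff(f0_range) < 0) abort("invalid `f0_range`")
  if (max(f0_range) >= 11025) abort("`f0_range` must stay below Nyquist at 22.05 kHz")
  if (any(duration_range <= 0) || diff(duration_range) < 0) abort("invalid `duration_range`")
  if (any(amplitude_range < 0) || diff(amplitude_range) < 0) abort("invalid `amplitude_range`")
  structure(list(kind = kind, f0_range = f0_range,
                 duration_range = duration_range,
                 amplitude_range = amplitude_range,
                 pulse_rate_range = pulse_rate_range,
                 bandwidth = bandwidth),
            class = "class_template")
}

#' Render one synthetic event
#'
#' Draws duration, frequency and amplitude from the template ranges and
#' synthesizes the waveform at 22.05 kHz with 10 ms raised-cosine
#' onset/offset ramps.
#'
#' @param template A [class_template()].
#' @param sample_rate Sample rate in Hz.
#' @param seed Optional seed for the parameter draws.
#' @return List with `samples` and the drawn `params`.
#' @export
render_event <- function(template, sample_rate = 22050, seed = NULL) {
  with_seed(seed, {
    dur <- runif(1, template$duration_range[1], template$duration_range[2])
    amp <- runif(1, template$amplitude_range[1], template$amplitude_range[2])
    ramp_s <- 0.01
    if (dur < 2 * ramp_s) {
      abort(sprintf("duration %.3f s shorter than two 10 ms ramps", dur))
    }
    n <- max(1L, round(dur * sample_rate))
    t <- (seq_len(n) - 1) / sample_rate
    kind <- template$kind
    params <- list(duration_s = dur, amplitude = amp, kind = kind)

    if (kind == "tone") {
      f0 <- runif(1, template$f0_range[1], template$f0_range[2])
      x <- sin(2 * pi * f0 * t)
      params$f0 <- f0
    } else if (kind %in% c("chirp_up", "chirp_down")) {
      f_lo <- template$f0_range[1]; f_hi <- template$f0_range[2]
      if (kind == "chirp_up") { f_start <- f_lo; f_end <- f_hi }
      else { f_start <- f_hi; f_end <- f_lo }
      # linear sweep: phase = 2*pi*(f_start*t + (f_end-f_start)/(2*dur)*t^2)
      x <- sin(2 * pi * (f_start * t + (f_end - f_start) / (2 * dur) * t^2))
      params$f_start <- f_start; params$f_end <- f_end
    } else if (kind == "pulse_train") {
      f0 <- runif(1, template$f0_range[1], template$f0_range[2])
      rate <- runif(1, template$pulse_rate_range[1], template$pulse_rate_range[2])
      gate <- as.numeric((t * rate) %% 1 < 0.5)
      x <- sin(2 * pi * f0 * t) * gate
      params$f0 <- f0; params$pulse_rate <- rate
    } else { # noise_band
      f0 <- runif(1, template$f0_range[1], template$f0_range[2])
      wn <- rnorm(n)
      spec <- fft(wn)
      freqs <- (seq_len(n) - 1) / n * sample_rate
      freqs <- pmin(freqs, sample_rate - freqs) # fold to [0, sr/2]
      keep <- freqs >= f0 - template$bandwidth / 2 &
        freqs <= f0 + template$bandwidth / 2
      spec[!keep] <- 0
      x <- Re(fft(spec, inverse = TRUE)) / n
      if (max(abs(x)) > 0) x <- x / max(abs(x))
      params$f0 <- f0
    }

    ramp_n <- round(ramp_s * sample_rate)
    env <- rep(1, n)
    if (ramp_n > 0 && n >= 2 * ramp_n) {
      up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
      env[seq_len(ramp_n)] <- up
      env[(n - ramp_n + 1):n] <- rev(up)
    }
    list(samples = amp * x * env, params = params)
  })
}

#' Synthetic scene configuration
#'
#' Describes one annotated recording: duration, the class templates it
#' contains, event density, background type and signal-to-noise ratio.
#'
#' @param duration_s Scene length in seconds.
#' @param classes Named list of [class_template()]s; names become class
#'   labels.
#' @param events_per_class Events rendered per class.
#' @param snr_db Signal-to-noise ratio in dB: mean event power relative
#'   to background power.
#' @param background `"white"` or `"pink"` noise.
#' @param unk_fraction Fraction of events relabeled `UNK`.
#' @param seed Integer seed; the same seed reproduces the scene
#'   bit-for-bit.
#' @return A `scene_config` list.
#' @export
scene_config <- function(duration_s = 60,
                         classes = list(A = class_template("tone", c(1800, 2200)),
                                        B = class_template("chirp_up", c(5000, 7000))),
                         events_per_class = 10, snr_db = 20,
                         background = c("white", "pink"), unk_fraction = 0,
                         seed = 1) {
  stopifnot_scalar_num(duration_s, "duration_s", 0, strict_lower = TRUE)
  stopifnot_scalar_num(events_per_class, "events_per_class", 1)
  stopifnot_scalar_num(unk_fraction, "unk_fraction", 0, 1)
  if (is.null(names(classes)) || any(names(classes) == "")) {
    abort("`classes` must be a named list of class templates")
  }
  max_event <- sum(vapply(classes, function(tp) tp$duration_range[2], numeric(1))) *
    events_per_class
  if (max_event >= duration_s) {
    abort("total event time would exceed the scene duration; lower the density")
  }
  structure(list(duration_s = duration_s, classes = classes,
                 events_per_class = as.integer(events_per_class),
                 snr_db = snr_db, background = match.arg(background),
                 unk_fraction = unk_fraction, seed = as.integer(seed)),
            class = "scene_config")
}

#' Generate an annotated synthetic scene
#'
#' Renders `events_per_class` events per class, places them uniformly at
#' random without overlap (rejection sampling with 50 ms guard gaps),
#' adds background noise at `snr_db` relative to the mean event power,
#' peak-normalizes to -1 dBFS, and returns the waveform with its
#' annotation table. A fraction `unk_fraction` of events is relabeled
#' UNK (never the first five of a class, so the first-K-shots protocol
#' stays satisfiable).
#'
#' @param cfg A [scene_config()].
#' @param sample_rate Sample rate in Hz.
#' @return List with `waveform` (a `waveform`) and `events` (annotation
#'   tibble with `status`).
#' @export
generate_scene <- function(cfg, sample_rate = 22050) {
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * sample_rate)
    guard <- 0.05
    placed <- data.frame(onset = numeric(0), offset = numeric(0),
                         label = character(0))
    snippets <- list()
    for (cl in names(cfg$classes)) {
      for (e in seq_len(cfg$events_per_class)) {
        ev <- render_event(cfg$classes[[cl]], sample_rate)
        dur <- length(ev$samples) / sample_rate
        ok <- FALSE
        for (try in seq_len(500)) {
          onset <- runif(1, 0, cfg$duration_s - dur)
          disjoint <- !nrow(placed) ||
            all(placed$offset + guard <= onset |
                  placed$onset - guard >= onset + dur)
          if (disjoint) { ok <- TRUE; break }
        }
        if (!ok) abort("could not place all events; lower the event density")
        placed <- rbind(placed, data.frame(onset = onset, offset = onset + dur,
                                           label = cl))
        snippets[[length(snippets) + 1L]] <- ev$samples
      }
    }

    x <- numeric(n)
    for (i in seq_len(nrow(placed))) {
      i0 <- round(placed$onset[i] * sample_rate) + 1L
      seg <- snippets[[i]]
      i1 <- min(n, i0 + length(seg) - 1L)
      x[i0:i1] <- x[i0:i1] + seg[seq_len(i1 - i0 + 1L)]
    }

    ev_power <- mean(vapply(snippets, function(s) mean(s^2), numeric(1)))
    noise_power <- ev_power / 10^(cfg$snr_db / 10)
    bg <- if (cfg$background == "white") {
      rnorm(n)
    } else {
      wn <- fft(rnorm(n))
      f <- pmax(1, pmin(seq_len(n) - 1, n - (seq_len(n) - 1)))
      Re(fft(wn / sqrt(f), inverse = TRUE)) / n
    }
    bg <- bg / sqrt(mean(bg^2)) * sqrt(noise_power)
    x <- x + bg

    # peak normalize to -1 dBFS
    x <- x / max(abs(x)) * 10^(-1 / 20)

    status <- rep("POS", nrow(placed))
    n_unk <- round(cfg$unk_fraction * nrow(placed))
    if (n_unk > 0) {
      eligible <- unlist(lapply(split(seq_len(nrow(placed)), placed$label),
                                function(idx) {
        ord <- idx[order(placed$onset[idx])]
        if (length(ord) > 5) ord[-seq_len(5)] else integer(0)
      }))
      if (length(eligible)) {
        pick <- eligible[sample.int(length(eligible),
                                    min(n_unk, length(eligible)))]
        status[pick] <- "UNK"
      }
    }
    events <- event_table(placed$onset, placed$offset, label = placed$label,
                          status = status)
    list(waveform = structure(list(samples = x, rate = sample_rate),
                              class = "waveform"),
         events = events)
  })
}

# Measured SNR of a generated scene: event-region power above the
# background power estimated from un-annotated samples, in dB.
scene_snr <- function(waveform, events) {
  x <- waveform$samples
  mask <- rep(FALSE, length(x))
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, round(events$onset_s[i] * waveform$rate) + 1L)
    i1 <- min(length(x), round(events$offset_s[i] * waveform$rate))
    mask[i0:i1] <- TRUE
  }
  p_ev <- mean(x[mask]^2)
  p_bg <- mean(x[!mask]^2)
  10 * log10(pmax(p_ev - p_bg, .Machine$double.eps) / p_bg)
}

#' Write a directory tree of synthetic training and validation scenes
#'
#' Mirrors the development-set layout used in few-shot bioacoustic
#' benchmarks: `Training_Set/` holds WAV + multi-class CSV pairs
#' (POS/NEG/UNK per class column); `Validation_Set/` holds WAV +
#' single-class CSV pairs (POS/UNK for the target class only). Every
#' validation scene is checked to contain at least 5 POS events of its
#' target class.
#'
#' @param out_dir Output directory (created).
#' @param train_configs List of [scene_config()]s for training scenes.
#' @param val_configs List of [scene_config()]s for validation scenes.
#' @param val_targets Target class per validation scene (default: first
#'   class of each config).
#' @param seed Base seed; per-file seeds are derived from it, overriding
#'   the per-config seeds.
#' @return Manifest tibble (one row per file) with `split`, `wav`,
#'   `csv`, `n_events`, invisibly written to `manifest.csv`.
#' @export
generate_dataset <- function(out_dir, train_configs, val_configs,
                             val_targets = NULL, seed = 1) {
  dir.create(file.path(out_dir, "Training_Set"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "Validation_Set"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list()

  for (i in seq_along(train_configs)) {
    cfg <- train_configs[[i]]
    cfg$seed <- (seed * 1000L + i) %% .Machine$integer.max
    sc <- generate_scene(cfg)
    base <- sprintf("train_%02d", i)
    wav <- file.path(out_dir, "Training_Set", paste0(base, ".wav"))
    csv <- file.path(out_dir, "Training_Set", paste0(base, ".csv"))
    write_wav(sc$waveform$samples, sc$waveform$rate, wav)
    ev <- dplyr::mutate(sc$events, audiofilename = paste0(base, ".wav"),
                        .before = 1)
    write_annotations(ev, csv, classes = names(cfg$classes))
    manifest[[length(manifest) + 1L]] <-
      tibble::tibble(split = "train", wav = wav, csv = csv,
                     n_events = nrow(ev))
  }

  for (i in seq_along(val_configs)) {
    cfg <- val_configs[[i]]
    target <- if (!is.null(val_targets)) val_targets[[i]] else names(cfg$classes)[1]
    attempt <- 0L
    repeat {
      cfg$seed <- (seed * 1000L + 500L + i + 37L * attempt) %% .Machine$integer.max
      sc <- generate_scene(cfg)
      n_pos <- sum(sc$events$label == target & sc$events$status == "POS")
      if (n_pos >= 5L) break
      attempt <- attempt + 1L
      if (attempt > 20L) abort("could not generate a validation scene with >= 5 POS target events")
    }
    base <- sprintf("val_%02d", i)
    wav <- file.path(out_dir, "Validation_Set", paste0(base, ".wav"))
    csv <- file.path(out_dir, "Validation_Set", paste0(base, ".csv"))
    write_wav(sc$waveform$samples, sc$waveform$rate, wav)
    ev <- sc$events |>
      dplyr::filter(.data$label == target) |>
      dplyr::mutate(audiofilename = paste0(base, ".wav"), .before = 1)
    write_annotations(ev, csv, classes = target)
    manifest[[length(manifest) + 1L]] <-
      tibble::tibble(split = "val", wav = wav, csv = csv, n_events = nrow(ev))
  }

  mf <- dplyr::bind_rows(manifest)
  readr::write_csv(mf, file.path(out_dir, "manifest.csv"), progress = FALSE)
  mf
}

#' Collect labeled training patches from a generated training set
#'
#' Reads every WAV/CSV pair under `Training_Set/`, extracts Mel + PCEN
#' features, and cuts patches from inside each POS event, labeled with
#' the event's class — the base dataset for encoder pre-training. By
#' default an explicit `background` class of patches sampled from
#' un-annotated stretches is added, so the embedding learns a
#' call-versus-noise axis even when the training set has few event
#' classes.
#'
#' @param train_dir Path to the `Training_Set` directory.
#' @param mel_cfg A [mel_config()].
#' @param pcen_cfg A [pcen_config()].
#' @param n_background Background patches sampled per file (0 disables
#'   the background class).
#' @param seed Seed for the background sampling.
#' @return List with `patches` (list of matrices) and `labels`.
#' @export
build_base_dataset <- function(train_dir, mel_cfg = mel_config(),
                               pcen_cfg = pcen_config(),
                               n_background = 100, seed = 1) {
  csvs <- sort(list.files(train_dir, pattern = "\\.csv$", full.names = TRUE))
  patches <- list(); labels <- character(0)
  for (csv in csvs) {
    ann <- read_annotations(csv, keep = c("POS", "UNK"))
    wav <- file.path(train_dir, sub("\\.csv$", ".wav", basename(csv)))
    if (!file.exists(wav)) next
    feats <- pcen(mel_spectrogram(load_audio(wav, mel_cfg$sample_rate),
                                  mel_cfg), pcen_cfg)
    pos <- ann[ann$status == "POS", , drop = FALSE]
    for (i in seq_len(nrow(pos))) {
      ps <- patches_for_interval(feats, mel_cfg, pos$onset_s[i], pos$offset_s[i])
      patches <- c(patches, ps)
      labels <- c(labels, rep(pos$label[i], length(ps)))
    }
    if (n_background > 0) {
      ap <- make_patches(feats, mel_cfg)
      clear <- vapply(seq_len(nrow(ap$info)), function(j) {
        !any(pmax(ann$onset_s, ap$info$start_s[j]) <
               pmin(ann$offset_s, ap$info$end_s[j]))
      }, logical(1))
      idx <- which(clear)
      if (length(idx)) {
        take <- with_seed(seed,
          idx[sample.int(length(idx), min(n_background, length(idx)))])
        bg <- lapply(take, function(j) {
          feats$values[ap$info$first_frame[j]:ap$info$last_frame[j], ,
                       drop = FALSE]
        })
        patches <- c(patches, bg)
        labels <- c(labels, rep("background", length(bg)))
      }
    }
  }
  if (!length(patches)) abort(sprintf("no labeled patches found under %s", train_dir))
  list(patches = patches, labels = labels)
}
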