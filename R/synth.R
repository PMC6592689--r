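# Ground-truth synthetic data: directed-song timelines, class-structured
# neuron event schedules, GCaMP6s-kernel fluorescence traces (and movies),
# multiunit/single-unit spike trains, and air-sac pressure waveforms.
#
# Defaults reproduce the statistical regime the analyses assume: ~0.6-0.7 s
# motifs grouped into bouts and phrases (inter-bout silences < 2 s,
# inter-phrase > 2 s), sparse peri-song events ramping toward -1.5 s before
# phrase onset, motif-locked song events with 55 ms onset jitter and 0.7
# per-motif participation, a calcium kernel with ~0.112 s rise to peak and
# 1.25 s decay, multiunit rate ramps beginning 1.5 s pre-song, tonic
# spontaneous spiking turning irregular in pre/song/post epochs, and
# respiratory cycles of ~0.38 s (quiet) vs ~0.18 s (song) at ~58% expiratory
# duty cycle.

#' Synthetic-data generator configuration
#'
#' Returns the default generator configuration, with any field overridden by
#' name. Times in seconds, rates in Hz.
#'
#' @param ... named overrides of the defaults.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(...) {
  cfg <- list(
    fps = 30,
    # timeline
    n_phrases = 2,
    quiet_lead = 12,          # silence before the first phrase
    quiet_tail = 12,          # silence after the last phrase
    phrase_gap_range = c(12, 16),
    bouts_per_phrase = 1:3,
    motifs_per_bout = 1:3,
    bout_gap_range = c(0.8, 1.8),
    n_intro_range = 2:4,
    intro_dur = 0.08, intro_gap = 0.08,
    syllables_per_motif = 4, syllable_dur = 0.12, syllable_gap = 0.05,
    motif_gap = 0.1,
    # neuron event statistics
    peri_peak_rate = 0.8,     # peak of the pre-song ramp (events/s/neuron)
    peri_peak_time = -1.5,    # ramp peak relative to phrase onset
    peri_ramp_start = -3.5,   # ramp foot relative to phrase onset
    post_peak_rate_frac = 0.7,
    gap_rate_frac = 0.15,     # event rate in within-phrase gaps, x peak
    motif_participation = 0.7,
    onset_jitter_sd = 0.055,
    # calcium kernel / trace
    tau_rise = 0.029,         # gives ~0.112 s kernel time-to-peak
    tau_decay = 1.25,
    amp_mean = 8, amp_sd = 1.5, amp_min = 5,  # trace units (= noise SDs at
    noise_sd = 1.0,                           # the default noise_sd of 1)
    drift_amp = 0.3, drift_period = 45,
    baseline_offset = 10, background_level = 4,
    # multiunit / single-unit spiking
    mu_baseline_rate = 25, mu_song_rate = 70,
    mu_step_time = -1.5,      # ramp begins here, reaches song rate at -0.5
    mu_ramp_end = -0.5,
    mu_post_decay = 0.5,
    su_rates = c(spontaneous = 25, pre_song = 25, song = 30, post_song = 25),
    su_shapes = c(spontaneous = 8, pre_song = 0.5, song = 0.5, post_song = 0.5),
    # respiration
    resp_fs = 22050,
    quiet_cycle = c(mean = 0.38, sd = 0.04), quiet_duty = 58,
    song_cycle = c(mean = 0.18, sd = 0.03), song_duty = 57,
    quiet_amp = 1, song_amp = 3,
    resp_pause_frac = 0.25,   # end-expiratory pause, fraction of expiration
    resp_noise_sd = 0.01
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

#' Time of the calcium kernel's peak
#'
#' For the difference-of-exponentials kernel with the configured rise and
#' decay constants; the default constants put the peak near 0.112 s.
#'
#' @param config a `synth_config`.
#' @export
kernel_peak_time <- function(config = synth_config()) {
  tr <- config$tau_rise; td <- config$tau_decay
  log(td / tr) / (1 / tr - 1 / td)
}

#' Generate a directed-song timeline
#'
#' Emits introductory notes and motif syllables organized into bouts and
#' phrases (inter-bout silences drawn below the 2-s phrase rule, inter-phrase
#' gaps well above it), and records the true phrase and bout boundaries.
#'
#' @param config a `synth_config`.
#' @param seed integer seed.
#' @return list of class `synth_timeline`: `syllables` (annotation table),
#'   `phrases` and `bouts` (ground truth), `motifs` (per-motif onsets),
#'   `trial_length`, `config`, `seed`.
#' @export
gen_timeline <- function(config = synth_config(), seed = 1) {
  set.seed(substream_seed(seed, 1))
  cfg <- config
  syl <- list(); motifs <- list()
  phrase_truth <- list(); bout_truth <- list()
  t <- cfg$quiet_lead
  motif_dur <- cfg$syllables_per_motif * cfg$syllable_dur +
    (cfg$syllables_per_motif - 1) * cfg$syllable_gap
  syl_labels <- paste0("syl_", letters[seq_len(cfg$syllables_per_motif)])
  for (p in seq_len(cfg$n_phrases)) {
    phrase_on <- t
    n_bouts <- sample(rep(cfg$bouts_per_phrase, 2), 1)
    for (b in seq_len(n_bouts)) {
      bout_on <- t
      if (b == 1L) {
        n_intro <- sample(rep(cfg$n_intro_range, 2), 1)
        for (k in seq_len(n_intro)) {
          syl[[length(syl) + 1L]] <- data.frame(
            onset_s = t, offset_s = t + cfg$intro_dur, label = "intro")
          t <- t + cfg$intro_dur + cfg$intro_gap
        }
      }
      n_motifs <- sample(rep(cfg$motifs_per_bout, 2), 1)
      for (m in seq_len(n_motifs)) {
        motifs[[length(motifs) + 1L]] <- data.frame(
          phrase_idx = p, onset_s = t, offset_s = t + motif_dur)
        for (s in seq_len(cfg$syllables_per_motif)) {
          syl[[length(syl) + 1L]] <- data.frame(
            onset_s = t, offset_s = t + cfg$syllable_dur,
            label = syl_labels[s])
          t <- t + cfg$syllable_dur +
            if (s < cfg$syllables_per_motif) cfg$syllable_gap else 0
        }
        if (m < n_motifs) t <- t + cfg$motif_gap
      }
      bout_truth[[length(bout_truth) + 1L]] <- data.frame(
        phrase_idx = p, onset_s = bout_on, offset_s = t)
      if (b < n_bouts) t <- t + stats::runif(1, cfg$bout_gap_range[1L],
                                             cfg$bout_gap_range[2L])
    }
    phrase_truth[[p]] <- data.frame(phrase_idx = p, onset_s = phrase_on,
                                    offset_s = t)
    if (p < cfg$n_phrases) {
      t <- t + stats::runif(1, cfg$phrase_gap_range[1L],
                            cfg$phrase_gap_range[2L])
    }
  }
  trial_length <- t + cfg$quiet_tail
  syllables <- do.call(rbind, syl)
  rownames(syllables) <- NULL
  structure(list(
    syllables = syllables,
    phrases = do.call(rbind, phrase_truth),
    bouts = do.call(rbind, bout_truth),
    motifs = do.call(rbind, motifs),
    trial_length = trial_length,
    config = cfg, seed = seed
  ), class = "synth_timeline")
}

# Peri-song event-rate profile relative to one phrase: a ramp rising from
# ramp_start to a peak at peak_time, declining toward phrase onset; after the
# phrase, a sharp increase then a gradual ramp-off over the post window.
peri_rate_profile <- function(rel, cfg, side) {
  peak <- cfg$peri_peak_rate
  if (side == "pre") {
    r <- numeric(length(rel))
    up <- rel >= cfg$peri_ramp_start & rel <= cfg$peri_peak_time
    dn <- rel > cfg$peri_peak_time & rel < -0.1
    r[up] <- peak * (rel[up] - cfg$peri_ramp_start) /
      (cfg$peri_peak_time - cfg$peri_ramp_start)
    r[dn] <- peak * (1 - 0.9 * (rel[dn] - cfg$peri_peak_time) /
                       (-0.1 - cfg$peri_peak_time))
    r
  } else {
    r <- numeric(length(rel))
    up <- rel >= 0.1 & rel <= 0.5
    dn <- rel > 0.5 & rel <= 5
    pk <- peak * cfg$post_peak_rate_frac
    r[up] <- pk * (rel[up] - 0.1) / 0.4
    r[dn] <- pk * (1 - (rel[dn] - 0.5) / 4.5)
    r
  }
}

# Sample an inhomogeneous point process on a grid by Bernoulli thinning.
sample_inhom <- function(grid, rate, dt) {
  p <- pmin(rate * dt, 1)
  grid[stats::runif(length(grid)) < p]
}

#' Generate planted calcium-event schedules for a neuron population
#'
#' Three classes: `peri_song` neurons draw events from an inhomogeneous
#' process ramping toward `peri_peak_time` before each phrase onset (plus a
#' low rate inside within-phrase gaps and a post-song burst/ramp-off);
#' `song` neurons emit at most one event per motif at a neuron-specific motif
#' phase plus Gaussian onset jitter, with per-motif participation
#' probability; `pan_song` neurons combine both processes.
#'
#' @param timeline a `synth_timeline`.
#' @param n_per_class named vector of neuron counts, e.g.
#'   `c(peri_song = 40, pan_song = 40, song = 40)`.
#' @param config `synth_config` (defaults to the timeline's).
#' @param seed integer seed; each neuron uses its own substream, so changing
#'   the population size does not perturb other neurons' events.
#' @return data.frame `neuron_id`, `class`, `onset_s` (ground-truth event
#'   onsets); per-neuron table attached as attribute `"neurons"`.
#' @export
gen_neuron_events <- function(timeline, n_per_class = c(peri_song = 40,
                                                        pan_song = 40,
                                                        song = 40),
                              config = timeline$config, seed = 1) {
  cfg <- config
  classes <- rep(names(n_per_class), n_per_class)
  dt <- 0.005
  grid <- seq(0, timeline$trial_length, by = dt)
  # population rate profile for peri-type activity
  peri_rate <- numeric(length(grid))
  for (i in seq_len(nrow(timeline$phrases))) {
    on <- timeline$phrases$onset_s[i]; off <- timeline$phrases$offset_s[i]
    peri_rate <- peri_rate + peri_rate_profile(grid - on, cfg, "pre")
    peri_rate <- peri_rate + peri_rate_profile(grid - off, cfg, "post")
  }
  # within-phrase silent gaps
  b <- timeline$bouts
  if (nrow(b) > 1L) {
    for (i in 2L:nrow(b)) {
      if (b$phrase_idx[i] == b$phrase_idx[i - 1L]) {
        # 0.1-s margins keep gap events clear of the bout boundaries (same
        # margin as the pre/post profiles use around phrase edges)
        sel <- grid >= b$offset_s[i - 1L] + 0.1 & grid < b$onset_s[i] - 0.1
        peri_rate[sel] <- cfg$gap_rate_frac * cfg$peri_peak_rate
      }
    }
  }
  motif_dur <- timeline$motifs$offset_s[1L] - timeline$motifs$onset_s[1L]

  rows <- list()
  neurons <- data.frame(neuron_id = seq_along(classes), class = classes)
  for (n in seq_along(classes)) {
    set.seed(substream_seed(seed, 100 + n))
    cls <- classes[n]
    ev <- numeric(0)
    if (cls %in% c("peri_song", "pan_song")) {
      ev <- c(ev, sample_inhom(grid, peri_rate, dt))
    }
    if (cls %in% c("song", "pan_song")) {
      phase <- stats::runif(1, 0.11, motif_dur - 0.15)
      for (m in seq_len(nrow(timeline$motifs))) {
        if (stats::runif(1) < cfg$motif_participation) {
          j <- stats::rnorm(1, 0, cfg$onset_jitter_sd)
          j <- max(min(j, 2.5 * cfg$onset_jitter_sd), -2.5 * cfg$onset_jitter_sd)
          ev <- c(ev, timeline$motifs$onset_s[m] + phase + j)
        }
      }
    }
    ev <- sort(ev)
    # enforce a minimum separation so transients remain resolvable
    if (length(ev) > 1L) ev <- ev[c(TRUE, diff(ev) > 0.2)]
    if (length(ev)) {
      rows[[length(rows) + 1L]] <- data.frame(neuron_id = n, class = cls,
                                              onset_s = ev)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(neuron_id = integer(0), class = character(0),
               onset_s = numeric(0))
  rownames(out) <- NULL
  attr(out, "neurons") <- neurons
  out
}

# Difference-of-exponentials calcium kernel, peak-normalized to 1.
calcium_kernel <- function(t, tau_rise, tau_decay) {
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  k[t < 0] <- 0
  tp <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  k / (exp(-tp / tau_decay) - exp(-tp / tau_rise))
}

#' Synthesize a fluorescence trace from planted events
#'
#' `raw = background_level + baseline_offset + drift + sum_i A_i k(t - t_i)
#' + noise`, with a difference-of-exponentials kernel (configured rise/decay
#' constants), a slow sinusoidal drift, and white Gaussian noise;
#' `background` is the constant `background_level`. Amplitudes are drawn in
#' units of the noise SD (truncated below at `amp_min`).
#'
#' @param event_times planted event onsets (s) for one neuron.
#' @param trial_length trace length (s).
#' @param config `synth_config`.
#' @param seed integer seed.
#' @param neuron_id identifier stored in the trace.
#' @return list: `trace` (a `fluor_trace`), `amplitudes`, `event_times`.
#' @export
gen_fluorescence <- function(event_times, trial_length,
                             config = synth_config(), seed = 1,
                             neuron_id = NA) {
  cfg <- config
  set.seed(substream_seed(seed, 200 + ifelse(is.na(neuron_id), 0, neuron_id)))
  ft <- seq(0, trial_length, by = 1 / cfg$fps)
  sig <- numeric(length(ft))
  amps <- numeric(0)
  if (length(event_times)) {
    amps <- pmax(stats::rnorm(length(event_times), cfg$amp_mean, cfg$amp_sd),
                 cfg$amp_min)
    for (i in seq_along(event_times)) {
      sig <- sig + amps[i] * calcium_kernel(ft - event_times[i],
                                            cfg$tau_rise, cfg$tau_decay)
    }
  }
  drift <- cfg$drift_amp * sin(2 * pi * ft / cfg$drift_period +
                                 stats::runif(1, 0, 2 * pi))
  noise <- stats::rnorm(length(ft), 0, cfg$noise_sd)
  raw <- cfg$background_level + cfg$baseline_offset + drift + sig + noise
  bg <- rep(cfg$background_level, length(ft))
  tr <- fluor_trace(raw, bg, ft, neuron_id = neuron_id)
  list(trace = tr, amplitudes = amps, event_times = event_times)
}

#' Render a movie from fluorescence traces
#'
#' Each neuron is a 2-D Gaussian footprint on a grid; pixel values are the
#' footprint-weighted trace plus a flat background and pixel noise. ROI
#' masks are the footprints above half maximum.
#'
#' @param traces list of `fluor_trace` objects (their `corrected` series are
#'   rendered).
#' @param dims spatial dimensions, default `c(40, 40)`.
#' @param footprint_sd Gaussian footprint SD in pixels, default 1.8.
#' @param background flat background level, default 2.
#' @param pixel_noise_sd per-pixel noise SD, default 0.02.
#' @param seed integer seed.
#' @return list `movie` (array rows x cols x frames), `roi_masks`.
#' @export
gen_movie <- function(traces, dims = c(40, 40), footprint_sd = 1.8,
                      background = 2, pixel_noise_sd = 0.02, seed = 1) {
  set.seed(substream_seed(seed, 300))
  n <- length(traces)
  nf <- length(traces[[1L]]$corrected)
  # centers on a jittered grid, away from borders
  k <- ceiling(sqrt(n))
  cx <- seq(8, dims[1L] - 8, length.out = k)
  cy <- seq(8, dims[2L] - 8, length.out = k)
  centers <- expand.grid(x = cx, y = cy)[seq_len(n), , drop = FALSE]
  movie <- array(background, dim = c(dims, nf))
  movie <- movie + array(stats::rnorm(prod(dims) * nf, 0, pixel_noise_sd),
                         dim = c(dims, nf))
  masks <- vector("list", n)
  grid_x <- matrix(seq_len(dims[1L]), dims[1L], dims[2L])
  grid_y <- matrix(seq_len(dims[2L]), dims[1L], dims[2L], byrow = TRUE)
  for (i in seq_len(n)) {
    fp <- exp(-((grid_x - centers$x[i])^2 + (grid_y - centers$y[i])^2) /
                (2 * footprint_sd^2))
    masks[[i]] <- fp > 0.5
    fp[fp < 0.05] <- 0
    tr <- traces[[i]]$corrected
    contrib <- outer(as.vector(fp), tr)
    movie <- movie + array(contrib, dim = c(dims, nf))
  }
  list(movie = movie, roi_masks = masks)
}

#' Generate a complete synthetic calcium-imaging dataset
#'
#' Timeline, planted events for a class-structured population, and one
#' fluorescence trace per neuron.
#'
#' @param n_per_class neuron counts per class.
#' @param config `synth_config`.
#' @param seed integer seed.
#' @return list `timeline`, `events` (ground truth), `neurons`, `traces`
#'   (list of `fluor_trace`).
#' @export
gen_calcium_dataset <- function(n_per_class = c(peri_song = 40,
                                                pan_song = 40, song = 40),
                                config = synth_config(), seed = 1) {
  tl <- gen_timeline(config, seed)
  ev <- gen_neuron_events(tl, n_per_class, config, seed)
  neurons <- attr(ev, "neurons")
  traces <- lapply(neurons$neuron_id, function(id) {
    gen_fluorescence(ev$onset_s[ev$neuron_id == id], tl$trial_length,
                     config, seed, neuron_id = id)$trace
  })
  list(timeline = tl, events = ev, neurons = neurons, traces = traces)
}

# Multiunit rate profile on the trial clock: baseline, a ramp beginning at
# mu_step_time before each phrase onset reaching the song rate at
# mu_ramp_end, the song rate through the phrase, and an exponential return
# to baseline after phrase offset.
mu_rate_profile <- function(t, timeline, cfg) {
  r <- rep(cfg$mu_baseline_rate, length(t))
  for (i in seq_len(nrow(timeline$phrases))) {
    on <- timeline$phrases$onset_s[i]; off <- timeline$phrases$offset_s[i]
    rel <- t - on
    ramp <- rel >= cfg$mu_step_time & rel < cfg$mu_ramp_end
    r[ramp] <- cfg$mu_baseline_rate +
      (cfg$mu_song_rate - cfg$mu_baseline_rate) *
      (rel[ramp] - cfg$mu_step_time) / (cfg$mu_ramp_end - cfg$mu_step_time)
    r[rel >= cfg$mu_ramp_end & t < off] <- cfg$mu_song_rate
    post <- t >= off & t < off + 4 * cfg$mu_post_decay
    r[post] <- cfg$mu_baseline_rate +
      (cfg$mu_song_rate - cfg$mu_baseline_rate) *
      exp(-(t[post] - off) / cfg$mu_post_decay)
  }
  r
}

#' Generate multiunit spike times (and optional voltage)
#'
#' Inhomogeneous Poisson spikes: baseline rate, a pre-song ramp beginning at
#' `mu_step_time`, elevated song rate, exponential post-song return. With
#' `voltage = TRUE` a 25 kHz voltage trace is synthesized by embedding
#' biphasic spike waveforms (negative peak at `spike_amp` noise SDs) in
#' white Gaussian noise.
#'
#' @param timeline a `synth_timeline`.
#' @param config `synth_config`.
#' @param seed integer seed.
#' @param voltage synthesize voltage as well? Default FALSE.
#' @param fs voltage sampling rate (Hz), default 25000.
#' @param spike_amp negative spike peak in noise SDs, default 8.
#' @return list `spike_times`, `rate_profile` (function of t); when
#'   `voltage` is set, also `voltage`, `fs`.
#' @export
gen_mu_spiketrain <- function(timeline, config = timeline$config, seed = 1,
                              voltage = FALSE, fs = 25000, spike_amp = 8) {
  cfg <- config
  set.seed(substream_seed(seed, 400))
  dt <- 0.001
  grid <- seq(0, timeline$trial_length, by = dt)
  rate <- mu_rate_profile(grid, timeline, cfg)
  spikes <- sample_inhom(grid, rate, dt)
  out <- list(spike_times = spikes,
              rate_profile = function(t) mu_rate_profile(t, timeline, cfg))
  if (voltage) {
    n <- ceiling(timeline$trial_length * fs)
    v <- stats::rnorm(n, 0, 1)
    tmpl_t <- seq(-0.0006, 0.0012, by = 1 / fs)
    tmpl <- -spike_amp * exp(-(tmpl_t)^2 / (2 * 0.00012^2)) +
      0.4 * spike_amp * exp(-(tmpl_t - 0.0005)^2 / (2 * 0.0002^2))
    for (s in spikes) {
      i0 <- round(s * fs) + 1L
      idx <- i0 + seq_along(tmpl_t) - 1L + round(tmpl_t[1L] * fs)
      ok <- idx >= 1L & idx <= n
      v[idx[ok]] <- v[idx[ok]] + tmpl[ok]
    }
    out$voltage <- v
    out$fs <- fs
  }
  out
}

#' Generate single-unit spike trains with epoch-dependent regularity
#'
#' Gamma-renewal ISIs within each epoch window: high shape gives regular
#' (low-CV) spontaneous firing, low shape gives irregular (high-CV) firing
#' in pre-song, song and post-song epochs.
#'
#' @param windows data.frame `epoch`, `start_s`, `end_s` (e.g. from
#'   [epoch_windows()]).
#' @param config `synth_config` (fields `su_rates`, `su_shapes`).
#' @param seed integer seed.
#' @return numeric spike times (s), sorted.
#' @export
gen_su_spiketrain <- function(windows, config = synth_config(), seed = 1) {
  cfg <- config
  set.seed(substream_seed(seed, 500))
  spikes <- numeric(0)
  for (i in seq_len(nrow(windows))) {
    e <- windows$epoch[i]
    rate <- cfg$su_rates[[e]]; shape <- cfg$su_shapes[[e]]
    t0 <- windows$start_s[i]; t1 <- windows$end_s[i]
    n_exp <- ceiling((t1 - t0) * rate * 3 + 20)
    isis <- stats::rgamma(n_exp, shape = shape, rate = shape * rate)
    st <- t0 + cumsum(isis)
    spikes <- c(spikes, st[st < t1])
  }
  sort(spikes)
}

# One respiratory cycle waveform: subambient (inspiratory) half-sine, then
# the expiratory phase as a supra-ambient half-sine followed by an
# end-expiratory pause at ambient (so the quiet-window median estimates the
# true ambient level).
cycle_wave <- function(n_insp, n_exp, amp, pause_frac) {
  n_pause <- round(n_exp * pause_frac)
  n_sine <- n_exp - n_pause
  c(-amp * sin(pi * seq_len(n_insp) / (n_insp + 1)),
    amp * sin(pi * seq_len(n_sine) / (n_sine + 1)),
    numeric(n_pause))
}

#' Generate an air-sac pressure waveform from a timeline
#'
#' Quiet-breathing cycles (duration ~ `quiet_cycle`, expiratory duty
#' `quiet_duty`) outside song, switching to short high-amplitude song cycles
#' (~`song_cycle`, `song_duty`) from the inspiration preceding each phrase's
#' first introductory note until the expiration ending after the phrase's
#' last syllable. Ground truth records every cycle with its state and the
#' per-phrase song onset/offset markers.
#'
#' @param timeline a `synth_timeline`.
#' @param config `synth_config`.
#' @param seed integer seed.
#' @return list: `pressure` (samples), `fs`, `cycles` (truth table with
#'   `start_s`, `duration_s`, `duty_pct`, `state`), `markers` (per-phrase
#'   `onset_s`, `offset_s`).
#' @export
gen_pressure <- function(timeline, config = timeline$config, seed = 1) {
  cfg <- config
  set.seed(substream_seed(seed, 600))
  fs <- cfg$resp_fs
  rtrunc <- function(m, s, lo, hi) {
    repeat {
      x <- stats::rnorm(1, m, s)
      if (x >= lo && x <= hi) return(x)
    }
  }
  draw_quiet <- function() rtrunc(cfg$quiet_cycle[["mean"]],
                                  cfg$quiet_cycle[["sd"]], 0.2, 0.6)
  draw_song <- function() rtrunc(cfg$song_cycle[["mean"]],
                                 cfg$song_cycle[["sd"]], 0.1, 0.3)

  intro_first <- vapply(seq_len(nrow(timeline$phrases)), function(p) {
    s <- timeline$syllables
    in_p <- s$onset_s >= timeline$phrases$onset_s[p] &
      s$onset_s < timeline$phrases$offset_s[p]
    min(s$onset_s[in_p])
  }, numeric(1))
  phrase_off <- timeline$phrases$offset_s

  cyc <- list()
  t <- 0
  markers <- list()
  for (p in seq_len(nrow(timeline$phrases))) {
    first_note <- intro_first[p]
    d_song1 <- draw_song()
    # quiet cycles until the switch point; the first song cycle begins
    # 0.6 cycle before the first note, so the note falls inside its
    # expiratory phase and cycle boundaries stay clear of the note onset
    switch_at <- first_note - 0.6 * d_song1
    while (TRUE) {
      d <- draw_quiet()
      if (t + d > switch_at) break
      cyc[[length(cyc) + 1L]] <- data.frame(start_s = t, duration_s = d,
                                            duty_pct = cfg$quiet_duty,
                                            amp = cfg$quiet_amp,
                                            state = "quiet")
      t <- t + d
    }
    remaining <- switch_at - t
    if (remaining >= 0.2) {
      cyc[[length(cyc) + 1L]] <- data.frame(start_s = t, duration_s = remaining,
                                            duty_pct = cfg$quiet_duty,
                                            amp = cfg$quiet_amp,
                                            state = "quiet")
      t <- t + remaining
    } else if (remaining > 0 && length(cyc)) {
      cyc[[length(cyc)]]$duration_s <- cyc[[length(cyc)]]$duration_s + remaining
      t <- t + remaining
    }
    onset_marker <- t
    # song cycles until the expiration ending covers the phrase offset
    d <- d_song1
    repeat {
      cyc[[length(cyc) + 1L]] <- data.frame(start_s = t, duration_s = d,
                                            duty_pct = cfg$song_duty,
                                            amp = cfg$song_amp,
                                            state = "song")
      t <- t + d
      if (t > phrase_off[p]) break
      d <- draw_song()
    }
    markers[[p]] <- data.frame(phrase_idx = p, onset_s = onset_marker,
                               offset_s = t)
  }
  while (t < timeline$trial_length) {
    d <- draw_quiet()
    cyc[[length(cyc) + 1L]] <- data.frame(start_s = t, duration_s = d,
                                          duty_pct = cfg$quiet_duty,
                                          amp = cfg$quiet_amp, state = "quiet")
    t <- t + d
  }
  cycles <- do.call(rbind, cyc)
  rownames(cycles) <- NULL

  n <- ceiling(t * fs) + 1L
  pressure <- numeric(n)
  for (i in seq_len(nrow(cycles))) {
    i0 <- round(cycles$start_s[i] * fs) + 1L
    i1 <- round((cycles$start_s[i] + cycles$duration_s[i]) * fs)
    len <- i1 - i0 + 1L
    if (len < 4L || i1 > n) next
    n_exp <- round(len * cycles$duty_pct[i] / 100)
    n_insp <- len - n_exp
    w <- cycle_wave(n_insp, n_exp, cycles$amp[i], cfg$resp_pause_frac)
    pressure[i0:(i0 + length(w) - 1L)] <- w
  }
  pressure <- pressure + stats::rnorm(n, 0, cfg$resp_noise_sd)
  list(pressure = pressure, fs = fs, cycles = cycles,
       markers = do.call(rbind, markers))
}
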