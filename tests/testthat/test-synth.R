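test_that("identical config and seed reproduce identical outputs", {
  cfg <- synth_config()
  a <- gen_timeline(cfg, seed = 9); b <- gen_timeline(cfg, seed = 9)
  expect_identical(a$syllables, b$syllables)
  ea <- gen_neuron_events(a, c(peri_song = 3, pan_song = 3, song = 3),
                          cfg, seed = 9)
  eb <- gen_neuron_events(b, c(peri_song = 3, pan_song = 3, song = 3),
                          cfg, seed = 9)
  expect_identical(ea, eb)
  fa <- gen_fluorescence(c(3, 7), 12, cfg, seed = 9, neuron_id = 1)
  fb <- gen_fluorescence(c(3, 7), 12, cfg, seed = 9, neuron_id = 1)
  expect_identical(fa$trace$raw, fb$trace$raw)
  pa <- gen_pressure(a, cfg, seed = 9); pb <- gen_pressure(b, cfg, seed = 9)
  expect_identical(pa$pressure, pb$pressure)
})

test_that("adding neurons does not perturb existing neurons' events", {
  tl <- gen_timeline(seed = 10)
  small <- gen_neuron_events(tl, c(peri_song = 3, pan_song = 0, song = 0),
                             seed = 10)
  big <- gen_neuron_events(tl, c(peri_song = 5, pan_song = 0, song = 0),
                           seed = 10)
  for (id in 1:3) {
    expect_identical(small$onset_s[small$neuron_id == id],
                     big$onset_s[big$neuron_id == id])
  }
})

test_that("gap configuration controls phrase structure by construction", {
  # gaps of 1 s only: each phrase is a single group
  cfg1 <- synth_config(bout_gap_range = c(1, 1), n_phrases = 1,
                       bouts_per_phrase = 3)
  tl1 <- gen_timeline(cfg1, seed = 11)
  expect_equal(nrow(assemble_phrases(tl1$syllables)), 1L)
  # gaps of 3 s: each bout becomes its own phrase
  cfg3 <- synth_config(bout_gap_range = c(3, 3), n_phrases = 1,
                       bouts_per_phrase = 3)
  tl3 <- gen_timeline(cfg3, seed = 11)
  ph3 <- assemble_phrases(tl3$syllables)
  expect_equal(nrow(ph3), nrow(tl3$bouts))
})

test_that("song-locked events honor participation and jitter settings", {
  cfg <- synth_config(motif_participation = 1, onset_jitter_sd = 0,
                      n_phrases = 4)
  tl <- gen_timeline(cfg, seed = 12)
  ev <- gen_neuron_events(tl, c(peri_song = 0, pan_song = 0, song = 1),
                          cfg, seed = 12)
  # with full participation and zero jitter, the phase offsets are constant
  rel <- vapply(ev$onset_s, function(o) {
    m <- which(tl$motifs$onset_s <= o & tl$motifs$offset_s > o)
    o - tl$motifs$onset_s[m[1]]
  }, numeric(1))
  expect_lt(diff(range(rel)), 1e-9)
  expect_equal(nrow(ev), nrow(tl$motifs))

  # zero peri ramp silences peri-song neurons
  cfg0 <- synth_config(peri_peak_rate = 0, gap_rate_frac = 0)
  tl0 <- gen_timeline(cfg0, seed = 12)
  ev0 <- gen_neuron_events(tl0, c(peri_song = 5, pan_song = 0, song = 0),
                           cfg0, seed = 12)
  expect_equal(nrow(ev0), 0L)
})

test_that("empirical per-motif participation sits inside its binomial CI", {
  cfg <- synth_config(n_phrases = 8, bouts_per_phrase = 3,
                      motifs_per_bout = 3)
  n_hit <- 0L; n_motif <- 0L
  for (s in 1:8) {
    tl <- gen_timeline(cfg, seed = 40 + s)
    ev <- gen_neuron_events(tl, c(peri_song = 0, pan_song = 0, song = 1),
                            cfg, seed = 40 + s)
    n_motif <- n_motif + nrow(tl$motifs)
    n_hit <- n_hit + nrow(ev)
  }
  ci <- stats::binom.test(n_hit, n_motif)$conf.int
  expect_true(0.7 >= ci[1] && 0.7 <= ci[2])
})

test_that("the calcium kernel peaks near the configured rise time", {
  expect_lt(abs(kernel_peak_time(synth_config()) - 0.112), 0.002)
  # round trip: a noise-free event is recovered with that rise
  gf <- gen_fluorescence(5, 12, synth_config(noise_sd = 0, drift_amp = 0),
                         seed = 1, neuron_id = 1)
  ev <- process_trace(gf$trace)$events
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$rise_s - 0.112), 1 / 30 + 1e-9)
  # degenerate config: no events, no noise, no drift -> flat trace
  gf0 <- gen_fluorescence(numeric(0), 12,
                          synth_config(noise_sd = 0, drift_amp = 0),
                          seed = 1, neuron_id = 1)
  expect_equal(diff(range(gf0$trace$corrected)), 0)
})

test_that("gamma-renewal units reach the configured regularity limits", {
  w <- data.frame(epoch = "spontaneous", start_s = 0, end_s = 60)
  # near-regular limit: high shape gives small CV
  cfg_hi <- synth_config(su_shapes = c(spontaneous = 400, pre_song = 1,
                                       song = 1, post_song = 1))
  st <- gen_su_spiketrain(w, cfg_hi, seed = 13)
  expect_lt(epoch_isi_cv(st, w)$cv, 0.1)
  # Poisson limit: shape 1 gives CV near 1 with ~500 ISIs
  cfg_p <- synth_config(su_rates = c(spontaneous = 10, pre_song = 10,
                                     song = 10, post_song = 10),
                        su_shapes = c(spontaneous = 1, pre_song = 1,
                                      song = 1, post_song = 1))
  st2 <- gen_su_spiketrain(w, cfg_p, seed = 14)
  cv <- epoch_isi_cv(st2, w)$cv
  expect_lt(abs(cv - 1), 0.1)
})

test_that("generated distributions match their configured laws", {
  # quiet-cycle durations: K-S against the configured normal (the 0.2-0.6 s
  # truncation sits 4.5 SD out, so the plain normal is the law here)
  durs <- unlist(lapply(1:8, function(s) {
    tl <- gen_timeline(synth_config(n_phrases = 1), seed = s)
    pw <- gen_pressure(tl, seed = s)
    pw$cycles$duration_s[pw$cycles$state == "quiet"]
  }))
  expect_gt(length(durs), 200)
  expect_gt(stats::ks.test(durs, "pnorm", 0.38, 0.04)$p.value, 0.01)

  # song-event onset jitter: centered spread matches the configured SD
  cfg <- synth_config(n_phrases = 10, motif_participation = 1)
  tl <- gen_timeline(cfg, seed = 16)
  jit <- unlist(lapply(1:30, function(n) {
    ev <- gen_neuron_events(tl, c(peri_song = 0, pan_song = 0, song = 1),
                            cfg, seed = 600 + n)
    rel <- vapply(ev$onset_s, function(o) {
      m <- which(tl$motifs$onset_s <= o)
      o - tl$motifs$onset_s[max(m)]
    }, numeric(1))
    rel - mean(rel)
  }))
  sd_trunc <- 0.055 * sqrt(1 - 2 * 2.5 * stats::dnorm(2.5) /
                             (2 * stats::pnorm(2.5) - 1))
  expect_lt(abs(stats::sd(jit) - sd_trunc), 0.006)
  expect_lt(abs(mean(jit)), 0.004)
})
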