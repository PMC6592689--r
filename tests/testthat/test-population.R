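test_that("phrase index matches its defining ratio and bounds", {
  expect_equal(phrase_index(5, 0), 1)
  expect_equal(phrase_index(0, 5), -1)
  expect_equal(phrase_index(3, 1), 0.5)
  expect_true(is.na(phrase_index(1, 0)))  # fewer than two events: excluded
  expect_error(phrase_index(-1, 2), ">= 0")
})

test_that("phrase index is antisymmetric in its two counts", {
  set.seed(3)
  for (i in 1:20) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    if (a + b < 2) next
    expect_equal(phrase_index(a, b), -phrase_index(b, a))
  }
})

test_that("neuron classes follow the index extremes and the band helper", {
  expect_equal(classify_neuron(c(-1, 1, 0.07, NA)),
               c("peri_song", "song", "pan_song", "excluded"))
  expect_true(in_index_band(0.07))
  expect_true(in_index_band(-0.18))
  expect_false(in_index_band(0.25))
  expect_false(in_index_band(NA))
})

test_that("event labeling uses the onset frame, peri_gap counts as peri", {
  s <- syl_tab(c(10, 11, 12.5), c(10.5, 11.5, 13), rep("syl_a", 3))
  mask <- build_epoch_mask(s, seq(0, 30, by = 1 / 30))
  ev <- data.frame(neuron_id = 1,
                   onset_s = c(8.7, 9.83, 11.7, 14.0, 29.5),
                   peak_s = c(8.8, 10.1, 11.8, 14.1, 29.6),
                   rise_s = 0.1, amplitude = 5, peak_over_sigma = 5)
  lab <- label_events(ev, mask)
  # onset 170 ms before song with rise extending past onset: peri governs
  expect_equal(lab$epoch[2], "peri_pre")
  expect_equal(lab$epoch, c("peri_pre", "peri_pre", "peri_gap", "peri_post",
                            "baseline"))
  expect_equal(sum(lab$is_peri), 4L)
  expect_equal(sum(lab$is_song), 0L)
  # events outside coverage warn and become other
  ev2 <- ev; ev2$onset_s[1] <- 45
  expect_warning(lab2 <- label_events(ev2, mask), "outside")
  expect_equal(lab2$epoch[1], "other")
})

test_that("neuron summaries pool counts and classify", {
  lab <- data.frame(neuron_id = c(1, 1, 1, 2, 2, 3),
                    is_song = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE),
                    is_peri = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE))
  ns <- neuron_summary(lab, neuron_ids = 1:4)
  expect_equal(ns$phrase_index, c(1 / 3, -1, NA, NA))
  expect_equal(ns$neuron_class, c("pan_song", "peri_song", "excluded",
                                  "excluded"))
})

test_that("unsmoothed rate traces conserve event counts exactly", {
  set.seed(5)
  for (r in 1:5) {
    n <- sample(5:40, 1)
    ev <- stats::runif(n, -4.9, 4.9)
    tr <- event_rate_trace(ev, alignments = 0)
    expect_equal(sum(tr$rate_raw) * attr(tr, "bin"), n)
    # smoothing changes the integral by < 5% (boundary truncation only)
    expect_lt(abs(sum(tr$rate_smooth) - sum(tr$rate_raw)) /
                max(sum(tr$rate_raw), 1), 0.05)
  }
  # 10 events uniform over one second: 10 events/s unsmoothed in that span
  ev <- seq(1.05, 1.95, by = 0.1)
  tr <- event_rate_trace(ev, alignments = 0)
  expect_equal(tr$rate_raw[tr$rel_time > 1 & tr$rel_time < 2], rep(10, 10))
})

test_that("rate smoothing never crosses the alignment boundary", {
  # all mass after 0: smoothed pre-onset trace must stay zero
  ev <- stats::runif(50, 0.05, 2)
  tr <- event_rate_trace(ev, alignments = 0)
  expect_true(all(tr$rate_smooth[tr$rel_time < 0] == 0))
  # and vice versa
  ev2 <- stats::runif(50, -2, -0.05)
  tr2 <- event_rate_trace(ev2, alignments = 0)
  expect_true(all(tr2$rate_smooth[tr2$rel_time > 0] == 0))
})

test_that("empty alignment sets give empty traces", {
  tr <- event_rate_trace(c(1, 2), alignments = numeric(0))
  expect_equal(attr(tr, "n_trials"), 0L)
  expect_true(all(tr$rate_raw == 0))
})

test_that("peri-event histograms match brute-force binning in both modes", {
  ev <- data.frame(neuron_id = c(1, 1, 2, 3),
                   onset_s = c(0.35, 0.25, 0.31, 2.2))
  h_ev <- perievent_histogram(ev, alignments = 0, mode = "events")
  h_nr <- perievent_histogram(ev, alignments = 0, mode = "neurons")
  b <- abs(h_ev$rel_time - 0.3) < 1e-6  # bin [0.2, 0.4)
  expect_equal(h_ev$count[b], 3)
  expect_equal(h_nr$count[b], 2)  # neuron 1 counted once in the bin
  expect_equal(sum(h_ev$count), 4)
  # empty input: all-zero histogram
  h0 <- perievent_histogram(ev[0, ], alignments = 0)
  expect_true(all(h0$count == 0))
  # brute-force check over random data
  set.seed(9)
  ev2 <- data.frame(neuron_id = sample(1:5, 60, TRUE),
                    onset_s = stats::runif(60, -5, 5))
  h2 <- perievent_histogram(ev2, alignments = 0, mode = "events")
  brute <- table(cut(ev2$onset_s, seq(-5, 5, by = 0.2), right = FALSE))
  expect_equal(h2$count, as.numeric(brute))
})

test_that("onset prediction finds step onsets and stays undefined when flat", {
  mk_trace <- function(rate) {
    tr <- data.frame(rel_time = seq(-4.95, 4.95, by = 0.1),
                     rate_raw = rate, rate_smooth = rate)
    attr(tr, "bin") <- 0.1
    class(tr) <- c("rate_trace", "data.frame")
    tr
  }
  rel <- seq(-4.95, 4.95, by = 0.1)
  step <- ifelse(rel >= -2, 5, 0)
  op <- onset_prediction(mk_trace(step))
  expect_lt(abs(op$crossing_time - (-2)), 0.1 + 1e-9)
  # constant rate: never crosses
  expect_true(is.na(onset_prediction(mk_trace(rep(3, length(rel))))$crossing_time))
  # sd floor applies on a silent baseline
  expect_equal(onset_prediction(mk_trace(step))$baseline_sd, 0.05)
})

test_that("event SNR is the per-neuron mean peak over baseline ratio", {
  out <- event_snr(c(50), neuron_id = c(1), baseline_mean = c(`1` = 5))
  expect_equal(out$snr, 10)
  out2 <- event_snr(c(40, 60), c(1, 1), c(`1` = 10))
  expect_equal(out2$snr, 5)
  expect_error(event_snr(c(1), c(1), c(`1` = 0)), "baseline")
})

test_that("matched planted amplitudes give no spurious class SNR difference", {
  set.seed(17)
  snr_a <- snr_b <- numeric(40)
  for (i in 1:40) {
    pk_a <- stats::rnorm(6, 50, 8); pk_b <- stats::rnorm(6, 50, 8)
    snr_a[i] <- mean(pk_a) / 5
    snr_b[i] <- mean(pk_b) / 5
  }
  expect_gt(stats::t.test(snr_a, snr_b)$p.value, 0.05)
})

test_that("interval fluorescence normalizes to the song mean", {
  s <- syl_tab(c(15, 16.5), c(16, 17.5), rep("syl_a", 2))
  times <- seq(0, 40, by = 1 / 30)
  mask <- build_epoch_mask(s, times)
  # constant trace: every interval ratio is 1
  tr <- fluor_trace(rep(4, length(times)), frame_times = times)
  out <- interval_fluorescence(tr, mask)
  expect_equal(unname(out), rep(1, 4))
  # song frames 10, pre frames 2.69: pre ratio 0.269
  y <- rep(0, length(times))
  y[mask$label == "song"] <- 10
  y[mask$label == "peri_pre"] <- 2.69
  tr2 <- fluor_trace(y, frame_times = times)
  out2 <- interval_fluorescence(tr2, mask)
  expect_equal(unname(out2["peri_pre"]), 0.269)
  expect_equal(unname(out2["song"]), 1)
  # no song frames: undefined
  mask0 <- build_epoch_mask(syl_tab(100, 101, "syl_a")[0, ], times)
  expect_error(interval_fluorescence(tr2, mask0), "song")
})

test_that("active fractions count distinct neurons per phrase", {
  lab <- data.frame(neuron_id = c(1, 1, 2, 3, 4, 5, 6, 2),
                    is_song = TRUE,
                    is_peri = FALSE,
                    phrase_idx = c(1, 1, 1, 1, 1, 1, 1, 2))
  af <- active_fraction(lab, n_neurons = 10, epoch = "song")
  expect_equal(af$pct_active[af$phrase_idx == 1], 60)  # 6 distinct of 10
  expect_equal(af$pct_active[af$phrase_idx == 2], 10)
  # no events: 0 percent
  af0 <- active_fraction(lab[0, ], n_neurons = 10, epoch = "song",
                         phrase_idx = 1)
  expect_equal(af0$pct_active, 0)
  expect_error(active_fraction(lab, n_neurons = 0), "neuron")
})

test_that("planted per-phrase activity probabilities are recovered", {
  set.seed(23)
  p_act <- 0.6; n_neurons <- 50; n_phrases <- 12
  rows <- list()
  for (ph in seq_len(n_phrases)) {
    act <- which(stats::runif(n_neurons) < p_act)
    if (length(act)) {
      rows[[ph]] <- data.frame(neuron_id = act, is_song = TRUE,
                               is_peri = FALSE, phrase_idx = ph)
    }
  }
  af <- active_fraction(do.call(rbind, rows), n_neurons, epoch = "song")
  ci <- stats::binom.test(round(mean(af$pct_active) / 100 * n_neurons),
                          n_neurons)$conf.int
  expect_true(p_act >= ci[1] && p_act <= ci[2])
})
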