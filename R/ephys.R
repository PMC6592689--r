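# Extracellular electrophysiology: multiunit spike detection, song-aligned
# normalized rate traces with onset/offset latencies, and single-unit
# inter-spike-interval variability across behavioral epochs.

#' Zero-phase Butterworth bandpass for spike-band voltage
#'
#' 4th-order Butterworth applied forward-backward (`filtfilt`), default band
#' 0.3-5 kHz.
#'
#' @param voltage sampled voltage.
#' @param fs sampling rate (Hz).
#' @param band passband (Hz), default `c(300, 5000)`.
#' @return filtered signal.
#' @export
bandpass_voltage <- function(voltage, fs, band = c(300, 5000)) {
  ny <- fs / 2
  stopifnot(band[1L] > 0, band[2L] < ny)
  bf <- signal::butter(4, band / ny, type = "pass")
  signal::filtfilt(bf, voltage)
}

#' Detect multiunit spikes by amplitude threshold
#'
#' Negative peaks of the (band-passed) voltage exceeding `k` SDs of
#' spontaneous activity are multiunit spikes. `spont_sd` is the SD of the
#' filtered signal over the spontaneous segments (which must lie far from
#' singing). Candidate peaks are local minima below `-k * spont_sd`; a
#' refractory lockout keeps only the most negative peak within `lockout`
#' seconds.
#'
#' @param voltage voltage trace (filtered if `prefiltered`, raw otherwise).
#' @param fs sampling rate (Hz).
#' @param spont_segments data.frame with `start_s`, `end_s` of spontaneous
#'   segments.
#' @param k threshold in spontaneous SDs, default 4.
#' @param lockout refractory lockout (s), default 0.001.
#' @param prefiltered set TRUE when `voltage` is already band-passed.
#' @param band passband for filtering (Hz).
#' @return list with `spike_times` (s, strictly increasing), `spont_sd`,
#'   `threshold`.
#' @export
detect_mu_spikes <- function(voltage, fs, spont_segments, k = 4,
                             lockout = 0.001, prefiltered = FALSE,
                             band = c(300, 5000)) {
  if (nrow(spont_segments) == 0L) {
    stop("no spontaneous segment: channel rejected")
  }
  x <- if (prefiltered) voltage else bandpass_voltage(voltage, fs, band)
  t <- (seq_along(x) - 1) / fs
  spont <- in_any_interval(t, spont_segments$start_s, spont_segments$end_s)
  if (!any(spont)) stop("spontaneous segments outside recording")
  sdv <- stats::sd(x[spont])
  thr <- -k * sdv
  n <- length(x)
  cand <- which(x < thr)
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] <= x[cand - 1L] & x[cand] <= x[cand + 1L]]
  if (length(cand) == 0L) {
    return(list(spike_times = numeric(0), spont_sd = sdv, threshold = thr))
  }
  # lockout: accept most negative first, drop candidates within lockout
  ord <- cand[order(x[cand])]
  lock <- round(lockout * fs)
  accepted <- logical(n)
  taken <- rep(FALSE, n)
  for (i in ord) {
    lo <- max(1L, i - lock); hi <- min(n, i + lock)
    if (!any(taken[lo:hi])) {
      accepted[i] <- TRUE
      taken[lo:hi] <- TRUE
    }
  }
  list(spike_times = t[which(accepted)], spont_sd = sdv, threshold = thr)
}

#' Alignment-relative averaged spike rate
#'
#' Per-rendition spike counts in `bin`-second bins over \[-range, +range\]
#' around each alignment, converted to spikes/s, averaged across renditions,
#' then smoothed with a centered moving average of `smooth` seconds
#' (shrinking at the trace edges).
#'
#' @param spike_times spike times (s).
#' @param alignments song onset (or offset) times (s).
#' @param bin bin width (s), default 0.01.
#' @param smooth smoothing window (s), default 0.5.
#' @param range half-range (s), default 5.
#' @return data.frame `rel_time`, `rate_raw`, `rate_smooth`; `n_renditions`
#'   attribute.
#' @export
aligned_rate <- function(spike_times, alignments, bin = 0.01, smooth = 0.5,
                         range = 5) {
  stopifnot(length(alignments) >= 1L)
  edges <- seq(-range, range, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  counts <- vapply(alignments, function(a) {
    rel <- spike_times - a
    rel <- rel[rel >= -range & rel < range]
    tabulate(findInterval(rel, edges), nbins = length(centers))
  }, numeric(length(centers)))
  counts <- matrix(counts, nrow = length(centers))
  rate_raw <- rowMeans(counts) / bin
  rate_smooth <- moving_average(rate_raw, round(smooth / bin))
  out <- data.frame(rel_time = centers, rate_raw = rate_raw,
                    rate_smooth = rate_smooth)
  attr(out, "n_renditions") <- length(alignments)
  attr(out, "bin") <- bin
  out
}

#' Normalize a smoothed rate to baseline = 0, song = 1
#'
#' Affine rescaling `(rate - baseline_mean) / (song_mean - baseline_mean)`.
#'
#' @param rate_smooth smoothed rate (spikes/s).
#' @param baseline_mean,song_mean mean rates during baseline and singing.
#' @return dimensionless normalized rate.
#' @export
normalize_rate <- function(rate_smooth, baseline_mean, song_mean) {
  if (song_mean == baseline_mean) {
    stop("song and baseline rates equal: normalization undefined")
  }
  (rate_smooth - baseline_mean) / (song_mean - baseline_mean)
}

#' Onset and offset latency of song-related rate changes
#'
#' Onset latency (from an onset-aligned trace): the earliest pre-song time at
#' which the smoothed rate crosses `spont_mean + k * spont_sd` and stays
#' above threshold until song onset. Offset latency (offset-aligned trace):
#' the last post-song time up to which the rate stays above threshold
#' continuously from song offset. `NA` when never crossed.
#'
#' @param rate data.frame with `rel_time` and `rate_smooth` (from
#'   [aligned_rate()]).
#' @param spont_mean,spont_sd spontaneous rate statistics (from the smoothed
#'   trace over spontaneous segments).
#' @param k threshold in spontaneous SDs, default 2.
#' @param side `"onset"` or `"offset"`.
#' @return latency (s): negative before song onset for `"onset"`, positive
#'   after song offset for `"offset"`; `NA` if never crossed.
#' @export
rate_onset_offset <- function(rate, spont_mean, spont_sd, k = 2,
                              side = c("onset", "offset")) {
  side <- match.arg(side)
  thr <- spont_mean + k * spont_sd
  above <- rate$rate_smooth > thr
  if (side == "onset") {
    pre <- which(rate$rel_time < 0)
    if (length(pre) == 0L || !above[max(pre)]) return(NA_real_)
    # walk back from song onset while continuously above threshold
    i <- max(pre)
    while (i > 1L && above[i - 1L]) i <- i - 1L
    rate$rel_time[i]
  } else {
    post <- which(rate$rel_time >= 0)
    if (length(post) == 0L || !above[min(post)]) return(NA_real_)
    i <- min(post)
    while (i < nrow(rate) && above[i + 1L]) i <- i + 1L
    rate$rel_time[i]
  }
}

#' Spontaneous spike-rate statistics from the smoothed rate trace
#'
#' Bins spikes inside the spontaneous segments (10-ms default), smooths with
#' the same moving-average window used for song-aligned traces, and returns
#' the mean and SD of the smoothed spontaneous rate — the statistics behind
#' the mean + 2 SD onset/offset threshold.
#'
#' When the threshold is applied to a trace averaged over `n_average` song
#' renditions, the spontaneous SD is divided by `sqrt(n_average)` so both
#' sides of the comparison live on the same averaging scale.
#'
#' @param spike_times spike times (s).
#' @param spont_segments data.frame `start_s`, `end_s`.
#' @param bin bin width (s), default 0.01.
#' @param smooth smoothing window (s), default 0.5.
#' @param n_average number of renditions averaged in the trace the threshold
#'   will be applied to, default 1.
#' @return list `mean`, `sd` (spikes/s).
#' @export
spont_rate_stats <- function(spike_times, spont_segments, bin = 0.01,
                             smooth = 0.5, n_average = 1) {
  vals <- numeric(0)
  for (i in seq_len(nrow(spont_segments))) {
    a <- spont_segments$start_s[i]; b <- spont_segments$end_s[i]
    if (b - a < smooth) next
    edges <- seq(a, b, by = bin)
    if (length(edges) < 2L) next
    cnt <- tabulate(findInterval(
      spike_times[spike_times >= a & spike_times < edges[length(edges)]],
      edges), nbins = length(edges) - 1L)
    vals <- c(vals, moving_average(cnt / bin, round(smooth / bin)))
  }
  if (length(vals) == 0L) stop("no usable spontaneous segment")
  list(mean = mean(vals), sd = stats::sd(vals) / sqrt(n_average))
}

#' Epoch windows for single-unit analysis around song bouts
#'
#' Builds the four analysis windows per bout: `spontaneous` (at least
#' `spont_gap` seconds from any bout), `pre_song` (2.5 to 0.5 s before the
#' first vocal element), `song` (bout onset to offset), `post_song` (0.5 to
#' 2.5 s after the last syllable).
#'
#' @param bouts data.frame with `onset_s`, `offset_s` per bout (or phrase).
#' @param trial_end recording end (s).
#' @param pre_window,post_window epoch offsets (s), defaults `c(2.5, 0.5)`
#'   and `c(0.5, 2.5)`.
#' @param spont_gap spontaneous distance from bouts (s), default 10.
#' @param trial_start recording start (s), default 0.
#' @return data.frame `epoch`, `start_s`, `end_s`.
#' @export
epoch_windows <- function(bouts, trial_end, pre_window = c(2.5, 0.5),
                          post_window = c(0.5, 2.5), spont_gap = 10,
                          trial_start = 0) {
  win <- list()
  for (i in seq_len(nrow(bouts))) {
    on <- bouts$onset_s[i]; off <- bouts$offset_s[i]
    win[[length(win) + 1L]] <- data.frame(
      epoch = c("pre_song", "song", "post_song"),
      start_s = c(on - pre_window[1L], on, off + post_window[1L]),
      end_s = c(on - pre_window[2L], off, off + post_window[2L]))
  }
  grid <- seq(trial_start, trial_end, by = 0.1)
  far <- dist_to_intervals(grid, bouts$onset_s, bouts$offset_s) >= spont_gap
  if (any(far)) {
    r <- rle(far)
    hi <- cumsum(r$lengths); lo <- hi - r$lengths + 1L
    spont <- data.frame(epoch = "spontaneous",
                        start_s = grid[lo[r$values]],
                        end_s = grid[hi[r$values]])
    spont <- spont[spont$end_s > spont$start_s, , drop = FALSE]
    win[[length(win) + 1L]] <- spont
  }
  out <- do.call(rbind, win)
  rownames(out) <- NULL
  out
}

#' Inter-spike-interval coefficient of variation per epoch
#'
#' ISIs whose two spikes fall inside one epoch window are pooled across
#' windows per epoch; CV = sample SD / mean (n - 1 denominator). ISIs
#' spanning window boundaries are discarded. Epochs with fewer than
#' `min_isis` ISIs are marked insufficient (`NA` CV).
#'
#' @param spike_times spike times (s) of one unit.
#' @param windows data.frame `epoch`, `start_s`, `end_s` (e.g. from
#'   [epoch_windows()]).
#' @param min_isis minimum ISIs per epoch, default 5.
#' @return data.frame `epoch`, `cv`, `mean_isi`, `n_isis`.
#' @export
epoch_isi_cv <- function(spike_times, windows, min_isis = 5) {
  epochs <- unique(windows$epoch)
  rows <- lapply(epochs, function(e) {
    w <- windows[windows$epoch == e, , drop = FALSE]
    isis <- numeric(0)
    for (i in seq_len(nrow(w))) {
      s <- spike_times[spike_times >= w$start_s[i] & spike_times <= w$end_s[i]]
      if (length(s) >= 2L) isis <- c(isis, diff(s))
    }
    if (length(isis) < min_isis) {
      data.frame(epoch = e, cv = NA_real_, mean_isi = NA_real_,
                 n_isis = length(isis))
    } else {
      data.frame(epoch = e, cv = stats::sd(isis) / mean(isis),
                 mean_isi = mean(isis), n_isis = length(isis))
    }
  })
  do.call(rbind, rows)
}
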