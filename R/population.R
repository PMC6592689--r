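# Population analysis: epoch labeling of calcium events, phrase index and
# neuron classes, peri-event rate traces and histograms, song-onset
# prediction, SNR and interval-normalized fluorescence.

PERI_LABELS <- c("peri_pre", "peri_gap", "peri_post")

#' Label calcium events by behavioral epoch
#'
#' Each event takes the epoch label of the frame containing its onset time
#' (frame-by-frame assignment; the onset frame governs even when the rise
#' extends into the next epoch). Events outside mask coverage are labeled
#' `other` with a warning. The three peri labels are additionally collapsed
#' into a logical `is_peri`; `peri_gap` counts as peri-song.
#'
#' @param events event table with at least `onset_s` (e.g. from
#'   [detect_events()]).
#' @param mask an `epoch_mask`.
#' @return `events` with `epoch`, `is_peri`, `is_song`, `phrase_idx` added.
#' @export
label_events <- function(events, mask) {
  stopifnot(inherits(mask, "epoch_mask"))
  if (nrow(events) == 0L) {
    events$epoch <- character(0); events$is_peri <- logical(0)
    events$is_song <- logical(0); events$phrase_idx <- integer(0)
    return(events)
  }
  times <- mask$time_s
  dt <- if (length(times) > 1L) stats::median(diff(times)) else 1 / 30
  idx <- findInterval(events$onset_s, times)
  covered <- idx >= 1L & events$onset_s < times[length(times)] + dt
  if (any(!covered)) {
    warning(sum(!covered), " event(s) outside mask coverage labeled 'other'")
  }
  epoch <- rep("other", nrow(events))
  phrase <- rep(NA_integer_, nrow(events))
  epoch[covered] <- as.character(mask$label[idx[covered]])
  phrase[covered] <- mask$phrase_idx[idx[covered]]
  events$epoch <- epoch
  events$is_peri <- epoch %in% PERI_LABELS
  events$is_song <- epoch == "song"
  events$phrase_idx <- phrase
  events
}

#' Phrase index of a neuron
#'
#' `(n_song - n_peri) / (n_song + n_peri)`: the number of song events minus
#' peri-song events over their total, bounded to -1 (peri-song exclusive) and
#' +1 (song exclusive). Neurons with fewer than `min_events` song+peri events
#' over a day of singing are excluded (`NA`), since sparse sampling could
#' spuriously mark a neuron as class-exclusive. Events labeled baseline or
#' other do not enter the ratio.
#'
#' @param n_song,n_peri nonnegative event counts (vectorized).
#' @param min_events exclusion threshold on `n_song + n_peri`, default 2.
#' @return numeric in \[-1, 1\], `NA` for excluded neurons.
#' @export
phrase_index <- function(n_song, n_peri, min_events = 2) {
  if (any(n_song < 0) || any(n_peri < 0)) stop("event counts must be >= 0")
  tot <- n_song + n_peri
  out <- ifelse(tot >= min_events, (n_song - n_peri) / tot, NA_real_)
  as.numeric(out)
}

#' Classify neurons by phrase index
#'
#' Index -1: `peri_song` (active exclusively in peri-song intervals);
#' +1: `song` (exclusively during singing); interior values: `pan_song`;
#' excluded (NA index): `excluded`.
#'
#' @param index phrase indices (possibly NA).
#' @return character vector of classes.
#' @export
classify_neuron <- function(index) {
  out <- rep("excluded", length(index))
  ok <- !is.na(index)
  out[ok & index == -1] <- "peri_song"
  out[ok & index == 1] <- "song"
  out[ok & index > -1 & index < 1] <- "pan_song"
  out
}

#' Pan-song neurons inside a near-zero phrase-index band
#'
#' Helper selecting neurons with `|index| <= band` (default band 0.18), the
#' subset with closely balanced song and peri-song activity.
#'
#' @param index phrase indices.
#' @param band half-width of the band, default 0.18.
#' @return logical vector.
#' @export
in_index_band <- function(index, band = 0.18) {
  !is.na(index) & abs(index) <= band
}

#' Summarize labeled events per neuron
#'
#' Pools song/peri/other event counts per neuron (neurons imaged across
#' multiple trials within one day should be pooled before this call; across
#' days they are distinct identities), computes the phrase index and class.
#'
#' @param labeled labeled event table from [label_events()] with `neuron_id`.
#' @param neuron_ids ids of all imaged neurons (so silent neurons appear).
#' @param min_events exclusion threshold, default 2.
#' @return data.frame `neuron_id`, `n_song_events`, `n_peri_events`,
#'   `n_other_events`, `phrase_index`, `neuron_class`.
#' @export
neuron_summary <- function(labeled, neuron_ids = unique(labeled$neuron_id),
                           min_events = 2) {
  count_for <- function(id, sel) sum(labeled$neuron_id == id & sel)
  n_song <- vapply(neuron_ids, count_for, numeric(1), sel = labeled$is_song)
  n_peri <- vapply(neuron_ids, count_for, numeric(1), sel = labeled$is_peri)
  n_oth <- vapply(neuron_ids, function(id) {
    sum(labeled$neuron_id == id & !labeled$is_song & !labeled$is_peri)
  }, numeric(1))
  idx <- phrase_index(n_song, n_peri, min_events)
  data.frame(neuron_id = neuron_ids, n_song_events = n_song,
             n_peri_events = n_peri, n_other_events = n_oth,
             phrase_index = idx, neuron_class = classify_neuron(idx))
}

# Boundary-aware moving average: for each bin center, the window is centered,
# clipped to the segment of `boundaries` containing the center so it never
# crosses a boundary, and extended within the segment (away from the clipped
# side) so its length never falls below `floor_s`.
smooth_with_boundaries <- function(centers, x, window, floor_s, boundaries) {
  boundaries <- sort(boundaries)
  out <- numeric(length(centers))
  eps <- 1e-9
  for (i in seq_along(centers)) {
    t0 <- centers[i]
    seg <- findInterval(t0, boundaries)
    a <- if (seg >= 1L) boundaries[seg] else -Inf
    b <- if (seg < length(boundaries)) boundaries[seg + 1L] else Inf
    lo <- max(a, t0 - window / 2)
    hi <- min(b, t0 + window / 2)
    need <- floor_s - (hi - lo)
    if (need > 0) {
      grow_hi <- min(need, b - hi)
      hi <- hi + grow_hi
      need <- need - grow_hi
      lo <- max(a, lo - need)
    }
    sel <- centers >= lo - eps & centers <= hi + eps
    out[i] <- mean(x[sel])
  }
  out
}

#' Alignment-relative calcium event rate trace
#'
#' Bins event onsets relative to phrase onsets (or offsets) into `bin`-second
#' bins over \[-range, +range\], converts to events/s, averages across
#' alignments (trials), and smooths with a centered moving-average window
#' that never crosses the range boundaries or the alignment point (time 0)
#' and never shrinks below `floor_s`.
#'
#' @param event_onsets event onset times (s), pooled over neurons.
#' @param alignments phrase onset (or offset) times to align to; supply only
#'   eligible phrases.
#' @param bin bin width (s), default 0.1.
#' @param window smoothing window (s), default 1.
#' @param floor_s minimum smoothing window at boundaries (s), default 0.5.
#' @param range half-range (s), default 5.
#' @param mode `"per_trial_mean"` (average per-alignment traces; default) or
#'   `"pooled"` (pool events, divide by number of alignments).
#' @return `rate_trace` data.frame: `rel_time` (bin centers), `rate_raw`,
#'   `rate_smooth`, with `n_trials`, bin and window parameters as attributes.
#' @export
event_rate_trace <- function(event_onsets, alignments, bin = 0.1, window = 1.0,
                             floor_s = 0.5, range = 5,
                             mode = c("per_trial_mean", "pooled")) {
  mode <- match.arg(mode)
  edges <- seq(-range, range, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  n_tr <- length(alignments)
  if (n_tr == 0L) {
    out <- data.frame(rel_time = centers, rate_raw = numeric(length(centers)),
                      rate_smooth = numeric(length(centers)))
    attr(out, "n_trials") <- 0L
    class(out) <- c("rate_trace", "data.frame")
    return(out)
  }
  count_one <- function(a) {
    rel <- event_onsets - a
    rel <- rel[rel >= -range & rel < range]
    tabulate(findInterval(rel, edges), nbins = length(centers))
  }
  counts <- vapply(alignments, count_one, numeric(length(centers)))
  counts <- matrix(counts, nrow = length(centers))
  rate_raw <- if (mode == "per_trial_mean") {
    rowMeans(counts / bin)
  } else {
    rowSums(counts) / (bin * n_tr)
  }
  rate_smooth <- smooth_with_boundaries(centers, rate_raw, window, floor_s,
                                        boundaries = c(-range, 0, range))
  out <- data.frame(rel_time = centers, rate_raw = rate_raw,
                    rate_smooth = rate_smooth)
  attr(out, "n_trials") <- n_tr
  attr(out, "bin") <- bin
  attr(out, "window") <- window
  attr(out, "floor_s") <- floor_s
  class(out) <- c("rate_trace", "data.frame")
  out
}

#' Peri-event histogram of calcium events
#'
#' Counts per alignment-relative bin, either raw event counts or the number
#' of distinct active neurons (a neuron counted once per bin).
#'
#' @param events data.frame with `onset_s` and (for neuron mode) `neuron_id`.
#' @param alignments alignment times (s).
#' @param bin bin width (s), default 0.2.
#' @param range half-range (s), default 5.
#' @param mode `"events"` or `"neurons"`.
#' @return data.frame `rel_time` (bin centers), `count`.
#' @export
perievent_histogram <- function(events, alignments, bin = 0.2, range = 5,
                                mode = c("events", "neurons")) {
  mode <- match.arg(mode)
  edges <- seq(-range, range, by = bin)
  centers <- edges[-length(edges)] + bin / 2
  count <- numeric(length(centers))
  for (a in alignments) {
    rel <- events$onset_s - a
    keep <- rel >= -range & rel < range
    if (!any(keep)) next
    b <- findInterval(rel[keep], edges)
    if (mode == "events") {
      count <- count + tabulate(b, nbins = length(centers))
    } else {
      u <- unique(data.frame(bin = b, id = events$neuron_id[keep]))
      count <- count + tabulate(u$bin, nbins = length(centers))
    }
  }
  data.frame(rel_time = centers, count = count)
}

#' Song-onset prediction from the population event-rate trace
#'
#' Baseline mean and SD of the smoothed rate come from the bins in
#' `baseline_range` (default -5 to -4 s before phrase onset). The predicted
#' crossing is the earliest time after the baseline window where the smoothed
#' rate exceeds `mean + k * sd` and stays above it for at least `dwell`
#' seconds; `NA` when never crossed. An SD floor guards silent baselines.
#'
#' @param trace a `rate_trace` aligned to phrase onset covering \[-5, 0\].
#' @param k threshold in baseline SDs, default 3.
#' @param baseline_range baseline window (s), default `c(-5, -4)`.
#' @param dwell required time above threshold (s), default 0.2.
#' @param sd_floor minimum baseline SD (events/s), default 0.05.
#' @return list with `baseline_mean`, `baseline_sd`, `threshold`,
#'   `crossing_time` (s, negative = before onset; `NA` if never crossed).
#' @export
onset_prediction <- function(trace, k = 3, baseline_range = c(-5, -4),
                             dwell = 0.2, sd_floor = 0.05) {
  stopifnot(inherits(trace, "rate_trace"))
  base <- trace$rate_smooth[trace$rel_time >= baseline_range[1L] &
                              trace$rel_time < baseline_range[2L]]
  if (length(base) == 0L) stop("trace does not cover the baseline window")
  mu <- mean(base)
  sdv <- max(stats::sd(base), sd_floor)
  thr <- mu + k * sdv
  bin <- attr(trace, "bin")
  need <- max(1L, ceiling(dwell / bin))
  cand <- which(trace$rel_time >= baseline_range[2L] & trace$rel_time < 0)
  crossing <- NA_real_
  above <- trace$rate_smooth > thr
  for (i in cand) {
    run <- i:min(i + need - 1L, nrow(trace))
    if (length(run) == need && all(above[run])) {
      crossing <- trace$rel_time[i]
      break
    }
  }
  list(baseline_mean = mu, baseline_sd = sdv, threshold = thr,
       crossing_time = crossing)
}

#' Per-neuron signal-to-noise ratio of song events
#'
#' Each song event's peak fluorescence is divided by the neuron's mean
#' fluorescence over a quiet baseline period (5 s, at least 10 s removed
#' from song or calls); the per-event ratios are averaged per neuron.
#'
#' @param peak_fluorescence peak fluorescence of each song event.
#' @param neuron_id neuron id per event.
#' @param baseline_mean named vector of per-neuron baseline means (names =
#'   neuron ids), all > 0.
#' @return data.frame `neuron_id`, `snr`, `n_events`.
#' @export
event_snr <- function(peak_fluorescence, neuron_id, baseline_mean) {
  ids <- unique(neuron_id)
  bm <- baseline_mean[as.character(ids)]
  if (any(is.na(bm)) || any(bm <= 0)) {
    stop("baseline mean missing or <= 0 for some neurons")
  }
  snr <- vapply(seq_along(ids), function(i) {
    mean(peak_fluorescence[neuron_id == ids[i]]) / bm[i]
  }, numeric(1))
  # per-event ratio then per-neuron average equals mean(peaks)/baseline since
  # the baseline is a per-neuron constant
  n_ev <- vapply(ids, function(id) sum(neuron_id == id), integer(1))
  data.frame(neuron_id = ids, snr = snr, n_events = n_ev)
}

#' Interval-normalized mean fluorescence
#'
#' Mean background-subtracted fluorescence over baseline, peri_pre, peri_post
#' and song frames, each divided by the song mean (song maps to 1 by
#' construction).
#'
#' @param trace `fluor_trace`.
#' @param mask `epoch_mask` on the same frame grid.
#' @return named numeric vector `baseline`, `peri_pre`, `peri_post`, `song`.
#' @export
interval_fluorescence <- function(trace, mask) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(mask, "epoch_mask"))
  stopifnot(length(trace$corrected) == nrow(mask))
  song_mean <- mean(trace$corrected[mask$label == "song"])
  if (!is.finite(song_mean) || is.nan(song_mean)) {
    stop("no song frames in mask: interval fluorescence undefined")
  }
  lv <- c("baseline", "peri_pre", "peri_post", "song")
  out <- vapply(lv, function(l) {
    mean(trace$corrected[mask$label == l]) / song_mean
  }, numeric(1))
  names(out) <- lv
  out
}

#' Fraction of neurons active per phrase and epoch
#'
#' For each phrase, the percentage of imaged neurons with at least one event
#' whose onset is labeled with the requested epoch group of that phrase.
#'
#' @param labeled labeled events (from [label_events()]) with `neuron_id` and
#'   `phrase_idx`.
#' @param n_neurons total number of imaged neurons.
#' @param epoch `"song"` or `"peri"` (peri_pre + peri_gap + peri_post).
#' @param phrase_idx phrases to evaluate; defaults to all phrases present.
#' @return data.frame `phrase_idx`, `pct_active`; mean and SD across phrases
#'   attached as attributes `mean` and `sd`.
#' @export
active_fraction <- function(labeled, n_neurons, epoch = c("song", "peri"),
                            phrase_idx = NULL) {
  epoch <- match.arg(epoch)
  if (n_neurons <= 0L) stop("need at least one imaged neuron")
  sel <- if (epoch == "song") labeled$is_song else labeled$is_peri
  if (is.null(phrase_idx)) {
    phrase_idx <- sort(unique(labeled$phrase_idx[!is.na(labeled$phrase_idx)]))
  }
  pct <- vapply(phrase_idx, function(p) {
    100 * length(unique(labeled$neuron_id[sel & labeled$phrase_idx %in% p])) /
      n_neurons
  }, numeric(1))
  out <- data.frame(phrase_idx = phrase_idx, pct_active = pct)
  attr(out, "mean") <- mean(pct)
  attr(out, "sd") <- stats::sd(pct)
  out
}
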