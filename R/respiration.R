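# Air-sac pressure analysis: respiratory cycle segmentation, song-relative
# markers, and per-epoch / per-bin summaries of cycle duration, expiratory
# duty cycle and rectified amplitude.

#' Segment an air-sac pressure trace into respiratory cycles
#'
#' A respiratory cycle is an inspiration (subambient pressurization) followed
#' by an expiration (return to and above ambient). The signal is low-pass
#' filtered, the ambient level estimated as the median over a quiet window,
#' and phase transitions detected with a hysteresis band (a fraction of the
#' quiet-breathing peak-to-peak amplitude) to suppress chatter: the state
#' switches to inspiratory only when the signal falls below `ambient - band`
#' and to expiratory only when it rises above `ambient + band`; the
#' band-crossing times mark the phase onsets. A cycle runs from one
#' inspiration onset to the next (so durations are insensitive to the small,
#' symmetric band-crossing delay); cycles missing an expiratory phase and
#' partial cycles at the trace edges are dropped.
#'
#' @param pressure sampled relative pressure (ambient near 0, arbitrary
#'   units).
#' @param fs sampling rate (Hz).
#' @param quiet_window `c(start_s, end_s)` of a quiet-breathing stretch used
#'   for the ambient level and hysteresis scale; defaults to the first 3 s.
#' @param hysteresis band half-width as a fraction of quiet peak-to-peak,
#'   default 0.05.
#' @param lowpass low-pass corner (Hz), default 400; `NULL` skips filtering.
#' @param ambient ambient pressure level; `NULL` (default) uses the median
#'   over `quiet_window`.
#' @return data.frame of cycles: `insp_onset_s`, `exp_onset_s`,
#'   `cycle_end_s`, `duration_s`, `duty_pct` (percent of the cycle in the
#'   expiratory phase), `amplitude` (mean rectified pressure about ambient);
#'   `ambient` attribute.
#' @export
segment_cycles <- function(pressure, fs, quiet_window = NULL,
                           hysteresis = 0.05, lowpass = 400, ambient = NULL) {
  x <- pressure
  if (!is.null(lowpass) && lowpass < fs / 2) {
    bf <- signal::butter(4, lowpass / (fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  t <- (seq_along(x) - 1) / fs
  if (is.null(quiet_window)) quiet_window <- c(0, min(3, max(t)))
  qsel <- t >= quiet_window[1L] & t < quiet_window[2L]
  if (!any(qsel)) stop("quiet window outside trace")
  if (is.null(ambient)) ambient <- stats::median(x[qsel])
  p2p <- diff(range(x[qsel]))
  band <- hysteresis * p2p
  xc <- x - ambient

  # hysteretic two-state machine: -1 inspiratory, +1 expiratory, 0 unknown
  below <- xc < -band
  above <- xc > band
  state <- 0L
  insp_idx <- integer(0)
  exp_idx <- integer(0)
  for (i in seq_along(xc)) {
    if (state != -1L && below[i]) {
      insp_idx <- c(insp_idx, i)
      state <- -1L
    } else if (state != 1L && above[i]) {
      if (state == -1L) exp_idx <- c(exp_idx, i)
      state <- 1L
    }
  }
  empty <- data.frame(insp_onset_s = numeric(0), exp_onset_s = numeric(0),
                      cycle_end_s = numeric(0), duration_s = numeric(0),
                      duty_pct = numeric(0), amplitude = numeric(0))
  if (length(insp_idx) < 2L) {
    attr(empty, "ambient") <- ambient
    return(empty)
  }
  rows <- list()
  for (ci in seq_len(length(insp_idx) - 1L)) {
    i0 <- insp_idx[ci]; i1 <- insp_idx[ci + 1L]
    ex <- exp_idx[exp_idx > i0 & exp_idx < i1]
    if (length(ex) == 0L) next  # no expiratory phase: discard
    ex <- ex[1L]
    seg <- i0:(i1 - 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      insp_onset_s = t[i0],
      exp_onset_s = t[ex],
      cycle_end_s = t[i1],
      duration_s = t[i1] - t[i0],
      duty_pct = 100 * (i1 - ex) / (i1 - i0),
      amplitude = mean(abs(xc[seg]))
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "ambient") <- ambient
  out
}

#' Song onset/offset markers on the respiratory clock
#'
#' Song onset is the inspiration preceding the first introductory note: the
#' `insp_onset_s` of the last cycle starting before the first intro note (or
#' first song element when no intro is annotated). Song offset is the
#' termination of the expiration generating the last song syllable: the
#' `cycle_end_s` of the cycle containing the last syllable's offset.
#'
#' @param cycles cycle table from [segment_cycles()].
#' @param syllables validated syllable table on the same clock.
#' @return list `onset_s`, `offset_s`.
#' @export
song_markers <- function(cycles, syllables) {
  validate_syllables(syllables)
  song <- syllables[is_song_label(syllables$label), , drop = FALSE]
  if (nrow(song) == 0L) stop("no song elements in annotations")
  intro <- song[song$label == "intro", , drop = FALSE]
  first_note <- if (nrow(intro)) min(intro$onset_s) else min(song$onset_s)
  last_off <- max(song$offset_s)
  pre <- cycles$insp_onset_s < first_note
  if (!any(pre)) stop("no respiratory cycle precedes the first song element")
  onset <- max(cycles$insp_onset_s[pre])
  containing <- cycles$insp_onset_s <= last_off & cycles$cycle_end_s > last_off
  offset <- if (any(containing)) {
    cycles$cycle_end_s[which(containing)[1L]]
  } else {
    # last syllable ends after the last complete cycle: use the first cycle
    # end at or after it, else the last cycle end
    ge <- cycles$cycle_end_s[cycles$cycle_end_s >= last_off]
    if (length(ge)) min(ge) else max(cycles$cycle_end_s)
  }
  list(onset_s = onset, offset_s = offset)
}

#' Assign cycles to pre/song/post epochs and summarize
#'
#' Cycles are assigned by their inspiration onset relative to the song
#' markers: `pre` within `pre_window` seconds before the onset marker,
#' `song` between the markers, `post` within `post_window` seconds after the
#' offset marker. Per-epoch means of duration, duty cycle and amplitude are
#' returned, together with per-`bin`-second means keyed to time before onset
#' (bin -1 = last second pre-song) and after offset (bin 1 = first second
#' post-song).
#'
#' @param cycles cycle table from [segment_cycles()].
#' @param markers list `onset_s`, `offset_s` from [song_markers()].
#' @param pre_window,post_window window lengths (s), default 5.
#' @param bin bin width (s) for the time course, default 1.
#' @return list with `cycles` (annotated with `epoch`, `rel_time_s`,
#'   `bin_idx`), `epoch_summary` (per-epoch means and n), `bin_summary`
#'   (per-bin means and n).
#' @export
summarize_epochs <- function(cycles, markers, pre_window = 5, post_window = 5,
                             bin = 1.0) {
  on <- markers$onset_s; off <- markers$offset_s
  ep <- rep(NA_character_, nrow(cycles))
  rel <- rep(NA_real_, nrow(cycles))
  io <- cycles$insp_onset_s
  ep[io >= on - pre_window & io < on] <- "pre"
  ep[io >= on & io < off] <- "song"
  ep[io >= off & io < off + post_window] <- "post"
  sel_pre <- !is.na(ep) & ep == "pre"
  sel_song <- !is.na(ep) & ep == "song"
  sel_post <- !is.na(ep) & ep == "post"
  rel[sel_pre] <- io[sel_pre] - on
  rel[sel_song] <- io[sel_song] - on
  rel[sel_post] <- io[sel_post] - off
  bin_idx <- rep(NA_integer_, nrow(cycles))
  bin_idx[sel_pre] <- -ceiling(-rel[sel_pre] / bin)
  bin_idx[sel_post] <- ceiling((rel[sel_post] + 1e-12) / bin)
  cyc <- cycles
  cyc$epoch <- ep; cyc$rel_time_s <- rel; cyc$bin_idx <- bin_idx

  mean_by <- function(key) {
    keep <- !is.na(key)
    if (!any(keep)) {
      return(data.frame(key = character(0), duration_s = numeric(0),
                        duty_pct = numeric(0), amplitude = numeric(0),
                        n = integer(0)))
    }
    agg <- stats::aggregate(
      cyc[keep, c("duration_s", "duty_pct", "amplitude")],
      by = list(key = key[keep]), FUN = mean)
    agg$n <- as.integer(table(key[keep])[as.character(agg$key)])
    agg
  }
  list(cycles = cyc,
       epoch_summary = mean_by(ep),
       bin_summary = mean_by(bin_idx))
}

#' Check the quiet-respiration requirement around a song
#'
#' A song is usable when at least `min_quiet` seconds of uninterrupted quiet
#' respiration (cycles present and no song elements) precede the onset
#' marker and follow the offset marker.
#'
#' @param cycles cycle table.
#' @param markers song markers.
#' @param min_quiet required quiet time (s), default 3.
#' @return TRUE/FALSE.
#' @export
has_quiet_respiration <- function(cycles, markers, min_quiet = 3) {
  io <- cycles$insp_onset_s
  pre <- io[io >= markers$onset_s - min_quiet - 1 & io < markers$onset_s]
  post <- io[io >= markers$offset_s & io < markers$offset_s + min_quiet + 1]
  pre_ok <- length(pre) > 0 && (markers$onset_s - min(pre)) >= min_quiet
  post_ok <- length(post) > 0 &&
    (max(cycles$cycle_end_s[io %in% post]) - markers$offset_s) >= min_quiet
  pre_ok && post_ok
}
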