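# Behavioral timeline: bouts, phrases, and frame-wise epoch labels from
# syllable annotations.
#
# Conventions used throughout: all intervals are half-open [onset, offset) in
# seconds (float), and a sample/frame is labeled by its start time. Syllable
# labels fall into four groups: introductory notes ("intro"), motif syllables
# (any label not listed below, e.g. "syl_a"), calls ("call"), and non-vocal
# noise ("noise"). Introductory notes and motif syllables are song elements;
# calls are vocal but not song; noise is neither.

SONG_EXCLUDED_LABELS <- c("call", "noise")
EPOCH_LEVELS <- c("song", "peri_pre", "peri_gap", "peri_post", "baseline", "other")

is_song_label <- function(label) !(label %in% SONG_EXCLUDED_LABELS)
is_vocal_label <- function(label) label != "noise"

#' Validate a syllable annotation table
#'
#' Checks the column contract (`onset_s`, `offset_s`, `label`), positive
#' durations, sorted onsets and absence of overlap between consecutive
#' intervals.
#'
#' @param syllables data.frame with columns `onset_s`, `offset_s`, `label`
#'   (and optionally `trial_id`).
#' @return the validated table, invisibly unchanged.
#' @export
validate_syllables <- function(syllables) {
  stopifnot(is.data.frame(syllables))
  req <- c("onset_s", "offset_s", "label")
  if (!all(req %in% names(syllables))) {
    stop("syllable table must have columns onset_s, offset_s, label")
  }
  if (nrow(syllables) == 0L) return(invisible(syllables))
  if (any(syllables$onset_s >= syllables$offset_s)) {
    stop("every syllable must satisfy onset_s < offset_s")
  }
  if (is.unsorted(syllables$onset_s)) {
    stop("syllable table must be sorted by onset_s")
  }
  if (nrow(syllables) > 1L) {
    gap <- syllables$onset_s[-1L] - syllables$offset_s[-nrow(syllables)]
    if (any(gap < -1e-9)) stop("syllable intervals must not overlap")
  }
  invisible(syllables)
}

#' Read a syllable annotation table from a delimited file
#'
#' Accepts comma- or tab-separated files with columns `onset_s`, `offset_s`,
#' `label` and optionally `trial_id`; the table is validated on read.
#'
#' @param path file path.
#' @param sep field separator; guessed from the first line when `NULL`.
#' @return validated data.frame of syllable intervals.
#' @export
read_annotations <- function(path, sep = NULL) {
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_syllables(tab)
  tab
}

# Group sorted intervals: a new group starts where the silent gap to the
# previous interval is >= threshold (strictly-less-than keeps the group).
group_by_gap <- function(onsets, offsets, threshold) {
  n <- length(onsets)
  if (n == 0L) return(integer(0))
  grp <- integer(n)
  grp[1L] <- 1L
  if (n > 1L) {
    running_off <- offsets[1L]
    for (i in 2L:n) {
      gap <- onsets[i] - running_off
      grp[i] <- grp[i - 1L] + (gap >= threshold)
      running_off <- max(running_off, offsets[i])
    }
  }
  grp
}

#' Assemble song phrases (and their bouts) from syllable annotations
#'
#' Song elements (introductory notes and motif syllables) separated by silent
#' gaps strictly shorter than `gap_threshold` belong to one song phrase; a gap
#' of `gap_threshold` or more starts a new phrase. Within a phrase, elements
#' separated by gaps shorter than `bout_gap` form one song bout. Calls and
#' noise never seed or extend a phrase. Phrase onset is the onset of the first
#' vocal element of the phrase, introductory notes included.
#'
#' @param syllables validated syllable table (see [validate_syllables()]).
#' @param gap_threshold silence (s) at or above which a new phrase begins.
#'   Default 2 s.
#' @param bout_gap silence (s) at or above which a new bout begins within a
#'   phrase. Default 0.5 s, above intra-bout mini-breath gaps (tens of ms)
#'   and below typical inter-bout silences.
#' @return data.frame with one row per phrase: `phrase_idx`, `onset_s`,
#'   `offset_s`, `n_bouts`, `n_syllables`, `n_motifs`; the per-phrase bout
#'   intervals are attached as attribute `"bouts"` (data.frame `phrase_idx`,
#'   `bout_idx`, `onset_s`, `offset_s`).
#' @export
assemble_phrases <- function(syllables, gap_threshold = 2.0, bout_gap = 0.5) {
  validate_syllables(syllables)
  song <- syllables[is_song_label(syllables$label), , drop = FALSE]
  empty <- data.frame(phrase_idx = integer(0), onset_s = numeric(0),
                      offset_s = numeric(0), n_bouts = integer(0),
                      n_syllables = integer(0), n_motifs = integer(0))
  attr(empty, "bouts") <- data.frame(phrase_idx = integer(0), bout_idx = integer(0),
                                     onset_s = numeric(0), offset_s = numeric(0))
  if (nrow(song) == 0L) return(empty)

  phr <- group_by_gap(song$onset_s, song$offset_s, gap_threshold)
  bout_rows <- list()
  phrase_rows <- lapply(unique(phr), function(p) {
    s <- song[phr == p, , drop = FALSE]
    b <- group_by_gap(s$onset_s, s$offset_s, bout_gap)
    bouts <- data.frame(
      phrase_idx = p,
      bout_idx = unique(b),
      onset_s = tapply(s$onset_s, b, min),
      offset_s = tapply(s$offset_s, b, max),
      row.names = NULL
    )
    bout_rows[[length(bout_rows) + 1L]] <<- bouts
    motif_labels <- s$label[s$label != "intro"]
    n_motifs <- if (length(motif_labels)) sum(motif_labels == motif_labels[1L]) else 0L
    data.frame(phrase_idx = p, onset_s = min(s$onset_s), offset_s = max(s$offset_s),
               n_bouts = max(b), n_syllables = nrow(s), n_motifs = n_motifs)
  })
  out <- do.call(rbind, phrase_rows)
  out$phrase_idx <- seq_len(nrow(out))
  bouts <- do.call(rbind, bout_rows)
  bouts$phrase_idx <- rep(out$phrase_idx, vapply(bout_rows, nrow, 1L))
  rownames(out) <- NULL
  attr(out, "bouts") <- bouts
  out
}

#' Build a frame-wise behavioral epoch mask
#'
#' Labels every time point of a sample grid with exactly one epoch:
#' \describe{
#'   \item{song}{within a song bout (vocal time including intra-bout
#'     mini-breath gaps).}
#'   \item{peri_gap}{silent gaps between bouts inside one phrase.}
#'   \item{peri_pre / peri_post}{up to `pre_window` / `post_window` seconds
#'     before / after each phrase, truncated where two phrases' windows would
#'     collide (split at the midpoint of the inter-phrase gap) and wherever
#'     song takes precedence.}
#'   \item{baseline}{points at least `baseline_gap` seconds away from any song
#'     bout or call.}
#'   \item{other}{everything else.}
#' }
#' Calls inside peri windows keep the peri label; calls reset the baseline
#' exclusion clock.
#'
#' @param syllables validated syllable table.
#' @param times strictly increasing sample/frame start times (s).
#' @param pre_window,post_window peri window lengths (s), default 5.
#' @param baseline_gap minimum distance (s) from song or calls for baseline,
#'   default 10.
#' @param gap_threshold,bout_gap passed to [assemble_phrases()].
#' @return an `epoch_mask`: data.frame with columns `time_s`, `label` (factor
#'   over song/peri_pre/peri_gap/peri_post/baseline/other) and `phrase_idx`
#'   (phrase a song/peri point belongs to, `NA` elsewhere); phrase table and
#'   window parameters attached as attributes.
#' @export
build_epoch_mask <- function(syllables, times, pre_window = 5, post_window = 5,
                             baseline_gap = 10, gap_threshold = 2.0,
                             bout_gap = 0.5) {
  validate_syllables(syllables)
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("sample grid must be strictly increasing")
  }
  phrases <- assemble_phrases(syllables, gap_threshold, bout_gap)
  bouts <- attr(phrases, "bouts")
  calls <- syllables[syllables$label == "call", , drop = FALSE]

  label <- rep("other", length(times))
  phrase_of <- rep(NA_integer_, length(times))

  # baseline: >= baseline_gap from every song bout and call (vocal elements)
  excl_start <- c(bouts$onset_s, calls$onset_s)
  excl_end <- c(bouts$offset_s, calls$offset_s)
  d <- dist_to_intervals(times, excl_start, excl_end)
  label[d >= baseline_gap] <- "baseline"

  n_p <- nrow(phrases)
  if (n_p > 0L) {
    for (i in seq_len(n_p)) {
      on <- phrases$onset_s[i]; off <- phrases$offset_s[i]
      pre_lo <- on - pre_window
      post_hi <- off + post_window
      if (i > 1L) {
        prev_off <- phrases$offset_s[i - 1L]
        if (on - prev_off < pre_window + post_window) {
          pre_lo <- max(pre_lo, (prev_off + on) / 2)
        }
      }
      if (i < n_p) {
        next_on <- phrases$onset_s[i + 1L]
        if (next_on - off < pre_window + post_window) {
          post_hi <- min(post_hi, (off + next_on) / 2)
        }
      }
      sel_pre <- times >= pre_lo & times < on
      sel_gap <- times >= on & times < off
      sel_post <- times >= off & times < post_hi
      label[sel_pre] <- "peri_pre"
      label[sel_gap] <- "peri_gap"
      label[sel_post] <- "peri_post"
      phrase_of[sel_pre | sel_gap | sel_post] <- phrases$phrase_idx[i]
    }
    # song takes precedence over every peri label
    in_song <- in_any_interval(times, bouts$onset_s, bouts$offset_s)
    label[in_song] <- "song"
  }

  out <- data.frame(
    time_s = times,
    label = factor(label, levels = EPOCH_LEVELS),
    phrase_idx = phrase_of
  )
  attr(out, "phrases") <- phrases
  attr(out, "params") <- list(pre_window = pre_window, post_window = post_window,
                              baseline_gap = baseline_gap,
                              gap_threshold = gap_threshold, bout_gap = bout_gap)
  class(out) <- c("epoch_mask", "data.frame")
  out
}

#' Run-length encode an epoch mask
#'
#' Compact serialization of an epoch mask as contiguous label runs.
#'
#' @param mask an `epoch_mask` from [build_epoch_mask()].
#' @return data.frame with `label`, `start_s`, `end_s`, `n_samples` per run.
#' @export
epoch_rle <- function(mask) {
  stopifnot(inherits(mask, "epoch_mask"))
  r <- rle(as.character(mask$label))
  hi <- cumsum(r$lengths)
  lo <- hi - r$lengths + 1L
  dt <- if (nrow(mask) > 1L) stats::median(diff(mask$time_s)) else 0
  data.frame(label = r$values,
             start_s = mask$time_s[lo],
             end_s = mask$time_s[hi] + dt,
             n_samples = r$lengths)
}

#' Phrase eligibility for pre-/post-song analysis
#'
#' A phrase is eligible for pre-song analysis when no vocal element (song
#' syllable, introductory note or call) occurs within `min_silence` seconds
#' before its onset; analogously after its offset for post-song analysis.
#' Phrases whose silence requirement would extend beyond the recorded trial
#' are ineligible and flagged truncated.
#'
#' @param phrases phrase table from [assemble_phrases()].
#' @param syllables the full syllable table (calls included).
#' @param min_silence required silence (s), default 5.
#' @param trial_start,trial_end recording limits (s).
#' @return data.frame with `phrase_idx`, `pre_eligible`, `post_eligible`,
#'   `pre_truncated`, `post_truncated`.
#' @export
phrase_eligibility <- function(phrases, syllables, min_silence = 5,
                               trial_start = 0, trial_end = Inf) {
  validate_syllables(syllables)
  vocal <- syllables[is_vocal_label(syllables$label), , drop = FALSE]
  out <- data.frame(phrase_idx = phrases$phrase_idx,
                    pre_eligible = logical(nrow(phrases)),
                    post_eligible = logical(nrow(phrases)),
                    pre_truncated = logical(nrow(phrases)),
                    post_truncated = logical(nrow(phrases)))
  for (i in seq_len(nrow(phrases))) {
    on <- phrases$onset_s[i]; off <- phrases$offset_s[i]
    pre_trunc <- (on - min_silence) < trial_start
    post_trunc <- (off + min_silence) > trial_end
    # vocal elements strictly inside the silence window, excluding the
    # phrase's own elements
    before <- vocal$offset_s > on - min_silence & vocal$offset_s <= on &
      vocal$onset_s < on
    after <- vocal$onset_s < off + min_silence & vocal$onset_s >= off &
      vocal$offset_s > off
    own <- vocal$onset_s >= on & vocal$offset_s <= off
    out$pre_truncated[i] <- pre_trunc
    out$post_truncated[i] <- post_trunc
    out$pre_eligible[i] <- !pre_trunc && !any(before & !own)
    out$post_eligible[i] <- !post_trunc && !any(after & !own)
  }
  out
}

#' @rdname phrase_eligibility
#' @param phrase_idx index of one phrase in `phrases`.
#' @export
eligible_for_pre_analysis <- function(phrases, syllables, phrase_idx,
                                      min_silence = 5, trial_start = 0) {
  e <- phrase_eligibility(phrases, syllables, min_silence, trial_start)
  e$pre_eligible[e$phrase_idx == phrase_idx]
}

#' @rdname phrase_eligibility
#' @export
eligible_for_post_analysis <- function(phrases, syllables, phrase_idx,
                                       min_silence = 5, trial_end = Inf) {
  e <- phrase_eligibility(phrases, syllables, min_silence,
                          trial_end = trial_end)
  e$post_eligible[e$phrase_idx == phrase_idx]
}
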