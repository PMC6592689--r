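# Calcium trace processing: ROI extraction with ring background, iterative
# baseline/noise estimation, AR(1) nonnegative deconvolution by
# pool-adjacent-violators pooling, and transient (event) detection.

#' Construct a fluorescence trace object
#'
#' Container for one neuron's per-frame fluorescence. `corrected` is always
#' `raw - background`.
#'
#' @param raw per-frame ROI-mean fluorescence (arbitrary units).
#' @param background per-frame ring-ROI background fluorescence; 0 if already
#'   corrected.
#' @param frame_times frame start times (s); defaults to a 30 frames/s grid.
#' @param neuron_id optional identifier.
#' @return object of class `fluor_trace`.
#' @export
fluor_trace <- function(raw, background = numeric(length(raw)),
                        frame_times = (seq_along(raw) - 1) / 30,
                        neuron_id = NA) {
  stopifnot(length(raw) == length(background),
            length(raw) == length(frame_times))
  structure(list(neuron_id = neuron_id, frame_times = frame_times,
                 raw = raw, background = background,
                 corrected = raw - background,
                 baseline = NULL, noise_sd = NULL, active_mask = NULL),
            class = "fluor_trace")
}

# Chebyshev dilation of a logical mask by r pixels (small images only).
dilate_mask <- function(mask, r) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i0 <- max(1L, idx[k, 1L] - r); i1 <- min(nr, idx[k, 1L] + r)
    j0 <- max(1L, idx[k, 2L] - r); j1 <- min(nc, idx[k, 2L] + r)
    out[i0:i1, j0:j1] <- TRUE
  }
  out
}

#' Extract ROI traces with ring-background subtraction from a movie
#'
#' For each neuronal ROI, `raw` is the per-frame mean over ROI pixels and
#' `background` the per-frame mean over a ring extending `ring_width` pixels
#' around the ROI boundary, excluding the pixels of every neuronal ROI. When
#' the exclusion empties a ring, the nearest non-ROI pixels are used instead
#' (with a warning).
#'
#' @param movie numeric array `[rows, cols, frames]`.
#' @param roi_masks list of logical matrices (one per neuron) matching the
#'   movie's spatial dimensions.
#' @param ring_width ring thickness in pixels, default 6.
#' @param frame_times optional frame times; default 30 frames/s grid.
#' @return list of `fluor_trace` objects.
#' @export
extract_roi_traces <- function(movie, roi_masks, ring_width = 6,
                               frame_times = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  nr <- dim(movie)[1L]; nc <- dim(movie)[2L]; nf <- dim(movie)[3L]
  if (is.null(frame_times)) frame_times <- (seq_len(nf) - 1) / 30
  all_roi <- Reduce(`|`, roi_masks)
  flat <- matrix(movie, nrow = nr * nc, ncol = nf)
  lapply(seq_along(roi_masks), function(i) {
    m <- roi_masks[[i]]
    stopifnot(identical(dim(m), c(nr, nc)))
    ring <- dilate_mask(m, ring_width) & !all_roi
    if (!any(ring)) {
      warning("ring empty after ROI exclusion; using nearest non-ROI pixels")
      d <- outer(seq_len(nr), seq_len(nc), function(a, b) {
        idx <- which(m, arr.ind = TRUE)
        apply(cbind(a, b), 1L, function(p) {
          min(pmax(abs(idx[, 1L] - p[1L]), abs(idx[, 2L] - p[2L])))
        })
      })
      d[all_roi] <- Inf
      ring <- d <= sort(d[is.finite(d)])[min(20L, sum(is.finite(d)))]
    }
    raw <- colMeans(flat[as.vector(m), , drop = FALSE])
    bg <- colMeans(flat[as.vector(ring), , drop = FALSE])
    fluor_trace(raw, bg, frame_times, neuron_id = i)
  })
}

# Running lower-percentile filter: percentile of the quiescent samples in a
# sliding window, evaluated on a coarse grid and interpolated.
running_percentile <- function(x, keep, window_frames, prob, stride) {
  n <- length(x)
  centers <- unique(c(seq(1L, n, by = stride), n))
  half <- floor(window_frames / 2)
  vals <- vapply(centers, function(c0) {
    lo <- max(1L, c0 - half); hi <- min(n, c0 + half)
    xs <- x[lo:hi][keep[lo:hi]]
    if (length(xs) == 0L) NA_real_ else stats::quantile(xs, prob, names = FALSE)
  }, numeric(1))
  ok <- !is.na(vals)
  if (!any(ok)) return(rep(NA_real_, n))
  stats::approx(centers[ok], vals[ok], xout = seq_len(n), rule = 2)$y
}

#' Iterative baseline, noise and activity estimation
#'
#' The noise SD is estimated once, robustly, from the first differences of
#' the trace (`1.4826 * mad(diff) / sqrt(2)`): transients are sparse and,
#' apart from their fast onsets, slow relative to the frame rate, so the
#' frame-to-frame differences are noise-dominated even when calcium rarely
#' returns to baseline during song. The procedure then alternates until the
#' active-frame mask is stable (or `max_iter`): (1) baseline from a running
#' 20th-percentile filter over the currently quiescent frames (window
#' `baseline_window` seconds), offset by `qnorm(0.8) * sigma` so the
#' estimate is consistent for Gaussian noise; (2) active frames = residual
#' above `k_active * sigma`, dilated by `dilate_frames` backward and by
#' `dilate_forward_s` seconds forward (indicator decay keeps fluorescence
#' elevated well past the suprathreshold run, and those tails would
#' otherwise bias the percentile baseline). A noise floor keeps thresholds
#' finite on noiseless input.
#'
#' @param trace a `fluor_trace` with `corrected` set.
#' @param k_active activity threshold in noise SDs, default 3.
#' @param max_iter maximum iterations, default 20.
#' @param baseline_window percentile-filter window (s), default 30.
#' @param dilate_frames backward dilation of the active mask (frames),
#'   default 2.
#' @param dilate_forward_s forward dilation of the active mask (s), default
#'   0.75 (roughly half a GCaMP6s decay constant).
#' @return the trace with `baseline`, `noise_sd`, `active_mask`,
#'   `converged`, `iterations` filled in.
#' @export
estimate_baseline_noise <- function(trace, k_active = 3, max_iter = 20,
                                    baseline_window = 30, dilate_frames = 2,
                                    dilate_forward_s = 0.75) {
  stopifnot(inherits(trace, "fluor_trace"))
  y <- trace$corrected
  n <- length(y)
  dt <- if (n > 1L) stats::median(diff(trace$frame_times)) else 1 / 30
  win <- max(3L, round(baseline_window / dt))
  stride <- max(1L, round(0.5 / dt))
  floor_sd <- function(s) max(s, 1e-6 * max(max(abs(y)), 1))

  sigma <- floor_sd(1.4826 * stats::mad(diff(y), constant = 1) / sqrt(2))
  active <- rep(FALSE, n)
  converged <- FALSE
  iter <- 0L
  baseline <- rep(0, n)
  for (iter in seq_len(max_iter)) {
    quiescent <- !active
    if (!any(quiescent)) stop("no quiescent baseline: all frames active")
    p20 <- running_percentile(y, quiescent, win, 0.2, stride)
    baseline <- p20 + stats::qnorm(0.8) * sigma
    resid <- y - baseline
    new_active <- resid > k_active * sigma
    if (any(new_active)) {
      idx <- which(new_active)
      fwd <- max(dilate_frames, round(dilate_forward_s / dt))
      for (d in seq_len(dilate_frames)) new_active[pmax(idx - d, 1L)] <- TRUE
      for (d in seq_len(fwd)) new_active[pmin(idx + d, n)] <- TRUE
    }
    if (identical(new_active, active)) { converged <- TRUE; break }
    active <- new_active
  }
  if (all(active)) stop("no quiescent baseline: all frames active")
  trace$baseline <- baseline
  trace$noise_sd <- sigma
  trace$active_mask <- active
  trace$converged <- converged
  trace$iterations <- iter
  trace
}

#' Nonnegative AR(1) deconvolution by pool-adjacent-violators pooling
#'
#' Solves
#' \deqn{\min_c \sum_t (y_t - c_t)^2 \quad \mathrm{s.t.}\ c_t \ge \gamma
#'   c_{t-1},\ c_t \ge 0}
#' by a single backward-merging pass over "pools" of adjacent samples, the
#' AR(1) generalization of isotonic-regression pool-adjacent-violators.
#' Within a pool the fit decays geometrically at rate `gamma`; a pool whose
#' (truncated) height falls below the decayed height of its predecessor is
#' merged with it, and merging propagates backwards. The per-frame drive
#' (deconvolved increment) is `s_t = c_t - gamma * c_{t-1}`.
#'
#' @param y baseline-subtracted fluorescence series.
#' @param gamma AR(1) decay factor per frame, in (0, 1). The GCaMP6s default
#'   used elsewhere in the package is `exp(-dt / 1.25)`.
#' @return object of class `decon_trace`: list with `inferred` (denoised
#'   nonnegative calcium), `drive` (nonnegative increments), `gamma`, and
#'   `normalized` (`inferred` scaled to max 1, all-zero when silent).
#' @export
deconvolve_pava <- function(y, gamma) {
  stopifnot(is.numeric(y))
  if (!(length(gamma) == 1L && is.finite(gamma) && gamma > 0 && gamma < 1)) {
    stop("gamma must be a single value in (0, 1)")
  }
  n <- length(y)
  if (n == 0L) {
    return(structure(list(inferred = numeric(0), drive = numeric(0),
                          gamma = gamma, normalized = numeric(0)),
                     class = "decon_trace"))
  }
  # pools: value v = sum gamma^j y, weight w = sum gamma^(2j), start t, len l
  v <- numeric(n); w <- numeric(n); tt <- integer(n); l <- integer(n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    v[m] <- y[i]; w[m] <- 1; tt[m] <- i; l[m] <- 1L
    while (m > 1L &&
           max(v[m] / w[m], 0) < gamma^l[m - 1L] * max(v[m - 1L] / w[m - 1L], 0)) {
      g <- gamma^l[m - 1L]
      v[m - 1L] <- v[m - 1L] + g * v[m]
      w[m - 1L] <- w[m - 1L] + g * g * w[m]
      l[m - 1L] <- l[m - 1L] + l[m]
      m <- m - 1L
    }
  }
  inferred <- numeric(n)
  for (p in seq_len(m)) {
    h <- max(v[p] / w[p], 0)
    j <- seq.int(0L, l[p] - 1L)
    inferred[tt[p] + j] <- h * gamma^j
  }
  drive <- c(inferred[1L], inferred[-1L] - gamma * inferred[-n])
  drive[drive < 0 & drive > -1e-9 * max(inferred, 1)] <- 0
  drive <- pmax(drive, 0)
  mx <- max(inferred)
  normalized <- if (mx > 0) inferred / mx else inferred
  structure(list(inferred = inferred, drive = drive, gamma = gamma,
                 normalized = normalized),
            class = "decon_trace")
}

#' Default AR(1) decay factor for a calcium indicator
#'
#' `gamma = exp(-dt / tau_decay)`; the GCaMP6s default uses a 1.25 s decay
#' time constant.
#'
#' @param dt frame interval (s), default 1/30.
#' @param tau_decay indicator decay time constant (s), default 1.25.
#' @export
gcamp_gamma <- function(dt = 1 / 30, tau_decay = 1.25) exp(-dt / tau_decay)

#' Rescale a deconvolved trace to \[0, 1\]
#'
#' @param decon a `decon_trace`.
#' @return numeric series, `inferred / max(inferred)`; all zero for a silent
#'   trace.
#' @export
normalize_trace <- function(decon) {
  stopifnot(inherits(decon, "decon_trace"))
  mx <- max(decon$inferred)
  if (mx > 0) decon$inferred / mx else decon$inferred
}

#' Detect calcium events from a deconvolved trace
#'
#' An event is a maximal run of frames where the inferred calcium exceeds
#' `k * noise_sd` (baseline already removed); runs separated by fewer than
#' `min_gap_frames` sub-threshold frames are merged. Within a run, event
#' onsets come from the deconvolved drive: the run's first burst of positive
#' drive marks the first event (falling back to the first threshold-crossing
#' frame when no drive is positive), and any later drive burst whose peak
#' exceeds `k * noise_sd` splits off a further event. Since a positive
#' increment at frame i means calcium rose during the preceding frame
#' interval, the onset is placed one frame before the burst start. Each
#' event's peak is the maximum of the inferred trace between its onset and
#' the next event (earliest frame on ties); rise time is peak minus onset.
#'
#' @param trace `fluor_trace` with `noise_sd` estimated.
#' @param decon matching `decon_trace`.
#' @param k event threshold in noise SDs, default 3.
#' @param min_gap_frames sub-threshold gap (frames) required to separate two
#'   runs, default 2.
#' @return data.frame with `neuron_id`, `onset_s`, `peak_s`, `rise_s`,
#'   `amplitude`, `peak_over_sigma` (one row per event).
#' @export
detect_events <- function(trace, decon, k = 3, min_gap_frames = 2) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(decon, "decon_trace"))
  if (is.null(trace$noise_sd)) stop("noise_sd missing: run estimate_baseline_noise first")
  times <- trace$frame_times
  inf_ <- decon$inferred
  drv <- decon$drive
  sigma <- trace$noise_sd
  thr <- k * sigma
  empty <- data.frame(neuron_id = trace$neuron_id[0], onset_s = numeric(0),
                      peak_s = numeric(0), rise_s = numeric(0),
                      amplitude = numeric(0), peak_over_sigma = numeric(0))
  above <- inf_ > thr
  if (!any(above)) return(empty)

  # maximal runs, merging runs split by short sub-threshold gaps
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) > 1L) {
    keep <- rep(TRUE, nrow(runs))
    for (i in 2L:nrow(runs)) {
      gap <- runs$start[i] - runs$end[i - 1L] - 1L
      if (gap < min_gap_frames) {
        j <- max(which(keep[seq_len(i - 1L)]))
        runs$end[j] <- runs$end[i]
        keep[i] <- FALSE
      }
    }
    runs <- runs[keep, , drop = FALSE]
  }

  drive_eps <- 1e-3 * sigma
  ev <- list()
  for (ri in seq_len(nrow(runs))) {
    a <- runs$start[ri]; b <- runs$end[ri]
    seg <- a:b
    pos <- drv[seg] > drive_eps
    onsets <- integer(0)
    if (any(pos)) {
      pr <- rle(pos)
      pe <- cumsum(pr$lengths); ps <- pe - pr$lengths + 1L
      bs <- ps[pr$values]; be <- pe[pr$values]
      onsets <- seg[bs[1L]]
      if (length(bs) > 1L) {
        for (bi in 2L:length(bs)) {
          burst <- seg[bs[bi]:be[bi]]
          if (max(drv[burst]) > thr) onsets <- c(onsets, seg[bs[bi]])
        }
      }
    } else {
      onsets <- a  # fallback: first threshold-crossing frame
    }
    # the increment at a burst-start frame reflects a rise during the
    # preceding frame interval
    onsets <- pmax(onsets - 1L, 1L)
    onsets <- onsets[!duplicated(onsets)]
    bounds <- c(onsets, b + 1L)
    for (ei in seq_along(onsets)) {
      span <- onsets[ei]:(bounds[ei + 1L] - 1L)
      pk <- span[which.max(inf_[span])]
      ev[[length(ev) + 1L]] <- data.frame(
        neuron_id = trace$neuron_id,
        onset_s = times[onsets[ei]],
        peak_s = times[pk],
        rise_s = times[pk] - times[onsets[ei]],
        amplitude = inf_[pk],
        peak_over_sigma = inf_[pk] / sigma
      )
    }
  }
  out <- do.call(rbind, ev)
  rownames(out) <- NULL
  out
}

#' Run the full single-neuron calcium pipeline
#'
#' Convenience wrapper: baseline/noise estimation, deconvolution of the
#' baseline-subtracted trace, and event detection.
#'
#' @param trace a `fluor_trace`.
#' @param gamma AR(1) decay per frame; default from [gcamp_gamma()] at the
#'   trace's frame interval.
#' @param k event threshold in noise SDs, default 3.
#' @param ... passed to [estimate_baseline_noise()].
#' @return list with elements `trace` (annotated), `decon`, `events`.
#' @export
process_trace <- function(trace, gamma = NULL, k = 3, ...) {
  trace <- estimate_baseline_noise(trace, ...)
  if (is.null(gamma)) {
    dt <- stats::median(diff(trace$frame_times))
    gamma <- gcamp_gamma(dt)
  }
  decon <- deconvolve_pava(trace$corrected - trace$baseline, gamma)
  events <- detect_events(trace, decon, k = k)
  list(trace = trace, decon = decon, events = events)
}
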