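# Shared fixtures and scoring helpers, built in code at test time.

# Simple syllable table constructor.
syl_tab <- function(onsets, offsets, labels) {
  data.frame(onset_s = onsets, offset_s = offsets, label = labels)
}

# Greedy one-to-one matching of detected event onsets to planted onsets.
# Returns tp/fn/fp counts plus per-match absolute onset errors and detected
# rise times.
match_events <- function(planted, detected, tol = 0.2) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0L; fn <- 0L
  onset_err <- numeric(0); rise <- numeric(0)
  for (tv in planted) {
    j <- which(!used & abs(detected$onset_s - tv) < tol)
    if (length(j)) {
      j <- j[which.min(abs(detected$onset_s[j] - tv))]
      used[j] <- TRUE
      tp <- tp + 1L
      onset_err <- c(onset_err, abs(detected$onset_s[j] - tv))
      rise <- c(rise, detected$rise_s[j])
    } else {
      fn <- fn + 1L
    }
  }
  list(tp = tp, fn = fn, fp = sum(!used), onset_err = onset_err, rise = rise)
}

# Independent brute-force solver for the AR(1) nonnegative deconvolution
# problem, via the innovation parameterization c_t = gamma c_{t-1} + s_t
# with s >= 0 (box-constrained L-BFGS-B). Returns the optimal objective.
pava_oracle_objective <- function(y, gamma) {
  n <- length(y)
  L <- outer(seq_len(n), seq_len(n),
             function(t, j) ifelse(t >= j, gamma^(t - j), 0))
  f <- function(s) sum((y - L %*% s)^2)
  gr <- function(s) as.numeric(-2 * t(L) %*% (y - L %*% s))
  o <- stats::optim(rep(0.1, n), f, gr, method = "L-BFGS-B", lower = 0,
                    control = list(factr = 1e1, maxit = 2000))
  o$value
}

# End-to-end calcium pipeline over a generated dataset: detect events on
# every trace, label them, and summarize per neuron.
run_calcium_pipeline <- function(ds) {
  times <- seq(0, ds$timeline$trial_length, by = 1 / ds$timeline$config$fps)
  mask <- build_epoch_mask(ds$timeline$syllables, times)
  detected <- lapply(ds$traces, function(tr) process_trace(tr)$events)
  labeled <- label_events(do.call(rbind, detected), mask)
  list(mask = mask, detected = detected, labeled = labeled,
       summary = neuron_summary(labeled, neuron_ids = ds$neurons$neuron_id))
}
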