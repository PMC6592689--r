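#!/usr/bin/env Rscript
# Respiratory analysis: segment the pressure recordings of six simulated
# birds (multiple songs each) into cycles, align them to song onset/offset
# markers, and summarize duration, expiratory duty cycle and amplitude per
# epoch and per 1-s bin; repeated-measures ANOVA on the per-bird epoch
# means via the stock aov routine.

library(perisong)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

bird_rows <- list()
cycle_rows <- list()
for (bird in 1:6) {
  per_song <- list()
  for (song in 1:5) {
    s <- seed + bird * 100 + song
    tl <- gen_timeline(synth_config(n_phrases = 1), seed = s)
    pw <- gen_pressure(tl, seed = s)
    cyc <- segment_cycles(pw$pressure, pw$fs)
    mk <- song_markers(cyc, tl$syllables)
    if (!has_quiet_respiration(cyc, mk)) next
    se <- summarize_epochs(cyc, mk)
    cycle_rows[[length(cycle_rows) + 1L]] <-
      cbind(bird = bird, song = song, se$cycles)
    per_song[[length(per_song) + 1L]] <- se$epoch_summary
  }
  es <- do.call(rbind, per_song)
  bird_rows[[bird]] <- aggregate(es[, c("duration_s", "duty_pct", "amplitude")],
                                 by = list(epoch = es$key), FUN = mean)
  bird_rows[[bird]]$bird <- bird
}
bird_tab <- do.call(rbind, bird_rows)
write.csv(bird_tab, "results/resp_bird_epoch_means.csv", row.names = FALSE)
write.csv(do.call(rbind, cycle_rows), "results/resp_cycles.csv",
          row.names = FALSE)

cat("per-bird epoch means (duration s / duty %):\n")
print(aggregate(bird_tab[, c("duration_s", "duty_pct")],
                by = list(epoch = bird_tab$epoch), FUN = mean))

bird_tab$epoch <- factor(bird_tab$epoch, levels = c("pre", "song", "post"))
bird_tab$bird <- factor(bird_tab$bird)
fit <- aov(duration_s ~ epoch + Error(bird / epoch), data = bird_tab)
cat("repeated-measures ANOVA, cycle duration by epoch:\n")
print(summary(fit))
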