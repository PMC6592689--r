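#!/usr/bin/env Rscript
# Generate the synthetic study dataset: a day of directed singing (six song
# phrases), a 120-neuron population (40 peri-song / 40 pan-song / 40 song),
# per-neuron fluorescence traces, a multiunit spike train, single-unit
# trains, and an air-sac pressure recording. Ground truth is written
# alongside so the downstream analyses can be scored.

library(perisong)

seed <- 20260921L
dir.create("results", showWarnings = FALSE)

cfg <- synth_config(n_phrases = 6)
ds <- gen_calcium_dataset(c(peri_song = 40, pan_song = 40, song = 40),
                          cfg, seed = seed)
tl <- ds$timeline

write.csv(tl$syllables, "results/annotations.csv", row.names = FALSE)
write.csv(tl$phrases, "results/true_phrases.csv", row.names = FALSE)
write.csv(ds$events, "results/true_events.csv", row.names = FALSE)
write.csv(ds$neurons, "results/true_neurons.csv", row.names = FALSE)

pw <- gen_pressure(tl, cfg, seed = seed)
write.csv(pw$cycles, "results/true_cycles.csv", row.names = FALSE)
write.csv(pw$markers, "results/true_markers.csv", row.names = FALSE)

cat(sprintf("timeline: %.0f s, %d phrases, %d bouts, %d motifs, %d syllables\n",
            tl$trial_length, nrow(tl$phrases), nrow(tl$bouts),
            nrow(tl$motifs), nrow(tl$syllables)))
cat(sprintf("planted calcium events: %d across %d neurons\n",
            nrow(ds$events), nrow(ds$neurons)))
cat(sprintf("respiration: %d cycles (%d song-state)\n",
            nrow(pw$cycles), sum(pw$cycles$state == "song")))
cat("wrote ground truth under results/\n")
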