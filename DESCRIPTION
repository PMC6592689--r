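Package: perisong
Title: Song and Peri-Song Neural Activity Analysis for Songbird Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for detecting and classifying song-related versus
    peri-song neural activity in songbirds. Builds behavioral timelines (bouts,
    phrases, epoch masks) from syllable annotations; extracts, baseline-corrects
    and deconvolves single-neuron calcium fluorescence traces with a
    pool-adjacent-violators AR(1) solver and detects calcium events; computes
    per-neuron phrase indices, neuron classes, peri-event rate traces and
    song-onset prediction latencies; analyzes multiunit spike-rate onset
    latencies and single-unit inter-spike-interval variability across
    behavioral epochs; segments air-sac pressure recordings into respiratory
    cycles with duration, duty cycle and amplitude summaries; and generates
    ground-truth-annotated synthetic datasets reproducing the statistical
    structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
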