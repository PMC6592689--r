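test_that("phrase assembly follows the strict 2-s silence rule", {
  # two bouts with a 1.5 s gap: one phrase
  s <- syl_tab(c(0, 2.5), c(1, 3.5), c("syl_a", "syl_a"))
  ph <- assemble_phrases(s)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$onset_s, 0)
  expect_equal(ph$offset_s, 3.5)

  # 2.5 s gap: two phrases
  s <- syl_tab(c(0, 3.5), c(1, 4.5), c("syl_a", "syl_a"))
  expect_equal(nrow(assemble_phrases(s)), 2L)

  # exactly 2.0 s is not "less than 2 s": two phrases
  s <- syl_tab(c(0, 3.0), c(1, 4.0), c("syl_a", "syl_a"))
  expect_equal(nrow(assemble_phrases(s)), 2L)
})

test_that("calls and noise never seed a phrase; intros set the phrase onset", {
  s <- syl_tab(c(0.5, 3, 3.2, 9),
               c(0.7, 3.1, 3.8, 9.4),
               c("call", "intro", "syl_a", "noise"))
  ph <- assemble_phrases(s)
  expect_equal(nrow(ph), 1L)
  expect_equal(ph$onset_s, 3)   # intro note onset, not the call
  expect_equal(ph$offset_s, 3.8)

  expect_equal(nrow(assemble_phrases(syl_tab(c(1), c(2), c("call")))), 0L)
})

test_that("unsorted or overlapping annotations are rejected", {
  expect_error(assemble_phrases(syl_tab(c(2, 0), c(3, 1), c("syl_a", "syl_a"))),
               "sorted")
  expect_error(assemble_phrases(syl_tab(c(0, 0.5), c(1, 1.5), c("syl_a", "syl_a"))),
               "overlap")
  expect_error(assemble_phrases(syl_tab(c(1), c(1), c("syl_a"))), "onset")
})

test_that("phrase assembly is idempotent and monotone in the gap threshold", {
  set.seed(11)
  for (rep in 1:5) {
    tl <- gen_timeline(seed = rep)
    ph <- assemble_phrases(tl$syllables)
    again <- assemble_phrases(
      data.frame(onset_s = ph$onset_s, offset_s = ph$offset_s,
                 label = "syl_a"))
    expect_equal(again$onset_s, ph$onset_s)
    expect_equal(again$offset_s, ph$offset_s)

    n_phr <- vapply(c(3, 2, 1, 0.5),
                    function(g) nrow(assemble_phrases(tl$syllables, g)), 1L)
    expect_true(all(diff(n_phr) >= 0))
  }
})

test_that("epoch mask partitions a single-phrase trial as expected", {
  # phrase [10, 13] in a 30 s trial, no calls
  s <- syl_tab(c(10, 11, 12.5), c(10.5, 11.5, 13), rep("syl_a", 3))
  times <- seq(0, 30, by = 0.1)
  mask <- build_epoch_mask(s, times)
  lab <- function(t) as.character(mask$label[which.min(abs(mask$time_s - t))])
  expect_equal(lab(7.0), "peri_pre")    # within [5, 10)
  expect_equal(lab(10.2), "song")
  expect_equal(lab(11.7), "peri_gap")   # between bouts inside the phrase
  expect_equal(lab(15.0), "peri_post")  # within [13, 18)
  expect_equal(lab(29.0), "baseline")   # >= 10 s from song (23+)
  expect_equal(lab(19.0), "other")
  # every point gets exactly one label
  expect_false(anyNA(mask$label))
})

test_that("calls reset the baseline exclusion clock but keep peri labels", {
  s <- syl_tab(c(10, 20), c(11, 20.2), c("syl_a", "call"))
  times <- seq(0, 40, by = 0.1)
  mask <- build_epoch_mask(s, times)
  # no baseline anywhere in [10, 30]: call at 20 excludes [10, 30.2)
  mid <- mask$time_s >= 10 & mask$time_s <= 30
  expect_false(any(mask$label[mid] == "baseline"))
  # the call at +9 s past the phrase is outside peri windows -> other
  expect_equal(as.character(mask$label[which.min(abs(mask$time_s - 20.1))]),
               "other")
  # a call inside the peri window keeps the peri label
  s2 <- syl_tab(c(10, 13), c(11, 13.2), c("syl_a", "call"))
  mask2 <- build_epoch_mask(s2, times)
  expect_equal(as.character(mask2$label[which.min(abs(mask2$time_s - 13.1))]),
               "peri_post")
})

test_that("colliding peri windows split at the inter-phrase midpoint", {
  # two phrases 6 s apart: post of 1 and pre of 2 overlap, split at midpoint
  s <- syl_tab(c(10, 17), c(11, 18), c("syl_a", "syl_a"))
  times <- seq(0, 30, by = 0.05)
  mask <- build_epoch_mask(s, times)
  lab <- function(t) as.character(mask$label[which.min(abs(mask$time_s - t))])
  expect_equal(lab(13.5), "peri_post")  # before midpoint 14
  expect_equal(lab(14.5), "peri_pre")   # after midpoint
  # enumerate: no gaps or double labels around the boundary
  sel <- mask$time_s > 11 & mask$time_s < 17
  expect_true(all(mask$label[sel] %in% c("peri_post", "peri_pre")))
  expect_equal(mask$phrase_idx[which.min(abs(mask$time_s - 13.5))], 1L)
  expect_equal(mask$phrase_idx[which.min(abs(mask$time_s - 14.5))], 2L)
})

test_that("rejects a non-monotone sample grid", {
  s <- syl_tab(10, 11, "syl_a")
  expect_error(build_epoch_mask(s, c(0, 1, 0.5)), "increasing")
})

test_that("pre/post eligibility enforces the 5-s silence rule", {
  # isolated phrase with 8 s of silence on both sides
  s <- syl_tab(10, 11, "syl_a")
  ph <- assemble_phrases(s)
  e <- phrase_eligibility(ph, s, trial_start = 0, trial_end = 30)
  expect_true(e$pre_eligible && e$post_eligible)

  # phrase starting 3 s after the previous ends: pre-ineligible
  s <- syl_tab(c(10, 14), c(11, 15), c("syl_a", "syl_a"))
  ph <- assemble_phrases(s)
  e <- phrase_eligibility(ph, s)
  expect_false(e$pre_eligible[2])
  expect_false(e$post_eligible[1])
  expect_true(e$pre_eligible[1])

  # a call 2 s after the phrase makes it post-ineligible
  s <- syl_tab(c(10, 13), c(11, 13.1), c("syl_a", "call"))
  ph <- assemble_phrases(s)
  expect_false(phrase_eligibility(ph, s)$post_eligible)

  # phrase too close to trial start: truncated and ineligible
  s <- syl_tab(2, 3, "syl_a")
  ph <- assemble_phrases(s)
  e <- phrase_eligibility(ph, s, trial_start = 0)
  expect_false(e$pre_eligible)
  expect_true(e$pre_truncated)
})

test_that("generated timelines round-trip through phrase assembly exactly", {
  for (seed in 1:20) {
    tl <- gen_timeline(seed = seed)
    ph <- assemble_phrases(tl$syllables)
    expect_equal(ph$onset_s, tl$phrases$onset_s)
    expect_equal(ph$offset_s, tl$phrases$offset_s)
  }
})

test_that("epoch masks serialize to run-length tables covering the grid", {
  tl <- gen_timeline(seed = 4)
  times <- seq(0, tl$trial_length, by = 1 / 30)
  mask <- build_epoch_mask(tl$syllables, times)
  r <- epoch_rle(mask)
  expect_equal(sum(r$n_samples), length(times))
  expect_true(all(r$end_s[-nrow(r)] - r$start_s[-1] < 1e-9))
})

test_that("annotation reader round-trips csv and tsv and validates", {
  tl <- gen_timeline(seed = 2)
  f1 <- tempfile(fileext = ".csv")
  utils::write.csv(tl$syllables, f1, row.names = FALSE)
  expect_equal(read_annotations(f1)$onset_s, tl$syllables$onset_s)
  f2 <- tempfile(fileext = ".tsv")
  utils::write.table(tl$syllables, f2, sep = "\t", row.names = FALSE)
  expect_equal(read_annotations(f2)$label, tl$syllables$label)
  bad <- tl$syllables[rev(seq_len(nrow(tl$syllables))), ]
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f3, row.names = FALSE)
  expect_error(read_annotations(f3), "sorted")
})
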