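test_that("zero-phase FIR band-pass attenuates out-of-band tones and passes in-band ones", {
  fs <- 125
  t <- (0:2499) / fs
  mid <- 500:2000  # steady-state region away from edge transients
  f_lo <- fir_filter(sin(2 * pi * 0.1 * t), fs)
  f_in <- fir_filter(sin(2 * pi * 10 * t), fs)
  expect_lt(max(abs(f_lo[mid])), 0.10)
  expect_gt(max(abs(f_in[mid])), 0.90)
  expect_equal(length(f_lo), length(t))
  expect_true(all(fir_filter(numeric(2000), fs) == 0))
  expect_error(fir_filter(sin(t), fs = 60), "Nyquist")
  expect_error(fir_filter(numeric(100), fs), "longer")
})

test_that("quality check passes clean records and fails flat or noisy ones", {
  r <- cohort_records(clean_cohort())[[1]]
  filt <- fir_filter(r$signal, r$fs)
  expect_true(quality_check(filt, r$fs)$pass)

  flat <- quality_check(rep(0.7, 1250), r$fs)
  expect_false(flat$pass)
  expect_equal(flat$reason, "flat")

  set.seed(8)
  noisy <- filt + stats::rnorm(length(filt), 0, 5 * stats::sd(filt))
  expect_false(quality_check(noisy, r$fs)$pass)
})

test_that("R-peak detection finds the generator's beats to within 2 samples", {
  # 60 bpm for 10 s: expect 10 +- 1 peaks at the true R locations
  tpl <- beat_template(rr_mean = 1.0, rr_cv = 0)
  co <- clean_cohort(n_subjects = 1, duration_s = 10, template = tpl, seed = 13)
  r <- cohort_records(co)[[1]]
  filt <- fir_filter(r$signal, r$fs)
  rp <- detect_rpeaks(filt, r$fs)
  expect_true(abs(length(rp) - 10) <= 1)
  truth <- r$rpeaks_true[seq_along(rp)]
  expect_true(all(abs(rp - truth) <= 2))

  expect_identical(detect_rpeaks(rep(0, 1250), 125), integer(0))
  expect_error(detect_rpeaks(numeric(50), 125), "short")
})

test_that("a single padded beat yields exactly one peak at the known R sample", {
  tpl <- beat_template()
  beat <- render_beat(tpl, 0, rr = 0.8, fs = 125)
  pad <- numeric(125)
  x <- c(pad, as.numeric(beat), pad)
  rp <- detect_rpeaks(x, 125)
  expect_length(rp, 1L)
  expect_lte(abs(rp - (125 + attr(beat, "r_index"))), 2)
})

test_that("detector recall and precision reach 0.99 on noiseless cohorts", {
  co <- clean_cohort(n_subjects = 3, records_per_class = 2, duration_s = 20, seed = 31)
  tp <- fp <- fn <- 0
  for (r in cohort_records(co)) {
    rp <- detect_rpeaks(fir_filter(r$signal, r$fs), r$fs)
    hits <- outer(rp, r$rpeaks_true, function(a, b) abs(a - b) <= 2)
    tp <- tp + sum(apply(hits, 2, any))
    fn <- fn + sum(!apply(hits, 2, any))
    fp <- fp + sum(!apply(hits, 1, any))
  }
  expect_gte(tp / (tp + fn), 0.99)
  expect_gte(tp / (tp + fp), 0.99)
})

test_that("segmentation emits 120-sample beats with the R peak at position 41", {
  x <- sin(seq(0, 40, length.out = 1000))
  rp <- c(100L, 500L, 950L)
  beats <- segment_beats(x, rp)
  expect_equal(nrow(beats), 2L)   # 950 + 80 > 1000 is dropped
  expect_equal(ncol(beats), 120L)
  expect_equal(beat_fiducial(), 41L)
  # the fiducial sample is the R sample itself
  expect_equal(beats[1, 41], x[100])
  expect_equal(beats[2, 41], x[500])
  # insufficient pre-samples
  expect_equal(nrow(segment_beats(x, 10L)), 0L)
  expect_error(segment_beats(x, c(5L, 5L)), "ascending")
  # beats never outnumber peaks
  expect_lte(nrow(beats), length(rp))
})

test_that("potassium labelling partitions values exactly as defined", {
  expect_equal(label_potassium(6.3), "hyper")
  expect_equal(label_potassium(4.3), "normo")
  expect_equal(label_potassium(5.2), "excluded")
  # boundary rules: 5.0 is normokalemia, 5.5 still excluded ('above 5.5' is strict)
  expect_equal(label_potassium(c(5.0, 5.5, 3.5, 3.4)),
               c("normo", "excluded", "normo", "excluded"))
  # exactly one label per value across a fine grid
  k <- seq(1, 9, by = 0.01)
  lab <- label_potassium(k)
  expect_true(all(lab %in% c("hyper", "normo", "excluded")))
  expect_error(label_potassium(0), "positive")
})

test_that("excerpt extraction takes the 10 minutes before the draw", {
  fs <- 125
  x <- seq_len(20 * 60 * fs)  # 20-minute ramp so indices are readable
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  ex <- extract_excerpt(x, fs, t0, t0 + 15 * 60)
  expect_length(ex, 600 * fs)
  expect_false(attr(ex, "short_window"))
  expect_equal(ex[length(ex)], x[15 * 60 * fs])
  expect_equal(ex[1], x[15 * 60 * fs - 600 * fs + 1])

  expect_error(extract_excerpt(x, fs, t0, t0 - 60), "overlap")

  y <- seq_len(8 * 60 * fs)
  ex8 <- extract_excerpt(y, fs, t0, t0 + 8 * 60)
  expect_length(ex8, 8 * 60 * fs)
  expect_true(attr(ex8, "short_window"))
})

test_that("process_record excludes mid-band potassium and failed QC", {
  co <- clean_cohort(n_subjects = 1, records_per_class = 1, duration_s = 10)
  r <- cohort_records(co)[[1]]
  p <- process_record(r)
  expect_gt(nrow(p$beats), 0)
  expect_true(all(abs(p$rpeaks[seq_len(min(3, length(p$rpeaks)))] -
                        r$rpeaks_true[seq_len(min(3, length(p$rpeaks)))]) <= 2))
  r$potassium <- 5.2
  p2 <- process_record(r)
  expect_equal(p2$label, "excluded")
  expect_equal(nrow(p2$beats), 0L)
})
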