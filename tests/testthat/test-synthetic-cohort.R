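test_that("severity map is piecewise linear with the stated anchors", {
  expect_equal(severity_score(4.3), 0)
  expect_equal(severity_score(7.5), 1)
  expect_equal(severity_score(6.0), 0.5)
  expect_equal(severity_score(5.0), 0)
  expect_equal(severity_score(7.0), 1)
  # monotone non-decreasing over a grid
  k <- seq(0.5, 9, by = 0.1)
  expect_true(all(diff(severity_score(k)) >= 0))
  expect_error(severity_score(-1), "positive")
  expect_error(severity_score(0), "positive")
})

test_that("render_beat applies severity effects in the stated directions", {
  tpl <- beat_template()
  b0 <- render_beat(tpl, severity = 0, rr = 0.8, fs = 125)
  expect_identical(b0, render_beat(tpl, rr = 0.8, fs = 125))  # severity-0 identity
  expect_equal(length(b0), round(0.8 * 125))

  co <- severity_coefs(t_gain = 0.8)
  b1 <- render_beat(tpl, severity = 1, rr = 0.8, fs = 125, coefs = co)
  # T-peak amplitude scales by 1 + t_gain at full severity (within 1%)
  tw <- round(tpl$centers[["T"]] * 0.8 * 125) + (-8:8)
  expect_equal(max(b1[tw]) / max(b0[tw]), 1.8, tolerance = 0.01)

  zero <- beat_template(amplitudes = c(P = 0, Q = 0, R = 0, S = 0, T = 0))
  expect_true(all(render_beat(zero, 0.5, 0.8, 125) == 0))

  expect_error(render_beat(tpl, 0, rr = 0.1, fs = 125), "20 samples")
  expect_error(render_beat(tpl, 1.5, 0.8, 125), "severity")
})

test_that("template invariants are enforced", {
  expect_error(beat_template(widths = c(P = 0, Q = .01, R = .01, S = .01, T = .06)),
               "positive")
  expect_error(beat_template(centers = c(P = 0.5, Q = 0.36, R = 0.4, S = 0.44, T = 0.72)),
               "ordered")
  expect_error(beat_template(rr_mean = 3), "rr_mean")
})

test_that("cohorts are seeded-deterministic with the configured counts and bands", {
  cfg <- cohort_config(n_subjects = 16, records_per_class = 8, duration_s = 5,
                       seed = 9)
  co1 <- generate_cohort(cfg)
  co2 <- generate_cohort(cfg)
  recs <- cohort_records(co1)
  expect_length(recs, 16 * 2 * 8)
  expect_identical(lapply(cohort_records(co1), `[[`, "signal"),
                   lapply(cohort_records(co2), `[[`, "signal"))
  k <- vapply(recs, `[[`, numeric(1), "potassium")
  lab <- label_potassium(k)
  expect_true(all(lab %in% c("hyper", "normo")))
  expect_true(all(k[lab == "normo"] >= 3.5 & k[lab == "normo"] <= 5.0))
  expect_true(all(k[lab == "hyper"] > 5.5 & k[lab == "hyper"] <= 8.0))
  # every subject has the configured records per class
  sid <- vapply(recs, `[[`, character(1), "subject_id")
  expect_true(all(table(sid, lab) == 8))
})

test_that("degenerate randomness: one subject, no noise/spread gives identical beats", {
  tpl <- beat_template(rr_cv = 0)
  cfg <- cohort_config(n_subjects = 1, records_per_class = 1, duration_s = 5,
                       subject_spread = 0, noise_sd = 0, wander_amp = 0,
                       template = tpl, seed = 3)
  r <- cohort_records(generate_cohort(cfg))[[1]]
  # normokalemic record: all full beats are bitwise identical
  stopifnot(label_potassium(r$potassium) == "normo")
  n_beat <- round(tpl$rr_mean * cfg$fs)
  full <- floor(length(r$signal) / n_beat)
  beats <- matrix(r$signal[seq_len(full * n_beat)], nrow = full, byrow = TRUE)
  for (i in seq_len(full - 1))
    expect_identical(beats[i, ], beats[i + 1, ])
})

test_that("separability knob: noiseless spread-0 cohorts order T peaks by class", {
  co <- clean_cohort(n_subjects = 3, records_per_class = 2, duration_s = 8,
                     seed = 11, wander_amp = 0)
  tpl_c <- attr(co, "config")$template
  for (subj in co) {
    tpeak <- function(rec) {
      off <- round((tpl_c$centers[["T"]] - tpl_c$centers[["R"]]) *
                     subj$profile$template$rr_mean * rec$fs)
      peaks <- rec$rpeaks_true
      peaks <- peaks[peaks + off + 5 <= length(rec$signal)]
      mean(vapply(peaks, function(p) max(rec$signal[p + off + (-5:5)]), numeric(1)))
    }
    labs <- vapply(subj$records, function(r) label_potassium(r$potassium), character(1))
    tp <- vapply(subj$records, tpeak, numeric(1))
    expect_gt(mean(tp[labs == "hyper"]), mean(tp[labs == "normo"]))
  }
})

test_that("heterogeneity knob: large subject spread dominates within-subject variance", {
  cfg <- cohort_config(n_subjects = 10, records_per_class = 4, duration_s = 6,
                       subject_spread = 0.8, seed = 21)
  co <- generate_cohort(cfg)
  per_subject <- lapply(co, function(subj) {
    labs <- vapply(subj$records, function(r) label_potassium(r$potassium), character(1))
    vapply(subj$records[labs == "normo"], function(r) {
      mean(vapply(r$rpeaks_true[r$rpeaks_true + 40 <= length(r$signal)],
                  function(p) max(r$signal[p + 20:40]), numeric(1)))
    }, numeric(1))
  })
  between <- stats::var(vapply(per_subject, mean, numeric(1)))
  within <- mean(vapply(per_subject, stats::var, numeric(1)))
  expect_gt(between, within)
})

test_that("subject sub-seeds are stable under cohort growth", {
  small <- generate_cohort(cohort_config(n_subjects = 2, records_per_class = 1,
                                         duration_s = 4, seed = 5))
  big <- generate_cohort(cohort_config(n_subjects = 4, records_per_class = 1,
                                       duration_s = 4, seed = 5))
  expect_identical(small[[1]]$records[[1]]$signal, big[[1]]$records[[1]]$signal)
  expect_identical(small[[2]]$records[[1]]$signal, big[[2]]$records[[1]]$signal)
})
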