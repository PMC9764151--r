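# Synthetic single-lead ECG cohorts with potassium-dependent morphology.
#
# Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) on an RR-long
# grid; hyperkalemia severity reshapes the bumps in the clinically expected
# directions (peaked/narrow T, wide QRS, flat P, long PR). Subjects carry
# multiplicative log-normal random effects on amplitudes and widths, which
# is the intersubject heterogeneity the personalization method targets.

#' Beat morphology template
#'
#' Describes one subject's archetypal heartbeat as five Gaussian bumps.
#' Amplitudes are in mV, centers are fractions of the RR interval in (0,1),
#' widths are in seconds. Defaults sketch a lead II beat at 75 bpm.
#'
#' @param amplitudes Named numeric vector (P, Q, R, S, T), mV.
#' @param centers Named numeric vector (P, Q, R, S, T), fractions of RR,
#'   strictly increasing.
#' @param widths Named numeric vector (P, Q, R, S, T), seconds, all positive.
#' @param rr_mean Mean RR interval in seconds, in `[0.4, 2]`.
#' @param rr_cv Coefficient of variation of the RR interval.
#' @return An object of class `beat_template`.
#' @export
beat_template <- function(amplitudes = c(P = 0.15, Q = -0.10, R = 1.00, S = -0.15, T = 0.30),
                          centers = c(P = 0.18, Q = 0.36, R = 0.40, S = 0.44, T = 0.72),
                          widths = c(P = 0.025, Q = 0.010, R = 0.012, S = 0.010, T = 0.060),
                          rr_mean = 0.8, rr_cv = 0.05) {
  waves <- c("P", "Q", "R", "S", "T")
  amplitudes <- amplitudes[waves]; centers <- centers[waves]; widths <- widths[waves]
  if (anyNA(amplitudes) || anyNA(centers) || anyNA(widths))
    stop("amplitudes, centers and widths must each name all of P, Q, R, S, T")
  if (any(widths <= 0)) stop("wave widths must be positive")
  if (any(diff(centers) <= 0)) stop("wave centers must be strictly ordered P < Q < R < S < T")
  if (any(centers <= 0) || any(centers >= 1)) stop("wave centers must lie in (0, 1)")
  if (rr_mean < 0.4 || rr_mean > 2.0) stop("rr_mean must lie in [0.4, 2.0] seconds")
  if (rr_cv < 0) stop("rr_cv must be non-negative")
  structure(list(amplitudes = amplitudes, centers = centers, widths = widths,
                 rr_mean = rr_mean, rr_cv = rr_cv),
            class = "beat_template")
}

#' Severity-response coefficients
#'
#' Dimensionless gains that convert a severity score in `[0, 1]` into
#' morphology change: T amplitude grows by `t_gain`, T width shrinks by
#' `t_shrink`, QRS widths grow by `qrs_widen`, P amplitude falls by
#' `p_loss`, and the P-to-R spacing grows by `pr_lengthen` (all relative,
#' at severity 1).
#'
#' @param t_gain,t_shrink,qrs_widen,p_loss,pr_lengthen Non-negative scalars.
#' @return Named list of coefficients.
#' @export
severity_coefs <- function(t_gain = 0.8, t_shrink = 0.3, qrs_widen = 0.5,
                           p_loss = 0.5, pr_lengthen = 0.3) {
  co <- list(t_gain = t_gain, t_shrink = t_shrink, qrs_widen = qrs_widen,
             p_loss = p_loss, pr_lengthen = pr_lengthen)
  if (any(unlist(co) < 0)) stop("severity coefficients must be non-negative")
  if (t_shrink >= 1 || p_loss > 1) stop("t_shrink must be < 1 and p_loss <= 1")
  co
}

#' Map serum potassium to a morphology severity score
#'
#' Piecewise-linear dose-response: 0 at or below 5.0 mEq/L, 1 at or above
#' 7.0 mEq/L, linear in between. The map is a modelling choice (no
#' quantitative ECG-vs-potassium dose-response is established); only its
#' monotone direction is clinically anchored.
#'
#' @param potassium Serum potassium in mEq/L (positive).
#' @return Severity score in `[0, 1]`, same length as `potassium`.
#' @export
severity_score <- function(potassium) {
  if (!is.numeric(potassium) || any(!is.finite(potassium)) || any(potassium <= 0))
    stop("potassium must be positive and finite (mEq/L)")
  pmin(1, pmax(0, (potassium - 5.0) / 2.0))
}

#' Render one heartbeat
#'
#' Evaluates the five-Gaussian template on an `fs`-spaced grid of
#' `round(rr * fs)` samples, applying severity-dependent morphology:
#' at severity `s` the T amplitude is scaled by `1 + t_gain * s`, the T
#' width by `1 - t_shrink * s`, the Q/R/S widths by `1 + qrs_widen * s`,
#' the P amplitude by `1 - p_loss * s`, and the P-to-R spacing by
#' `1 + pr_lengthen * s`. Severity 0 reproduces the template exactly.
#'
#' @param template A [beat_template()].
#' @param severity Severity score in `[0, 1]`.
#' @param rr RR interval for this beat, seconds.
#' @param fs Sampling frequency, Hz.
#' @param coefs Severity-response coefficients, see [severity_coefs()].
#' @return Numeric vector of `round(rr * fs)` samples (mV), with attribute
#'   `r_index` giving the 1-based sample index of the R-wave center.
#' @export
render_beat <- function(template, severity = 0, rr = template$rr_mean,
                        fs = 125, coefs = severity_coefs()) {
  stopifnot(inherits(template, "beat_template"))
  if (length(severity) != 1 || !is.finite(severity) || severity < 0 || severity > 1)
    stop("severity must be a scalar in [0, 1]")
  n <- round(rr * fs)
  if (n < 20) stop("rr * fs must give at least 20 samples")
  a <- template$amplitudes; ce <- template$centers; w <- template$widths
  s <- severity
  a[["T"]] <- a[["T"]] * (1 + coefs$t_gain * s)
  w[["T"]] <- w[["T"]] * (1 - coefs$t_shrink * s)
  w[c("Q", "R", "S")] <- w[c("Q", "R", "S")] * (1 + coefs$qrs_widen * s)
  a[["P"]] <- a[["P"]] * (1 - coefs$p_loss * s)
  # PR lengthening: R is the fiducial, so the P center moves earlier
  ce[["P"]] <- max(0.02, ce[["R"]] - (ce[["R"]] - ce[["P"]]) * (1 + coefs$pr_lengthen * s))
  t <- (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (wv in c("P", "Q", "R", "S", "T"))
    y <- y + a[[wv]] * exp(-((t - ce[[wv]] * rr)^2) / (2 * w[[wv]]^2))
  attr(y, "r_index") <- round(ce[["R"]] * rr * fs) + 1L
  y
}

#' Cohort generation configuration
#'
#' Defaults mirror the study's data structure: ten-minute single-lead
#' records sampled at 125 Hz, class potassium distributions centered on the
#' reported cohort means (normokalemia 4.3 (SD 0.40), hyperkalemia
#' 6.3 (SD 0.64) mEq/L), truncated to the label bands (normo `[3.5, 5.0]`,
#' hyper `(5.5, 8.0]`), and strong multiplicative intersubject
#' heterogeneity (`subject_spread` = 1 on the log scale, dominated by a
#' shared per-subject voltage scale).
#'
#' @param n_subjects Number of subjects.
#' @param records_per_class Records per subject per class.
#' @param duration_s Record duration in seconds.
#' @param fs Sampling frequency in Hz; `duration_s * fs` must be an integer.
#' @param subject_spread SD of the log-normal subject random effects on
#'   template amplitudes and widths (0 disables heterogeneity).
#' @param k_normo_mean,k_normo_sd,k_hyper_mean,k_hyper_sd Class potassium
#'   distributions (mEq/L) before band truncation.
#' @param noise_sd Additive white noise SD, mV.
#' @param wander_amp,wander_freq Baseline wander sinusoid amplitude (mV)
#'   and frequency (Hz).
#' @param template Population-level [beat_template()].
#' @param coefs Population-level [severity_coefs()].
#' @param seed Master seed (integer).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 16, records_per_class = 8,
                          duration_s = 600, fs = 125,
                          subject_spread = 1.0,
                          k_normo_mean = 4.3, k_normo_sd = 0.40,
                          k_hyper_mean = 6.3, k_hyper_sd = 0.64,
                          noise_sd = 0.02, wander_amp = 0.05, wander_freq = 0.3,
                          template = beat_template(), coefs = severity_coefs(),
                          seed = 1L) {
  if (n_subjects < 1 || records_per_class < 1) stop("need at least one subject and one record per class")
  if (fs <= 0) stop("fs must be positive")
  n_samp <- duration_s * fs
  if (abs(n_samp - round(n_samp)) > 1e-9) stop("duration_s * fs must be an integer sample count")
  if (subject_spread < 0 || noise_sd < 0 || wander_amp < 0) stop("spread/noise/wander must be non-negative")
  if (k_normo_mean < 3.5 || k_normo_mean > 5.0) stop("k_normo_mean must lie inside the normokalemia band [3.5, 5.0]")
  if (k_hyper_mean <= 5.5 || k_hyper_mean > 8.0) stop("k_hyper_mean must lie inside the hyperkalemia band (5.5, 8.0]")
  structure(list(n_subjects = as.integer(n_subjects),
                 records_per_class = as.integer(records_per_class),
                 duration_s = duration_s, fs = fs,
                 subject_spread = subject_spread,
                 k_normo_mean = k_normo_mean, k_normo_sd = k_normo_sd,
                 k_hyper_mean = k_hyper_mean, k_hyper_sd = k_hyper_sd,
                 noise_sd = noise_sd, wander_amp = wander_amp, wander_freq = wander_freq,
                 template = template, coefs = coefs, seed = as.integer(seed)),
            class = "cohort_config")
}

# Deterministic per-subject sub-seed: master and subject index mixed through
# a fixed affine map mod 2^31 - 1, so cohorts are reproducible and a
# subject's stream does not move when the cohort grows.
subject_seed <- function(master, i) {
  as.integer((as.double(master) + 1000003 * as.double(i)) %% 2147483647)
}

# Truncated-normal draw via inverse CDF; deterministic given the RNG state.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Subject random effects: a shared log-normal voltage scale (electrode
# placement, body habitus) plus smaller per-wave log-normal variation on
# amplitudes, log-normal variation on widths, small additive shifts on
# centers (redrawn until ordering holds), and mild variation of the
# severity coefficients.
draw_subject_profile <- function(config, subject_id) {
  tpl <- config$template
  sp <- config$subject_spread
  scale <- exp(stats::rnorm(1, 0, sp))
  amp <- tpl$amplitudes * scale * exp(stats::rnorm(5, 0, sp * 0.3))
  wid <- tpl$widths * exp(stats::rnorm(5, 0, sp * 0.5))
  for (try in seq_len(100)) {
    cen <- tpl$centers + stats::rnorm(5, 0, sp * 0.02)
    cen[["R"]] <- tpl$centers[["R"]]  # R stays the fiducial anchor
    if (all(diff(cen) > 0) && all(cen > 0) && all(cen < 1)) break
    if (try == 100) cen <- tpl$centers
  }
  rr_mean <- min(2.0, max(0.4, tpl$rr_mean * exp(stats::rnorm(1, 0, sp * 0.2))))
  co <- config$coefs
  cs <- lapply(co, function(x) x * exp(stats::rnorm(1, 0, sp * 0.3)))
  cs$t_shrink <- min(cs$t_shrink, 0.9); cs$p_loss <- min(cs$p_loss, 1)
  list(subject_id = subject_id,
       template = beat_template(amp, cen, wid, rr_mean = rr_mean, rr_cv = tpl$rr_cv),
       coefs = do.call(severity_coefs, cs),
       noise_sd = config$noise_sd,
       wander_amp = config$wander_amp,
       wander_freq = config$wander_freq)
}

# One record: concatenated beats with RR jitter + baseline wander + noise.
synthesize_record <- function(profile, severity, config, record_id, potassium, draw_time) {
  fs <- config$fs
  n_target <- round(config$duration_s * fs)
  tpl <- profile$template
  sig <- numeric(0); rpeaks <- integer(0); offset <- 0L
  while (offset < n_target) {
    rr <- tpl$rr_mean
    if (tpl$rr_cv > 0)
      rr <- max(0.4 * tpl$rr_mean, stats::rnorm(1, tpl$rr_mean, tpl$rr_cv * tpl$rr_mean))
    beat <- render_beat(tpl, severity = severity, rr = rr, fs = fs, coefs = profile$coefs)
    r_at <- offset + attr(beat, "r_index")
    sig <- c(sig, as.numeric(beat))
    if (r_at <= n_target) rpeaks <- c(rpeaks, r_at)
    offset <- offset + length(beat)
  }
  sig <- sig[seq_len(n_target)]
  if (profile$wander_amp > 0) {
    phase <- stats::runif(1, 0, 2 * pi)
    sig <- sig + profile$wander_amp *
      sin(2 * pi * profile$wander_freq * (seq_len(n_target) - 1) / fs + phase)
  }
  if (profile$noise_sd > 0) sig <- sig + stats::rnorm(n_target, 0, profile$noise_sd)
  structure(list(record_id = record_id, subject_id = profile$subject_id,
                 signal = sig, fs = fs, potassium = potassium,
                 draw_time = draw_time,
                 start_time = draw_time - config$duration_s,
                 rpeaks_true = rpeaks),
            class = "ecg_record")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject morphology profiles and, for each subject,
#' `records_per_class` normokalemic and hyperkalemic records. Potassium is
#' drawn from the class distribution truncated to the label band
#' (normokalemia `[3.5, 5.0]`, hyperkalemia `(5.5, 8.0]`). Fully
#' deterministic given the config's master seed: each subject uses a
#' sub-seed derived from the master seed and the subject index, so the same
#' subject reproduces bitwise across runs and cohort sizes.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ecg_cohort`: one element per subject, each with
#'   `profile` and `records` (list of `ecg_record`, carrying ground-truth
#'   R-peak indices in `rpeaks_true`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  t0 <- as.POSIXct("2020-01-01 08:00:00", tz = "UTC")
  cohort <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    sid <- sprintf("S%03d", i)
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(subject_seed(config$seed, i))
    profile <- draw_subject_profile(config, sid)
    n_rec <- config$records_per_class
    k_normo <- rtrunc_norm(n_rec, config$k_normo_mean, config$k_normo_sd, 3.5, 5.0)
    k_hyper <- rtrunc_norm(n_rec, config$k_hyper_mean, config$k_hyper_sd, 5.5 + 1e-6, 8.0)
    ks <- c(k_normo, k_hyper)
    records <- vector("list", 2L * n_rec)
    for (j in seq_along(ks)) {
      rid <- sprintf("%s_R%02d", sid, j)
      draw_time <- t0 + (i - 1) * 30 * 86400 + (j - 1) * 86400
      records[[j]] <- synthesize_record(profile, severity_score(ks[j]), config,
                                        rid, ks[j], draw_time)
    }
    cohort[[i]] <- list(profile = profile, records = records)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  structure(cohort, class = "ecg_cohort", config = config)
}

#' Flatten a cohort to a list of records
#'
#' @param cohort An `ecg_cohort`.
#' @return Unnamed list of `ecg_record` objects.
#' @export
cohort_records <- function(cohort) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  unlist(lapply(cohort, `[[`, "records"), recursive = FALSE)
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s subject %s: %d samples @ %g Hz, K = %.2f mEq/L>\n",
              x$record_id, x$subject_id, length(x$signal), x$fs, x$potassium))
  invisible(x)
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<ecg_cohort: %d subjects x %d records (%g s @ %g Hz), seed %d>\n",
              length(x), length(x[[1]]$records), cfg$duration_s, cfg$fs, cfg$seed))
  invisible(x)
}
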