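# Beat-level preprocessing: zero-phase FIR band-pass, automated quality
# control, R-peak detection, 120-sample segmentation and potassium
# labelling.

#' FIR band-pass filter specification
#'
#' Default is the standard ECG monitoring band, 0.5-40 Hz, as a 255-tap
#' Hamming-window FIR design applied forward-backward (zero phase).
#'
#' @param low,high Passband edges in Hz (`0 < low < high`).
#' @param taps Number of filter taps (odd).
#' @param window Design window name (only `"hamming"` is supported).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low = 0.5, high = 40, taps = 255L, window = "hamming") {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (taps %% 2 == 0) stop("taps must be odd")
  if (!identical(window, "hamming")) stop("only the hamming window is supported")
  structure(list(low = low, high = high, taps = as.integer(taps), window = window),
            class = "filter_spec")
}

#' Zero-phase FIR band-pass filter
#'
#' Designs the band-pass with [signal::fir1()] and applies it with
#' [signal::filtfilt()] (forward-backward, so no phase distortion and no
#' fiducial shift). Output length equals input length.
#'
#' @param x Numeric signal (mV).
#' @param fs Sampling frequency, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
fir_filter <- function(x, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high >= fs / 2) stop("passband high edge must be below the Nyquist frequency fs/2")
  if (length(x) <= spec$taps) stop("signal must be longer than the filter (", spec$taps, " taps)")
  b <- signal::fir1(spec$taps - 1L, c(spec$low, spec$high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(b, x))
}

#' Quality-control configuration
#'
#' Automated surrogate for manual noise inspection. A record fails QC when
#' the fraction of flat first differences exceeds `flat_frac`, the
#' fraction of spectral power outside `band` exceeds `oob_power_ratio`,
#' or the RR coefficient of variation of the detected beats exceeds
#' `rr_cv_max` (a surrogate for excluding rhythms without an identifiable
#' beat cycle, such as atrial fibrillation or pacing).
#'
#' @param flat_frac Maximum tolerated fraction of flat samples.
#' @param oob_power_ratio Maximum tolerated out-of-band power fraction.
#' @param rr_cv_max Maximum tolerated RR coefficient of variation.
#' @param band In-band frequency range in Hz.
#' @param flat_eps Absolute first-difference threshold (mV) below which a
#'   sample counts as flat.
#' @return A list of thresholds.
#' @export
qc_config <- function(flat_frac = 0.1, oob_power_ratio = 0.5, rr_cv_max = 0.25,
                      band = c(0.5, 40), flat_eps = 1e-7) {
  list(flat_frac = flat_frac, oob_power_ratio = oob_power_ratio,
       rr_cv_max = rr_cv_max, band = band, flat_eps = flat_eps)
}

#' Automated signal quality check
#'
#' @param x Numeric signal (mV).
#' @param fs Sampling frequency, Hz.
#' @param config Thresholds, see [qc_config()].
#' @return List with `pass` (logical) and `reason` (`"ok"`, `"flat"`,
#'   `"noise"`, or `"rhythm"`).
#' @export
quality_check <- function(x, fs, config = qc_config()) {
  if (length(x) < 2) return(list(pass = FALSE, reason = "flat"))
  flat <- mean(abs(diff(x)) < config$flat_eps)
  if (flat > config$flat_frac) return(list(pass = FALSE, reason = "flat"))
  # spectral out-of-band power fraction
  xc <- x - mean(x)
  spec <- Mod(stats::fft(xc))^2
  n <- length(xc)
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  inband <- half & freq >= config$band[1] & freq <= config$band[2]
  ptot <- sum(spec[half])
  if (ptot > 0) {
    oob <- 1 - sum(spec[inband]) / ptot
    if (oob > config$oob_power_ratio) return(list(pass = FALSE, reason = "noise"))
  }
  # beat-cycle regularity
  rp <- tryCatch(detect_rpeaks(x, fs), error = function(e) integer(0))
  if (length(rp) >= 3) {
    rr <- diff(rp)
    cv <- stats::sd(rr) / mean(rr)
    if (is.finite(cv) && cv > config$rr_cv_max) return(list(pass = FALSE, reason = "rhythm"))
  } else {
    return(list(pass = FALSE, reason = "rhythm"))
  }
  list(pass = TRUE, reason = "ok")
}

#' Detect R peaks (Pan-Tompkins style)
#'
#' Derivative -> squaring -> 150 ms moving-window integration -> adaptive
#' thresholding with running signal/noise peak estimates and a 200 ms
#' refractory period. Candidate locations are refined to the maximum of
#' the input signal within +-100 ms, so on a band-passed signal the
#' returned indices sit on the R wave itself.
#'
#' @param x Filtered signal (mV).
#' @param fs Sampling frequency, Hz.
#' @return Strictly increasing integer vector of R-peak sample indices
#'   (1-based); empty when no beats are found.
#' @export
detect_rpeaks <- function(x, fs) {
  if (length(x) < fs) stop("signal too short for R-peak detection (need >= 1 s)")
  # five-point derivative (Pan-Tompkins), centered to avoid group delay
  d <- stats::filter(x, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- max(3L, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  mwi[is.na(mwi)] <- 0
  refr <- round(0.200 * fs)
  # local maxima of the integrated signal
  n <- length(mwi)
  if (n < 3) return(integer(0))
  is_max <- c(FALSE, mwi[2:(n - 1)] >= mwi[1:(n - 2)] & mwi[2:(n - 1)] > mwi[3:n], FALSE)
  cand <- which(is_max & mwi > 0)
  if (length(cand) == 0) return(integer(0))
  # adaptive signal/noise running estimates, with slope-based T-wave
  # discrimination: a candidate within 360 ms of the last accepted peak
  # whose maximal derivative is less than half the previous peak's is a
  # T wave, not a QRS complex
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.5
  npki <- mean(init) * 0.5
  slope_win <- round(0.075 * fs)
  max_slope <- function(i) {
    lo <- max(1L, i - slope_win); hi <- min(n, i + slope_win)
    max(abs(d[lo:hi]))
  }
  twave <- round(0.360 * fs)
  peaks <- integer(0)
  last <- -Inf; last_slope <- 0
  for (i in cand) {
    thr <- npki + 0.25 * (spki - npki)
    accept <- mwi[i] > thr && (i - last) > refr
    if (accept && (i - last) <= twave && max_slope(i) < 0.5 * last_slope)
      accept <- FALSE
    if (accept) {
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
      last <- i; last_slope <- max_slope(i)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
  }
  if (length(peaks) == 0) return(integer(0))
  # refine to the R wave on the input signal
  halfw <- round(0.100 * fs)
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - halfw); hi <- min(length(x), i + halfw)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  sort(unique(refined))
}

#' Segment a record into 120-sample beats
#'
#' For each R peak at (1-based) index `r`, emits the 120 samples
#' `[r - 40, r + 79]`, so the R peak is the 41st sample of the segment.
#' Peaks too close to either record edge are dropped.
#'
#' @param x Signal the peaks were detected on.
#' @param rpeaks Ascending R-peak indices (1-based).
#' @return Matrix with one 120-sample beat per row; attribute `rpeaks`
#'   gives the source peak of each row.
#' @export
segment_beats <- function(x, rpeaks) {
  if (length(rpeaks) && any(diff(rpeaks) <= 0)) stop("rpeaks must be strictly ascending")
  keep <- rpeaks[rpeaks - 40 >= 1 & rpeaks + 79 <= length(x)]
  beats <- matrix(0, nrow = length(keep), ncol = 120)
  for (i in seq_along(keep)) beats[i, ] <- x[(keep[i] - 40):(keep[i] + 79)]
  attr(beats, "rpeaks") <- keep
  beats
}

#' Fiducial position of segmented beats
#'
#' @return The 1-based index of the R peak within a segment (41).
#' @export
beat_fiducial <- function() 41L

#' Label a potassium value
#'
#' Hyperkalemia above 5.5 mEq/L; normokalemia in `[3.5, 5.0]`; the band
#' `(5.0, 5.5]` is excluded so that no heartbeat can be labelled both ways;
#' values below 3.5 (hypokalemia) are outside the study scope and are also
#' excluded.
#'
#' @param potassium Serum potassium, mEq/L (positive).
#' @return Character vector in `{"hyper", "normo", "excluded"}`.
#' @export
label_potassium <- function(potassium) {
  if (!is.numeric(potassium) || any(!is.finite(potassium)) || any(potassium <= 0))
    stop("potassium must be positive and finite (mEq/L)")
  ifelse(potassium > 5.5, "hyper",
         ifelse(potassium >= 3.5 & potassium <= 5.0, "normo", "excluded"))
}

#' Extract the pre-draw ECG excerpt
#'
#' Returns the 600 s of signal ending at the lab draw time. If the
#' recording covers less than the full window, all available signal is
#' returned with attribute `short_window = TRUE`.
#'
#' @param x Full waveform.
#' @param fs Sampling frequency, Hz.
#' @param start_time Recording start (POSIXct).
#' @param draw_time Lab draw time (POSIXct).
#' @param window_s Excerpt length in seconds (default 600).
#' @return Numeric excerpt with attribute `short_window`.
#' @export
extract_excerpt <- function(x, fs, start_time, draw_time, window_s = 600) {
  end_i <- floor(as.numeric(difftime(draw_time, start_time, units = "secs")) * fs)
  if (end_i <= 0) stop("draw time precedes the recording: no overlap with the excerpt window")
  end_i <- min(end_i, length(x))
  start_i <- end_i - round(window_s * fs) + 1L
  short <- start_i < 1L
  start_i <- max(1L, start_i)
  out <- x[start_i:end_i]
  attr(out, "short_window") <- short
  out
}

#' Preprocess one record into labelled beats
#'
#' Runs the full per-record chain: band-pass filter, quality check, R-peak
#' detection, 120-sample segmentation, and potassium labelling.
#'
#' @param record An `ecg_record`.
#' @param fspec Filter specification.
#' @param qc Quality-control thresholds, or `NULL` to skip QC.
#' @return List with `beats` (matrix), `label`, `potassium`, `record_id`,
#'   `subject_id`, `rpeaks`, `qc`. `beats` has zero rows when QC fails or
#'   the record label is `"excluded"`.
#' @export
process_record <- function(record, fspec = filter_spec(), qc = qc_config()) {
  stopifnot(inherits(record, "ecg_record"))
  lab <- label_potassium(record$potassium)
  filt <- fir_filter(record$signal, record$fs, fspec)
  qcres <- if (is.null(qc)) list(pass = TRUE, reason = "ok") else quality_check(filt, record$fs, qc)
  if (!qcres$pass || lab == "excluded") {
    beats <- matrix(0, 0, 120); rp <- integer(0)
  } else {
    rp <- detect_rpeaks(filt, record$fs)
    beats <- segment_beats(filt, rp)
  }
  list(beats = beats, label = lab, potassium = record$potassium,
       record_id = record$record_id, subject_id = record$subject_id,
       rpeaks = rp, qc = qcres)
}

#' Preprocess a cohort into a beat set
#'
#' @param records List of `ecg_record` (e.g. from [cohort_records()]).
#' @param fspec,qc Passed to [process_record()].
#' @return A `beat_set`: list with `X` (n x 120 matrix of beats) and `meta`
#'   (data.frame with one row per beat: record_id, subject_id, label,
#'   potassium), plus `records` (per-record data.frame including excluded /
#'   failed-QC records with beat counts).
#' @export
build_beat_set <- function(records, fspec = filter_spec(), qc = qc_config()) {
  proc <- lapply(records, process_record, fspec = fspec, qc = qc)
  Xs <- list(); metas <- list()
  recrows <- data.frame(record_id = character(0), subject_id = character(0),
                        label = character(0), potassium = numeric(0),
                        n_beats = integer(0), qc_pass = logical(0),
                        qc_reason = character(0), stringsAsFactors = FALSE)
  for (p in proc) {
    nb <- nrow(p$beats)
    recrows <- rbind(recrows, data.frame(
      record_id = p$record_id, subject_id = p$subject_id, label = p$label,
      potassium = p$potassium, n_beats = nb, qc_pass = p$qc$pass,
      qc_reason = p$qc$reason, stringsAsFactors = FALSE))
    if (nb > 0 && p$label %in% c("hyper", "normo")) {
      Xs[[length(Xs) + 1L]] <- p$beats
      metas[[length(metas) + 1L]] <- data.frame(
        record_id = rep(p$record_id, nb), subject_id = rep(p$subject_id, nb),
        label = rep(p$label, nb), potassium = rep(p$potassium, nb),
        stringsAsFactors = FALSE)
    }
  }
  X <- if (length(Xs)) do.call(rbind, Xs) else matrix(0, 0, 120)
  meta <- if (length(metas)) do.call(rbind, metas) else
    data.frame(record_id = character(0), subject_id = character(0),
               label = character(0), potassium = numeric(0), stringsAsFactors = FALSE)
  structure(list(X = X, meta = meta, records = recrows), class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set: %d beats from %d records (%d subjects); %d hyper / %d normo>\n",
              nrow(x$X), nrow(x$records), length(unique(x$meta$subject_id)),
              sum(x$meta$label == "hyper"), sum(x$meta$label == "normo")))
  invisible(x)
}

#' Subset a beat set by row index
#'
#' @param bs A `beat_set`.
#' @param idx Integer or logical beat index.
#' @return A `beat_set` with the selected beats (record table untouched).
#' @export
beat_subset <- function(bs, idx) {
  structure(list(X = bs$X[idx, , drop = FALSE], meta = bs$meta[idx, , drop = FALSE],
                 records = bs$records), class = "beat_set")
}
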