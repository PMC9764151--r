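# Readers and writers: WFDB-style header+signal records, a plain CSV
# waveform dialect, the lab table, checkpoint serialization, and the
# end-to-end pipeline driver used for determinism audits.

WFDB_GAIN <- 200         # ADC units per mV, the usual monitor convention
WFDB_INVALID <- -32768L  # format-16 missing-sample sentinel

#' Write an ECG record
#'
#' `format = "wfdb"` writes a minimal WFDB pair: a text header
#' (`<id>.hea`: record line with sampling frequency and length, one signal
#' line with format 16 and gain) and a 16-bit little-endian signal file
#' (`<id>.dat`). `format = "csv"` writes the package's CSV dialect:
#' comment header lines (`# key=value` carrying record_id, fs, potassium)
#' followed by `sample,mv` rows.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory (created if needed).
#' @param format `"wfdb"` or `"csv"`.
#' @return The path of the main file written, invisibly.
#' @export
write_waveform <- function(record, dir, format = c("wfdb", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "wfdb") {
    base <- record$record_id
    adc <- as.integer(round(record$signal * WFDB_GAIN))
    adc[adc > 32767L] <- 32767L; adc[adc < -32767L] <- -32767L
    chk <- sum(adc) %% 65536
    if (chk > 32767) chk <- chk - 65536
    hea <- file.path(dir, paste0(base, ".hea"))
    writeLines(c(
      sprintf("%s 1 %g %d", base, record$fs, length(adc)),
      sprintf("%s.dat 16 %d/mV 16 0 %d %d 0 II", base, WFDB_GAIN,
              adc[1], as.integer(chk))), hea)
    con <- file(file.path(dir, paste0(base, ".dat")), "wb")
    writeBin(adc, con, size = 2L, endian = "little")
    close(con)
    invisible(hea)
  } else {
    path <- file.path(dir, paste0(record$record_id, ".csv"))
    con <- file(path, "w")
    writeLines(c(sprintf("# record_id=%s", record$record_id),
                 sprintf("# subject_id=%s", record$subject_id),
                 sprintf("# fs=%g", record$fs),
                 sprintf("# potassium=%g", record$potassium),
                 "sample,mv"), con)
    utils::write.table(data.frame(sample = seq_along(record$signal) - 1L,
                                  mv = record$signal),
                       con, sep = ",", row.names = FALSE, col.names = FALSE)
    close(con)
    invisible(path)
  }
}

format_error <- function(message, dialect, line = NA_integer_) {
  stop(errorCondition(message, class = "format_error",
                      dialect = dialect, line = line))
}

#' Read an ECG record
#'
#' Supports the WFDB header+signal pairs and the CSV dialect written by
#' [write_waveform()]. The dialect is sniffed from the extension; WFDB
#' missing-sample sentinels become `NA` with a `gaps` attribute.
#'
#' @param path Path to a `.hea` or `.csv` file.
#' @return List with `signal` (mV), `fs`, and any metadata found
#'   (`record_id`, `potassium`); attribute `gaps` flags missing samples.
#' @export
read_waveform <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "hea") {
    lines <- readLines(path)
    rec <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(rec) < 4) format_error("malformed WFDB record line", "wfdb", 1L)
    fs <- as.numeric(rec[3]); nsamp <- as.integer(rec[4])
    sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    gain <- as.numeric(sub("/mV$", "", sig[3]))
    if (!is.finite(gain) || gain <= 0) format_error("bad ADC gain", "wfdb", 2L)
    dat <- file.path(dirname(path), sig[1])
    con <- file(dat, "rb")
    adc <- readBin(con, integer(), n = nsamp, size = 2L, endian = "little")
    close(con)
    gaps <- adc == WFDB_INVALID
    signal <- adc / gain
    signal[gaps] <- NA_real_
    out <- list(signal = signal, fs = fs, record_id = rec[1])
    attr(out$signal, "gaps") <- gaps
    out
  } else if (ext == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines)
    meta <- list()
    for (h in hdr) {
      kv <- sub("^#\\s*", "", lines[h])
      parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(parts) == 2) meta[[trimws(parts[1])]] <- trimws(parts[2])
    }
    body_start <- if (length(hdr)) max(hdr) + 1L else 1L
    if (!grepl("^sample\\s*,\\s*mv$", lines[body_start]))
      format_error("missing 'sample,mv' column header", "csv", body_start)
    rows <- lines[-seq_len(body_start)]
    rows <- rows[nzchar(rows)]
    vals <- strsplit(rows, ",", fixed = TRUE)
    bad <- which(vapply(vals, function(v)
      length(v) != 2 || is.na(suppressWarnings(as.numeric(v[2]))), logical(1)))
    if (length(bad))
      format_error(sprintf("non-numeric sample row at line %d",
                           body_start + bad[1]), "csv", body_start + bad[1])
    signal <- vapply(vals, function(v) as.numeric(v[2]), numeric(1))
    fs <- as.numeric(meta$fs)
    if (!is.finite(fs)) format_error("missing fs metadata", "csv")
    out <- list(signal = signal, fs = fs, record_id = meta$record_id)
    if (!is.null(meta$potassium)) out$potassium <- as.numeric(meta$potassium)
    attr(out$signal, "gaps") <- rep(FALSE, length(signal))
    out
  } else {
    format_error(paste0("unknown waveform dialect: .", ext), ext)
  }
}

#' Write the lab table
#'
#' @param records List of `ecg_record` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labs <- function(records, path) {
  df <- do.call(rbind, lapply(records, function(r)
    data.frame(subject_id = r$subject_id, record_id = r$record_id,
               timestamp = format(r$draw_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               potassium_mEq_L = r$potassium, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the lab table
#'
#' Strict CSV reader for columns subject_id, record_id, timestamp
#' (ISO 8601) and potassium_mEq_L. Rows with an empty potassium value are
#' dropped and counted; malformed numbers (e.g. comma decimals) are an
#' error, never silently coerced.
#'
#' @param path Lab CSV path.
#' @return Data frame with parsed columns and attribute `n_dropped`.
#' @export
read_labs <- function(path) {
  df <- tryCatch(utils::read.csv(path, colClasses = "character"),
                 error = function(e)
                   format_error(paste("malformed lab CSV:", conditionMessage(e)),
                                "labs-csv"))
  need <- c("subject_id", "record_id", "timestamp", "potassium_mEq_L")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    format_error(paste("missing required column(s):",
                       paste(missing_cols, collapse = ", ")), "labs-csv")
  empty <- !nzchar(trimws(df$potassium_mEq_L))
  kept <- df[!empty, , drop = FALSE]
  bad <- which(!grepl("^[+-]?([0-9]*\\.)?[0-9]+([eE][+-]?[0-9]+)?$",
                      trimws(kept$potassium_mEq_L)))
  if (length(bad))
    format_error(sprintf("unparseable potassium value '%s' (row %d)",
                         kept$potassium_mEq_L[bad[1]], bad[1]), "labs-csv", bad[1])
  ts <- as.POSIXct(kept$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(ts))
    format_error("timestamp not in ISO 8601 (YYYY-MM-DDTHH:MM:SSZ)", "labs-csv",
                 which(is.na(ts))[1])
  out <- data.frame(subject_id = kept$subject_id, record_id = kept$record_id,
                    timestamp = ts,
                    potassium = as.numeric(kept$potassium_mEq_L),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(empty)
  out
}

# ---- checkpoints -----------------------------------------------------------

#' Save a checkpoint
#'
#' Directory layout: `spec.json` (architecture, metadata, freeze mask,
#' array names/shapes) plus one little-endian float64 `.bin` file per named
#' array. Round-trips bitwise.
#'
#' @param ckpt An `ecg_checkpoint`.
#' @param dir Target directory (created; must be empty or absent).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(ckpt, dir) {
  stopifnot(inherits(ckpt, "ecg_checkpoint"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arrays <- c(ckpt$params, stats::setNames(ckpt$buffers,
                                           paste0("buffer:", names(ckpt$buffers))))
  manifest <- list(
    spec = ckpt$spec[setdiff(names(ckpt$spec), NULL)],
    meta = ckpt$meta,
    freeze = as.list(ckpt$freeze),
    arrays = lapply(arrays, function(a) as.integer(if (is.matrix(a)) dim(a) else length(a))))
  jsonlite::write_json(manifest, file.path(dir, "spec.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(ckpt$log))
    utils::write.csv(ckpt$log, file.path(dir, "training_log.csv"), row.names = FALSE)
  for (nm in names(arrays)) {
    fn <- file.path(dir, paste0(gsub("[:]", "_", nm), ".bin"))
    con <- file(fn, "wb")
    writeBin(as.vector(arrays[[nm]]), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Load a checkpoint
#'
#' @param dir Directory written by [save_checkpoint()].
#' @return The reconstructed `ecg_checkpoint`.
#' @export
load_checkpoint <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "spec.json"))
  spec <- manifest$spec
  spec$layout <- as.integer(unlist(spec$layout))
  spec$widths <- as.integer(unlist(spec$widths))
  spec$strides <- as.integer(unlist(spec$strides))
  for (f in c("expansion", "stem_width", "stem_kernel", "kernel", "input_length",
              "in_channels", "num_classes"))
    spec[[f]] <- as.integer(spec[[f]])
  class(spec) <- "network_spec"
  params <- list(); buffers <- list()
  for (nm in names(manifest$arrays)) {
    dims <- as.integer(unlist(manifest$arrays[[nm]]))
    fn <- file.path(dir, paste0(gsub("[:]", "_", nm), ".bin"))
    con <- file(fn, "rb")
    v <- readBin(con, numeric(), n = prod(dims), size = 8L, endian = "little")
    close(con)
    a <- if (length(dims) == 2) matrix(v, dims[1], dims[2]) else v
    if (startsWith(nm, "buffer:")) buffers[[sub("^buffer:", "", nm)]] <- a
    else params[[nm]] <- a
  }
  log <- NULL
  if (file.exists(file.path(dir, "training_log.csv")))
    log <- utils::read.csv(file.path(dir, "training_log.csv"))
  new_checkpoint(spec, params, buffers, meta = manifest$meta, log = log,
                 freeze = unlist(manifest$freeze))
}

# ---- end-to-end smoke pipeline --------------------------------------------

#' Run the end-to-end pipeline on a small synthetic cohort
#'
#' Simulates a cohort, preprocesses it to beats, trains a generic model on
#' the subject-level train/validation partitions, personalizes the eligible
#' subjects, and writes a run manifest (seed, config hash, package version),
#' the checkpoint, and the round-metrics CSV. Everything is seeded, so a
#' rerun with the same seed reproduces the metrics CSV bitwise.
#'
#' @param out_dir Output directory.
#' @param seed Master seed for every stage.
#' @param cohort_cfg A [cohort_config()]; its own seed is overridden by
#'   `seed`.
#' @param spec Network spec (default the fast resnet18_1d variant).
#' @param train_cfg A [train_config()] (seed overridden by `seed`).
#' @param plan A [personalization_plan()] (seed overridden by `seed`).
#' @param personalize_n Cap on the number of subjects personalized (keeps
#'   the smoke run short).
#' @return List with paths (`manifest`, `metrics_csv`, `checkpoint_dir`)
#'   and the in-memory `metrics` and `summary` tables.
#' @export
run_smoke_pipeline <- function(out_dir, seed = 1L,
                               cohort_cfg = cohort_config(
                                 n_subjects = 5, records_per_class = 8,
                                 duration_s = 15, subject_spread = 0.5, seed = seed),
                               spec = resnet_spec("resnet18_1d"),
                               train_cfg = train_config(lr = 1e-3, batch_size = 64,
                                                        max_epochs = 2, seed = seed),
                               plan = personalization_plan(lr = 3e-3, max_rounds = 1,
                                                           seed = seed),
                               personalize_n = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  cohort_cfg$seed <- as.integer(seed)
  train_cfg$seed <- as.integer(seed)
  plan$seed <- as.integer(seed)
  message("[simulate] ", cohort_cfg$n_subjects, " subjects")
  cohort <- generate_cohort(cohort_cfg)
  bs <- build_beat_set(cohort_records(cohort))
  split <- split_dataset(bs$records, ratio = train_cfg$ratio, seed = seed)
  tr <- beat_subset(bs, bs$meta$subject_id %in% split$train)
  va <- beat_subset(bs, bs$meta$subject_id %in% split$validation)
  message("[pretrain] ", nrow(tr$X), " train beats, ", nrow(va$X), " validation beats")
  ckpt <- train_generic(tr, va, spec, train_cfg)
  ckpt_dir <- file.path(out_dir, "checkpoint")
  save_checkpoint(ckpt, ckpt_dir)
  elig <- eligible_subjects(bs$records)
  elig <- elig[seq_len(min(length(elig), personalize_n))]
  message("[personalize] ", length(elig), " subjects")
  pers <- personalize_cohort(bs, ckpt, plan, subjects = elig)
  metrics_csv <- file.path(out_dir, "round_metrics.csv")
  utils::write.csv(format(pers$metrics, digits = 15), metrics_csv,
                   row.names = FALSE, quote = FALSE)
  summary <- aggregate_rounds(pers$metrics)
  utils::write.csv(format(summary, digits = 15),
                   file.path(out_dir, "round_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(cohort = cohort_cfg[setdiff(names(cohort_cfg),
                                                        c("template", "coefs"))],
                            train = unclass(train_cfg), plan = unclass(plan),
                            spec = list(variant = spec$variant)),
                       cfg_file, auto_unbox = TRUE, digits = NA)
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("ecgkalemia")),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    manifest, auto_unbox = TRUE)
  list(manifest = manifest, metrics_csv = metrics_csv, checkpoint_dir = ckpt_dir,
       metrics = pers$metrics, summary = summary)
}
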