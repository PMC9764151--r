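# Desk-scale study protocols. These fix the problem sizes used throughout
# the package's tests, analysis scripts and acceptance checks, so every
# entry point runs the identical experiment. Sizes and optimizer settings
# are the package's desk-scale choices (see the methods vignette): the
# fast resnet18_1d variant, small cohorts of short records, and a larger
# learning rate than the full-scale protocol because only a few hundred
# Adam steps are taken.

#' Generic-model sanity experiment
#'
#' Trains the generic classifier on a separable, noiseless synthetic cohort
#' (15 subjects, 2 records per class, 20 s records, no subject
#' heterogeneity) with a subject-level 6:2:2 split. With `shuffled = TRUE`
#' the training labels are permuted first — the leakage control, whose
#' validation accuracy should sit at chance.
#'
#' @param seed Master seed for cohort, split, shuffling and training.
#' @param shuffled Permute training labels (leakage control).
#' @param epochs Training epochs (protocol: 5).
#' @return List with `checkpoint`, `val_accuracy` (at the checkpointed
#'   epoch), `log`, and the partition sizes.
#' @export
experiment_generic_sanity <- function(seed = 1L, shuffled = FALSE, epochs = 5L) {
  cfg <- cohort_config(n_subjects = 15, records_per_class = 2, duration_s = 20,
                       subject_spread = 0, noise_sd = 0, seed = seed)
  bs <- build_beat_set(cohort_records(generate_cohort(cfg)))
  spl <- split_dataset(bs$records, seed = seed)
  tr <- beat_subset(bs, bs$meta$subject_id %in% spl$train)
  va <- beat_subset(bs, bs$meta$subject_id %in% spl$validation)
  if (shuffled) {
    set.seed(seed + 424243L)
    tr$meta$label <- sample(tr$meta$label)
  }
  ck <- train_generic(tr, va, resnet_spec("resnet18_1d"),
                      train_config(lr = 1e-3, batch_size = 64, max_epochs = epochs,
                                   seed = seed))
  list(checkpoint = ck,
       val_accuracy = ck$log$val_accuracy[ck$meta$epoch],
       log = ck$log,
       n_train_beats = nrow(tr$X), n_val_beats = nrow(va$X))
}

#' Personalized transfer-learning experiment
#'
#' The package's scaled-down version of the study's central experiment.
#' A generic model is pretrained on a heterogeneous pooled cohort
#' (15 subjects, 2 records per class); a separate heterogeneous cohort of
#' 12 candidate subjects with 10 records per class is preprocessed, and the
#' first 8 eligible subjects (at least 8 usable records per class) undergo
#' round-based transfer learning: 25% per-class holdout, one record pair
#' per round, 5 fine-tuning epochs, at most 5 rounds, stem + first 3 stages
#' frozen.
#'
#' @param seed Master seed.
#' @param n_personal Number of eligible subjects personalized (protocol: 8).
#' @return List with `pretrained` (generic checkpoint), `metrics` (stacked
#'   per-subject round metrics), `summary` ([aggregate_rounds()] table),
#'   `fits` (per-subject results), and `frozen_drift` (max absolute change
#'   over all frozen weights, all subjects; 0 when freezing is airtight).
#' @export
experiment_transfer <- function(seed = 1L, n_personal = 8L) {
  gcfg <- cohort_config(n_subjects = 15, records_per_class = 2, duration_s = 20,
                        seed = seed)
  gbs <- build_beat_set(cohort_records(generate_cohort(gcfg)))
  spl <- split_dataset(gbs$records, seed = seed)
  tr <- beat_subset(gbs, gbs$meta$subject_id %in% spl$train)
  va <- beat_subset(gbs, gbs$meta$subject_id %in% spl$validation)
  ck <- train_generic(tr, va, resnet_spec("resnet18_1d"),
                      train_config(lr = 1e-3, batch_size = 64, max_epochs = 5,
                                   seed = seed))
  pcfg <- cohort_config(n_subjects = 12, records_per_class = 10, duration_s = 30,
                        seed = seed + 5000L)
  pbs <- build_beat_set(cohort_records(generate_cohort(pcfg)))
  elig <- eligible_subjects(pbs$records)
  if (length(elig) == 0) stop("no eligible subjects in the personal cohort")
  if (length(elig) < n_personal)
    warning("only ", length(elig), " eligible subjects (protocol asks for ",
            n_personal, "); personalizing all of them")
  elig <- elig[seq_len(min(n_personal, length(elig)))]
  pers <- personalize_cohort(pbs, ck, personalization_plan(lr = 3e-3, seed = seed),
                             subjects = elig)
  drift <- max(vapply(pers$fits, function(f) {
    frozen <- names(f$checkpoint$freeze)[f$checkpoint$freeze]
    max(vapply(frozen, function(nm)
      max(abs(f$checkpoint$params[[nm]] - ck$params[[nm]])), numeric(1)))
  }, numeric(1)))
  list(pretrained = ck, metrics = pers$metrics,
       summary = aggregate_rounds(pers$metrics), fits = pers$fits,
       frozen_drift = drift, eligible = elig)
}
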