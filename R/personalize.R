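# Round-based patient-adaptive transfer learning: start from the generic
# checkpoint, re-initialize the classification head, freeze the early
# stages, and fine-tune on one hyperkalemic plus one normokalemic record
# per round, evaluating on a fixed per-subject holdout after every round.

#' Personalization plan
#'
#' Defaults follow the study protocol: 25% of records per class held out,
#' one record of each class consumed per round, 5 fine-tuning epochs per
#' round, at most 5 rounds, stem plus the first 3 of 4 residual stages
#' frozen.
#'
#' @param holdout_frac Fraction of records per class reserved as the
#'   personal test set (rounded up per class).
#' @param epochs_per_round Fine-tuning epochs per round.
#' @param max_rounds Maximum number of rounds.
#' @param frozen_stages Number of leading residual stages frozen (the stem
#'   is always frozen with them).
#' @param lr Fine-tuning learning rate.
#' @param batch_size Fine-tuning mini-batch size.
#' @param seed RNG seed (head re-initialization, holdout draw, record order).
#' @return An object of class `personalization_plan`.
#' @export
personalization_plan <- function(holdout_frac = 0.25, epochs_per_round = 5L,
                                 max_rounds = 5L, frozen_stages = 3L,
                                 lr = 5e-5, batch_size = 16L, seed = 1L) {
  if (holdout_frac <= 0 || holdout_frac >= 1) stop("holdout_frac must lie in (0, 1)")
  if (max_rounds < 1) stop("max_rounds must be >= 1")
  if (frozen_stages < 0 || frozen_stages >= 4) stop("frozen_stages must be < the number of stages (4)")
  structure(list(holdout_frac = holdout_frac,
                 epochs_per_round = as.integer(epochs_per_round),
                 max_rounds = as.integer(max_rounds),
                 frozen_stages = as.integer(frozen_stages),
                 lr = lr, batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "personalization_plan")
}

#' Subjects eligible for personalized transfer learning
#'
#' A subject qualifies with at least 8 records of each class; all others
#' are routed to generic training.
#'
#' @param records Data frame with `subject_id` and `label` columns, one row
#'   per record (e.g. the `records` table of a `beat_set`).
#' @param min_records Minimum records per class (default 8).
#' @return Character vector of eligible subject ids (possibly empty).
#' @export
eligible_subjects <- function(records, min_records = 8L) {
  if (nrow(records) == 0) return(character(0))
  if (!is.null(records$qc_pass)) records <- records[records$qc_pass, , drop = FALSE]
  if (!is.null(records$n_beats)) records <- records[records$n_beats > 0, , drop = FALSE]
  if (nrow(records) == 0) return(character(0))
  tab <- table(records$subject_id, records$label)
  nh <- if ("hyper" %in% colnames(tab)) tab[, "hyper"] else rep(0L, nrow(tab))
  nn <- if ("normo" %in% colnames(tab)) tab[, "normo"] else rep(0L, nrow(tab))
  rownames(tab)[nh >= min_records & nn >= min_records]
}

#' Prepare a personal model from the generic checkpoint
#'
#' Copies the pretrained weights, replaces the classification layer with a
#' freshly initialized fully connected layer, and freezes the stem plus the
#' first `frozen_stages` residual stages (weights and batch-norm statistics
#' alike).
#'
#' @param ckpt The generic `ecg_checkpoint`.
#' @param plan A [personalization_plan()].
#' @return A `resnet1d` model with `frozen_stages` set; attribute
#'   `freeze_names` lists the frozen parameter names.
#' @export
prepare_personal_model <- function(ckpt, plan) {
  stopifnot(inherits(ckpt, "ecg_checkpoint"), inherits(plan, "personalization_plan"))
  model <- checkpoint_model(ckpt)
  set.seed(plan$seed)
  cfin <- nrow(model$params$fc.W)
  model$params$fc.W <- matrix(stats::rnorm(cfin * ncol(model$params$fc.W),
                                           sd = sqrt(2 / cfin)),
                              cfin, ncol(model$params$fc.W))
  model$params$fc.b <- rep(0, length(model$params$fc.b))
  model$frozen_stages <- plan$frozen_stages
  attr(model, "freeze_names") <- frozen_param_names(model)
  model
}

#' Group a beat set into per-record beat lists for one subject
#'
#' @param bs A `beat_set`.
#' @param subject_id Subject to extract.
#' @return List with one element per labelled record: `record_id`, `label`,
#'   `beats` (matrix).
#' @export
subject_record_beats <- function(bs, subject_id) {
  sel <- bs$meta$subject_id == subject_id
  meta <- bs$meta[sel, , drop = FALSE]
  X <- bs$X[sel, , drop = FALSE]
  ids <- unique(meta$record_id)
  lapply(ids, function(rid) {
    rows <- meta$record_id == rid
    list(record_id = rid, label = meta$label[rows][1],
         beats = X[rows, , drop = FALSE])
  })
}

# record-level evaluation of a model on a list of record beat entries
evaluate_records <- function(model, recs) {
  pred <- vapply(recs, function(r) {
    p <- predict_record(model, r$beats)
    c(p$score, as.numeric(p$class == "hyper"))
  }, numeric(2))
  truth <- vapply(recs, `[[`, character(1), "label")
  classes <- ifelse(pred[2, ] == 1, "hyper", "normo")
  cm <- confusion_metrics(classes, truth)
  auc <- if (length(unique(truth)) == 2) auc_score(pred[1, ], truth) else NA_real_
  list(accuracy = cm$accuracy, auc = auc,
       sensitivity = cm$sensitivity, specificity = cm$specificity)
}

#' Run personalization rounds for one subject
#'
#' Round 0 evaluates the unmodified pretrained checkpoint on the subject's
#' holdout records. Each subsequent round consumes one previously unused
#' hyperkalemic and one normokalemic training record (all their beats),
#' fine-tunes the trainable stages for `epochs_per_round` epochs, and
#' re-evaluates the fixed holdout. Rounds stop at `max_rounds` or when
#' either class's training records run out. Frozen weights are bitwise
#' unchanged throughout.
#'
#' @param recs Per-record beat list for the subject (see
#'   [subject_record_beats()]).
#' @param ckpt The generic `ecg_checkpoint`.
#' @param plan A [personalization_plan()].
#' @param subject_id Subject id recorded in the metrics table.
#' @return List with `metrics` (data frame: subject_id, round, accuracy,
#'   auc, sensitivity, specificity; round 0 is the pretrained baseline),
#'   `checkpoint` (final personalized `ecg_checkpoint` with freeze mask),
#'   `holdout_ids`, and `consumed_ids` (training records used, by round).
#' @export
run_rounds <- function(recs, ckpt, plan = personalization_plan(),
                       subject_id = recs[[1]]$subject_id %||% "subject") {
  labels <- vapply(recs, `[[`, character(1), "label")
  hy <- which(labels == "hyper"); no <- which(labels == "normo")
  if (length(hy) == 0 || length(no) == 0)
    stop("subject needs records of both classes")
  set.seed(plan$seed)
  n_hold_h <- ceiling(length(hy) * plan$holdout_frac)
  n_hold_n <- ceiling(length(no) * plan$holdout_frac)
  hold_h <- sample(hy, n_hold_h); hold_n <- sample(no, n_hold_n)
  if (length(hold_h) == 0 || length(hold_n) == 0)
    stop("holdout is empty for one class")
  pool_h <- sample(setdiff(hy, hold_h))   # seeded round order
  pool_n <- sample(setdiff(no, hold_n))
  if (length(pool_h) == 0 || length(pool_n) == 0)
    stop("no training records left after the holdout split")
  holdout <- recs[c(hold_h, hold_n)]

  baseline <- checkpoint_model(ckpt)
  metrics <- cbind(data.frame(subject_id = subject_id, round = 0L),
                   as.data.frame(evaluate_records(baseline, holdout)))
  model <- prepare_personal_model(ckpt, plan)
  frozen_names <- attr(model, "freeze_names")
  consumed <- list()
  n_rounds <- min(plan$max_rounds, length(pool_h), length(pool_n))
  for (r in seq_len(n_rounds)) {
    take_h <- recs[[pool_h[r]]]; take_n <- recs[[pool_n[r]]]
    consumed[[r]] <- c(take_h$record_id, take_n$record_id)
    X <- rbind(take_h$beats, take_n$beats)
    y <- labels_to_y(c(rep(take_h$label, nrow(take_h$beats)),
                       rep(take_n$label, nrow(take_n$beats))))
    fit <- fit_model(model, X, y, epochs = plan$epochs_per_round, lr = plan$lr,
                     batch_size = plan$batch_size, seed = plan$seed + r)
    model <- fit$model
    metrics <- rbind(metrics,
                     cbind(data.frame(subject_id = subject_id, round = r),
                           as.data.frame(evaluate_records(model, holdout))))
  }
  freeze <- stats::setNames(names(model$params) %in% frozen_names, names(model$params))
  final <- new_checkpoint(model$spec, model$params, model$buffers,
                          meta = list(subject_id = subject_id,
                                      rounds = n_rounds, seed = plan$seed),
                          freeze = freeze)
  list(metrics = metrics, checkpoint = final,
       holdout_ids = vapply(holdout, `[[`, character(1), "record_id"),
       consumed_ids = consumed)
}

#' Personalize every eligible subject in a beat set
#'
#' @param bs A `beat_set`.
#' @param ckpt The generic `ecg_checkpoint`.
#' @param plan A [personalization_plan()]; each subject uses a sub-seed
#'   derived from `plan$seed` and its position for its holdout and rounds.
#' @param subjects Subjects to personalize; defaults to
#'   [eligible_subjects()] of the beat set's record table.
#' @return List with `metrics` (stacked per-subject round metrics) and
#'   `fits` (per-subject results from [run_rounds()]).
#' @export
personalize_cohort <- function(bs, ckpt, plan = personalization_plan(),
                               subjects = eligible_subjects(bs$records)) {
  if (length(subjects) == 0) stop("no eligible subjects")
  fits <- list()
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    sp <- plan; sp$seed <- subject_seed(plan$seed, i)
    fits[[sid]] <- run_rounds(subject_record_beats(bs, sid), ckpt, sp, subject_id = sid)
  }
  list(metrics = do.call(rbind, lapply(fits, `[[`, "metrics")), fits = fits)
}
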