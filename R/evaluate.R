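# Record-level evaluation: majority voting over beats, confusion metrics,
# rank-based AUC, and Mann-Whitney U tests (exact by enumeration for small
# samples).

#' Majority vote over beat classes
#'
#' The record is assigned the more frequent beat class; an exact tie goes
#' to hyperkalemia (the sensitivity-favouring choice, reflecting the
#' clinical cost asymmetry).
#'
#' @param classes Character vector of beat classes (`"hyper"` / `"normo"`).
#' @return `"hyper"` or `"normo"`.
#' @export
majority_vote <- function(classes) {
  if (length(classes) == 0) stop("cannot vote over an empty class list")
  if (!all(classes %in% c("hyper", "normo"))) stop("classes must be hyper/normo")
  if (sum(classes == "hyper") >= sum(classes == "normo")) "hyper" else "normo"
}

#' Record-level prediction from beat-level probabilities
#'
#' Beats are classified individually; the record class is their majority
#' vote and the record score is the mean per-beat hyperkalemia probability
#' (used for AUC). A vote-fraction score is available as an alternative.
#'
#' @param model A `resnet1d` model.
#' @param beats `n x input_length` beat matrix for one record.
#' @param score Record score definition: `"mean_prob"` (default) or
#'   `"vote_fraction"`.
#' @return List with `class`, `score`, `beat_classes`, `beat_probs`
#'   (per-beat hyperkalemia probability).
#' @export
predict_record <- function(model, beats, score = c("mean_prob", "vote_fraction")) {
  score <- match.arg(score)
  probs <- predict_proba(model, beats)
  p_hyper <- probs[, 2]
  beat_classes <- ifelse(p_hyper >= 0.5, "hyper", "normo")
  list(class = majority_vote(beat_classes),
       score = if (score == "mean_prob") mean(p_hyper) else mean(beat_classes == "hyper"),
       beat_classes = beat_classes, beat_probs = p_hyper)
}

#' Accuracy, sensitivity and specificity
#'
#' Hyperkalemia is the positive class. Ratios with an empty denominator
#' (no positives, or no negatives, among the truths) are reported as `NA`,
#' never as 0.
#'
#' @param predictions,truths Character vectors (`"hyper"` / `"normo"`) of
#'   equal length.
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(predictions, truths) {
  if (length(predictions) != length(truths)) stop("predictions and truths differ in length")
  if (!all(truths %in% c("hyper", "normo"))) stop("truths must be hyper/normo")
  tp <- sum(predictions == "hyper" & truths == "hyper")
  fn <- sum(predictions == "normo" & truths == "hyper")
  tn <- sum(predictions == "normo" & truths == "normo")
  fp <- sum(predictions == "hyper" & truths == "normo")
  list(accuracy = (tp + tn) / length(truths),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Area under the ROC curve (rank formulation)
#'
#' Equals the Mann-Whitney U statistic of the scores normalized by
#' `n1 * n0`, counting ties as one half — i.e. the probability that a
#' random hyperkalemic record scores above a random normokalemic one.
#'
#' @param scores Numeric record scores (larger = more hyperkalemic).
#' @param truths Character truths (`"hyper"` / `"normo"`), both present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truths) {
  if (length(scores) != length(truths)) stop("scores and truths differ in length")
  pos <- truths == "hyper"; neg <- truths == "normo"
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# U statistic for group a vs b (ties count one half)
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Mann-Whitney U test
#'
#' Exact two-sided p-value by full enumeration of group assignments when
#' `length(a) + length(b) <= exact_max` (ties handled by half-counting);
#' otherwise a normal approximation with tie correction and continuity
#' correction. The two-sided p-value is symmetric in the group order.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_max Largest pooled size for exact enumeration (default 12).
#' @return List with `U` (for group `a`) and `p_value`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  u <- u_statistic(a, b)
  if (N <= exact_max) {
    pool <- c(a, b)
    combs <- utils::combn(N, n1)
    us <- apply(combs, 2, function(ii) u_statistic(pool[ii], pool[-ii]))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(us <= u + eps), mean(us >= u - eps)))
  } else {
    pool <- c(a, b)
    ties <- table(pool)
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
      if (abs(u - mu) < 0.5) z <- 0
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = u, p_value = p)
}

# Exact (<= 12 pairs) or normal-approximation Wilcoxon signed-rank test,
# used for the optional paired round comparison.
signed_rank_test <- function(d, exact_max = 12L) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w + eps), mean(ws >= w - eps)))
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24
    z <- (w - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p)
}

#' Aggregate personalization metrics across subjects
#'
#' Produces the per-round mean (SD) of each metric across subjects plus a
#' comparison of each round against the round-0 baseline. The default
#' comparison is the unpaired Mann-Whitney U test (the test the analysis
#' protocol names); a paired signed-rank alternative is available.
#'
#' @param metrics Stacked round metrics (subject_id, round, accuracy, auc,
#'   sensitivity, specificity), e.g. from [personalize_cohort()].
#' @param paired Use the paired signed-rank comparison instead.
#' @return Data frame with one row per round: n_subjects, mean and SD per
#'   metric, and `p_*` columns versus round 0 (NA at round 0 and for n = 1
#'   the SDs are NA).
#' @export
aggregate_rounds <- function(metrics, paired = FALSE) {
  mnames <- c("accuracy", "auc", "sensitivity", "specificity")
  rounds <- sort(unique(metrics$round))
  base <- metrics[metrics$round == 0L, , drop = FALSE]
  out <- lapply(rounds, function(r) {
    mr <- metrics[metrics$round == r, , drop = FALSE]
    row <- data.frame(round = r, n_subjects = nrow(mr))
    for (m in mnames) {
      v <- mr[[m]]
      row[[paste0("mean_", m)]] <- mean(v, na.rm = TRUE)
      row[[paste0("sd_", m)]] <- if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else NA_real_
      if (r == 0L) {
        row[[paste0("p_", m)]] <- NA_real_
      } else if (paired) {
        both <- merge(base[, c("subject_id", m)], mr[, c("subject_id", m)],
                      by = "subject_id", suffixes = c("_0", "_r"))
        d <- both[[paste0(m, "_r")]] - both[[paste0(m, "_0")]]
        d <- d[is.finite(d)]
        row[[paste0("p_", m)]] <- if (length(d)) signed_rank_test(d)$p_value else NA_real_
      } else {
        x <- mr[[m]][is.finite(mr[[m]])]; y <- base[[m]][is.finite(base[[m]])]
        row[[paste0("p_", m)]] <- if (length(x) && length(y))
          mann_whitney_u(x, y)$p_value else NA_real_
      }
    }
    row
  })
  do.call(rbind, out)
}
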