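# Builds one tiny shared personalization fixture: a 4-stage narrow network
# (so freezing semantics match the real nets) and a subject with 8 + 8
# synthetic record beat sets.
pers_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sp <- tiny_spec("basic", stages = 4L, widths = c(4L, 4L, 8L, 8L),
                    input_length = 120L)
    m <- build_network(sp, seed = 21)
    ckpt <- new_checkpoint(sp, m$params, m$buffers,
                           meta = list(epoch = 1L, val_loss = 0.5, seed = 21L))
    set.seed(77)
    recs <- list()
    for (i in 1:16) {
      lab <- if (i <= 8) "hyper" else "normo"
      nb <- 6L
      X <- matrix(stats::rnorm(nb * 120, sd = 0.1), nb)
      if (lab == "hyper") X[, 70:90] <- X[, 70:90] + 1.5
      recs[[i]] <- list(record_id = sprintf("R%02d", i), label = lab, beats = X)
    }
    cache <<- list(spec = sp, ckpt = ckpt, recs = recs)
    cache
  }
})

test_that("eligibility requires 8 usable records of each class", {
  rec_tab <- function(nh, nn) data.frame(
    subject_id = "s1", label = rep(c("hyper", "normo"), c(nh, nn)))
  expect_equal(eligible_subjects(rec_tab(8, 8)), "s1")
  expect_equal(eligible_subjects(rec_tab(8, 7)), character(0))
  expect_equal(eligible_subjects(rec_tab(12, 8)), "s1")
  expect_equal(eligible_subjects(data.frame(subject_id = character(0),
                                            label = character(0))), character(0))
  # QC-failed and beatless records do not count
  tab <- rec_tab(8, 8)
  tab$qc_pass <- c(FALSE, rep(TRUE, 15))
  tab$n_beats <- 10L
  expect_equal(eligible_subjects(tab), character(0))
})

test_that("personal model preparation reinitializes the head and freezes the prefix", {
  fx <- pers_fixture()
  plan <- personalization_plan(seed = 5)
  m <- prepare_personal_model(fx$ckpt, plan)
  expect_false(identical(m$params$fc.W, fx$ckpt$params$fc.W))
  frozen <- attr(m, "freeze_names")
  # frozen prefix 3 on a 4-stage network: trainable = stage 4 + final bn + head
  trainable <- setdiff(names(m$params), frozen)
  expect_setequal(unique(sub("\\..*$", "", trainable)),
                  c("stage4", "final", "fc"))
  expect_true(all(grepl("^(stem|stage[123])\\.", frozen)))
  for (nm in setdiff(frozen, c("fc.W", "fc.b")))
    expect_identical(m$params[[nm]], fx$ckpt$params[[nm]])
  # identical seed reproduces the head
  m2 <- prepare_personal_model(fx$ckpt, plan)
  expect_identical(m2$params$fc.W, m$params$fc.W)
})

test_that("rounds consume record pairs, keep the holdout isolated and freeze bitwise", {
  fx <- pers_fixture()
  plan <- personalization_plan(lr = 5e-3, seed = 11)
  res <- run_rounds(fx$recs, fx$ckpt, plan, subject_id = "s1")
  # 8 + 8 records, 25% holdout -> 2 + 2 held out, 6 + 6 trainable, capped at 5 rounds
  expect_length(res$holdout_ids, 4L)
  expect_equal(max(res$metrics$round), 5L)
  expect_equal(nrow(res$metrics), 6L)      # round 0 baseline + 5 rounds
  expect_equal(res$metrics$round[1], 0L)
  # monotone data usage: each round consumed exactly one record per class
  expect_true(all(lengths(res$consumed_ids) == 2L))
  used <- unlist(res$consumed_ids)
  expect_length(used, 10L)
  expect_length(unique(used), 10L)         # without replacement
  expect_length(intersect(used, res$holdout_ids), 0L)
  # freeze conservation: every frozen weight is bitwise unchanged
  frozen <- names(res$checkpoint$freeze)[res$checkpoint$freeze]
  expect_gt(length(frozen), 0)
  for (nm in frozen)
    expect_identical(res$checkpoint$params[[nm]], fx$ckpt$params[[nm]])
  # buffers of frozen stages are preserved too (eval-mode batch norm)
  for (nm in names(fx$ckpt$buffers))
    if (grepl("^(stem|stage[123])\\.", nm))
      expect_identical(res$checkpoint$buffers[[nm]], fx$ckpt$buffers[[nm]])
  # metrics lie in [0, 1]
  vals <- unlist(res$metrics[, c("accuracy", "auc", "sensitivity", "specificity")])
  expect_true(all(is.na(vals) | (vals >= 0 & vals <= 1)))
})

test_that("round training fits the easy personal signal", {
  fx <- pers_fixture()
  plan <- personalization_plan(lr = 5e-3, seed = 11)
  res <- run_rounds(fx$recs, fx$ckpt, plan, subject_id = "s1")
  last <- res$metrics[nrow(res$metrics), ]
  expect_gte(last$accuracy, 0.75)
  expect_gte(last$auc, 0.75)
})

test_that("rounds stop when a class runs out of training records", {
  fx <- pers_fixture()
  # 3 hyper + 8 normo records: holdout 1 + 2, trainable 2 + 6 -> 2 rounds
  recs <- fx$recs[c(1:3, 9:16)]
  plan <- personalization_plan(lr = 5e-3, max_rounds = 5, seed = 2)
  res <- run_rounds(recs, fx$ckpt, plan, subject_id = "s2")
  expect_equal(max(res$metrics$round), 2L)
})
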