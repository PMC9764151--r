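test_that("majority vote matches direct counting, with ties going to hyperkalemia", {
  expect_equal(majority_vote(rep("hyper", 12)), "hyper")
  expect_equal(majority_vote(c(rep("hyper", 7), rep("normo", 5))), "hyper")
  expect_equal(majority_vote(c(rep("hyper", 6), rep("normo", 6))), "hyper")
  expect_equal(majority_vote(c("normo", "normo", "hyper")), "normo")
  expect_error(majority_vote(character(0)), "empty")
  # property: agrees with a brute-force count on random vote vectors
  set.seed(10)
  for (i in 1:50) {
    v <- sample(c("hyper", "normo"), sample(1:25, 1), replace = TRUE)
    nh <- sum(v == "hyper"); nn <- sum(v == "normo")
    expect_equal(majority_vote(v), if (nh >= nn) "hyper" else "normo")
  }
})

test_that("confusion metrics come from the 2x2 table with NA for empty denominators", {
  truth <- c("hyper", "hyper", "hyper", "hyper", "normo", "normo")
  pred <- c("hyper", "hyper", "hyper", "normo", "normo", "hyper")
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 0.5)
  expect_equal(cm$accuracy, 2 / 3)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))

  all_normo <- confusion_metrics(c("normo", "hyper"), c("normo", "normo"))
  expect_true(is.na(all_normo$sensitivity))
  expect_equal(all_normo$specificity, 0.5)
  expect_error(confusion_metrics("hyper", c("hyper", "normo")), "length")
})

test_that("rank-based AUC equals brute-force pair counting", {
  expect_equal(auc_score(c(0.9, 0.8, 0.1, 0.2), c("hyper", "hyper", "normo", "normo")), 1)
  expect_equal(auc_score(rep(0.5, 6), rep(c("hyper", "normo"), 3)), 0.5)
  s <- c(0.9, 0.8, 0.4, 0.3, 0.7); tr <- c("hyper", "hyper", "normo", "normo", "hyper")
  expect_equal(auc_score(s, tr), auc_brute(s, tr))
  # property sweep over random score vectors of length <= 10, with ties
  set.seed(22)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    tr <- c("hyper", "normo", sample(c("hyper", "normo"), n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # coarse grid forces ties
    expect_equal(auc_score(s, tr), auc_brute(s, tr))
  }
  expect_error(auc_score(1:3, rep("hyper", 3)), "both classes")
})

test_that("Mann-Whitney U: exact enumeration, ties, symmetry and approximation", {
  r <- mann_whitney_u(1, 1)
  expect_equal(r$U, 0.5)
  expect_equal(r$p_value, 1)

  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 arrangements

  a <- c(1.2, 3.4, 0.5, 2.2); b <- c(4.1, 2.8, 5.0)
  expect_equal(mann_whitney_u(a, b)$p_value, mann_whitney_u(b, a)$p_value)

  # exact p agrees with full enumeration for all sizes up to 6 + 6
  set.seed(5)
  for (n1 in c(2, 4, 6)) for (n2 in c(3, 6)) {
    x <- sample(1:8, n1, replace = TRUE)  # ties likely
    y <- sample(1:8, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_exact_brute(x, y))
  }

  # exact route agrees with the reference implementation when ties are absent
  set.seed(6)
  x <- rnorm(5); y <- rnorm(6)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value)

  # large samples: normal approximation tracks the reference implementation
  set.seed(7)
  x <- rnorm(30); y <- rnorm(25, 0.5)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  got <- mann_whitney_u(x, y)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("round aggregation reports mean (SD) per round and baseline comparisons", {
  m <- data.frame(subject_id = rep(c("a", "b"), each = 2),
                  round = rep(0:1, 2),
                  accuracy = c(0.5, 0.9, 0.7, 1.0),
                  auc = c(0.6, 0.95, 0.8, 1.0),
                  sensitivity = c(0.4, 0.9, 0.6, 1.0),
                  specificity = c(0.6, 0.9, 0.8, 1.0))
  agg <- aggregate_rounds(m)
  expect_equal(agg$mean_accuracy, c(0.6, 0.95))
  expect_equal(agg$sd_accuracy[1], stats::sd(c(0.5, 0.7)))
  expect_true(is.na(agg$p_accuracy[1]))
  expect_false(is.na(agg$p_accuracy[2]))
  # paired variant runs and stays in [0, 1]
  aggp <- aggregate_rounds(m, paired = TRUE)
  expect_true(all(aggp$p_accuracy[-1] >= 0 & aggp$p_accuracy[-1] <= 1))
  # single subject: SD is reported missing, not zero
  agg1 <- aggregate_rounds(m[m$subject_id == "a", ])
  expect_true(all(is.na(agg1$sd_accuracy)))
  expect_equal(agg1$n_subjects, c(1L, 1L))
})
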